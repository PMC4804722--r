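# Seeded full-pipeline replicates, computed once per test run and shared
# between the planted-structure and oracle test blocks.

.replicate_cache <- new.env(parent = emptyenv())

pipeline_replicates <- function(seeds = 1:20) {
  key <- paste(seeds, collapse = ",")
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])
  rows <- lapply(seeds, function(sd) {
    fix <- make_fixture(fixture_spec(seed = sd))
    res <- analyze_fixture(fix)
    gt <- fix$ground_truth
    deg_recall <- mean(unlist(lapply(names(gt$deg_sets), function(s)
      gt$deg_sets[[s]] %in% res$deg_sets[[s]])))
    multi_leak <- any(gt$multi_de_genes %in% unlist(res$deg_sets))
    freq_exact <- all(vapply(names(fix$promoters), function(s) {
      freq <- aggregate_frequencies(fix$library, fix$promoters[[s]],
                                    fix$pwms, stage = s)
      truth <- gt$pair_weights[gt$pair_weights$stage == s,
                               c("pair_id", "weight")]
      truth <- truth[order(truth$pair_id), ]
      identical(freq$pair_id, truth$pair_id) &&
        identical(as.integer(freq$weight), as.integer(truth$weight))
    }, logical(1)))
    hubs_found <- identical(sort(res$hubs), sort(names(gt$hubs)))
    partners_exact <- hubs_found && all(vapply(names(gt$hubs), function(h) {
      tab <- res$tables[[h]]
      !is.null(tab) && setequal(rownames(tab$presence),
                                gt$hubs[[h]]$partners)
    }, logical(1)))
    presence_exact <- hubs_found && all(vapply(names(gt$hubs), function(h) {
      tab <- res$tables[[h]]
      if (is.null(tab)) return(FALSE)
      ord <- order(rownames(tab$presence))
      gp <- gt$hubs[[h]]$presence
      gp <- gp[order(rownames(gp)), , drop = FALSE]
      identical(rownames(tab$presence)[ord], rownames(gp)) &&
        identical(unname(tab$presence[ord, , drop = FALSE]), unname(gp))
    }, logical(1)))
    data.frame(seed = sd, deg_recall = deg_recall,
               multi_leak = multi_leak, freq_exact = freq_exact,
               hubs_found = hubs_found, partners_exact = partners_exact,
               presence_exact = presence_exact)
  })
  out <- do.call(rbind, rows)
  .replicate_cache[[key]] <- out
  out
}
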