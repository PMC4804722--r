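#' Run the full analysis on an in-memory fixture
#'
#' Chains the pipeline: per-stage differential calls, stage-unique gene
#' selection, promoter extraction and overlap removal, composite-pair
#' scanning and frequency aggregation, network construction, Markov
#' clustering, reportable-cluster filtering, hub identification, and
#' hub-centered stage tracking with expression annotation.
#'
#' @param fixture A `tfbs_fixture` (see [make_fixture()]) or any list with
#'   elements `expression`, `annotations`, `genome`, `pwms`, `library`,
#'   `tf_mapping`.
#' @param params [mcl_params()] for the clustering.
#' @param p_max,fdr_max Differential-expression thresholds.
#' @param mode Frequency counting mode (see [aggregate_frequencies()]).
#' @param min_edges Reportable-cluster threshold (see
#'   [filter_reportable_clusters()]).
#' @param window Promoter window (see [extract_promoters()]).
#' @param fpkm_threshold Expression threshold for pair annotation.
#' @return List with per-stage and cross-stage results: `calls`,
#'   `deg_sets`, `regions`, `stage_sequences`, `freqs`, `networks`,
#'   `clusters`, `reportable`, `hubs`, `tables`, `pair_presence`,
#'   `annotations`.
#' @export
analyze_fixture <- function(fixture, params = mcl_params(), p_max = 0.05,
                            fdr_max = 0.01, mode = "promoter",
                            min_edges = 3L, window = c(-1000, 0),
                            fpkm_threshold = 10) {
  stages <- stage_definitions()
  calls <- lapply(seq_len(nrow(stages)), function(s)
    call_stage_degs(fixture$expression, stages[s, , drop = FALSE]))
  names(calls) <- stages$stage
  deg_sets <- filter_unique_degs(calls, fixture$annotations,
                                 p_max = p_max, fdr_max = fdr_max)
  proms <- extract_promoters(fixture$annotations, fixture$genome,
                             window = window)
  kept <- remove_overlapping_promoters(proms$regions)
  networks <- list(); freqs <- list(); clusters <- list()
  reportable <- list(); stage_sequences <- list()
  for (s in stages$stage) {
    gset <- intersect(deg_sets[[s]], kept$gene)
    seqs <- proms$sequences[gset]
    stage_sequences[[s]] <- seqs
    if (!length(seqs)) {
      freqs[[s]] <- NULL
      next
    }
    freq <- aggregate_frequencies(fixture$library, seqs, fixture$pwms,
                                  mode = mode, stage = s)
    freqs[[s]] <- freq
    if (!nrow(freq)) next
    net <- build_network(freq, fixture$library)
    networks[[s]] <- net
    res <- run_mcl(to_markov(net, params), params)
    clusters[[s]] <- res$clusters
    reportable[[s]] <- filter_reportable_clusters(res$clusters, net,
                                                  min_edges)
  }
  hubs <- sort(unique(unlist(lapply(stages$stage, function(s) {
    if (is.null(reportable[[s]])) return(character(0))
    vapply(reportable[[s]], find_hub, character(1L), net = networks[[s]])
  }))))
  tables <- lapply(hubs, function(h)
    track_hub_across_stages(clusters, networks, h, min_edges = min_edges))
  names(tables) <- hubs
  # stage presence of every detected pair (for annotation)
  pair_ids <- sort(unique(unlist(lapply(freqs, function(f) f$pair_id))))
  pair_presence <- vapply(stages$stage, function(s) {
    pair_ids %in% (if (is.null(freqs[[s]])) character(0)
                   else freqs[[s]]$pair_id)
  }, logical(length(pair_ids)))
  pair_presence <- matrix(pair_presence, nrow = length(pair_ids),
                          dimnames = list(pair_ids, stages$stage))
  annotations <- list()
  for (pid in pair_ids) {
    row <- fixture$library[fixture$library$pair_id == pid, , drop = FALSE]
    ann <- tryCatch(
      annotate_expression(row$pwm_a, row$pwm_b, pair_presence[pid, ],
                          fixture$tf_mapping, fixture$expression,
                          threshold = fpkm_threshold),
      error = function(e) NULL)  # pairs with unmapped sides are skipped
    if (!is.null(ann)) annotations[[pid]] <- ann
  }
  list(calls = calls, deg_sets = deg_sets, regions = kept,
       stage_sequences = stage_sequences, freqs = freqs,
       networks = networks, clusters = clusters, reportable = reportable,
       hubs = hubs, tables = tables, pair_presence = pair_presence,
       annotations = annotations)
}

#' Pipeline configuration
#'
#' Flat key-value configuration for the command-line pipeline. Paths are
#' resolved against the fixture/run directories; the promoter window must
#' be one of the three supported variants (`-1000:0`, `-500:0`,
#' `-500:100`) or an explicit custom pair.
#'
#' @param input_dir Directory holding the input files (as written by
#'   [write_fixture()]).
#' @param out_dir Output (run) directory.
#' @param seed Integer seed used by `simulate` and recorded in the log.
#' @param window Promoter window string `"<from>:<to>"`.
#' @param scan_threshold Default scanner threshold.
#' @param mode Frequency counting mode.
#' @param inflation,self_loop,tol,max_iter,prune MCL parameters.
#' @param fpkm_threshold Expression threshold.
#' @param p_max,fdr_max Differential-expression thresholds.
#' @param min_edges Reportable-cluster threshold.
#' @return Named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_dir = ".", out_dir = "run",
                            seed = 1L, window = "-1000:0",
                            scan_threshold = 0.95, mode = "promoter",
                            inflation = 2, self_loop = "max", tol = 1e-6,
                            max_iter = 200L, prune = 1e-9,
                            fpkm_threshold = 10, p_max = 0.05,
                            fdr_max = 0.01, min_edges = 3L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are
#' rejected. Values are coerced to the type of the corresponding
#' [pipeline_config()] default.
#'
#' @param path File path.
#' @param overrides Named list of values that win over the file contents
#'   (command-line flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_config()
  apply_kv <- function(key, value) {
    if (!key %in% names(cfg))
      stop(sprintf("invalid config key '%s'", key))
    default <- cfg[[key]]
    cfg[[key]] <<- if (is.numeric(default) && key != "self_loop") {
      as.numeric(value)
    } else value
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("missing config file '%s'", path))
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L)
        stop(sprintf("malformed config line '%s'", ln))
      apply_kv(trimws(kv[1L]), trimws(kv[2L]))
    }
  }
  for (key in names(overrides)) apply_kv(key, overrides[[key]])
  cfg
}

.parse_window <- function(window) {
  if (is.numeric(window)) return(window)
  parts <- as.numeric(strsplit(window, ":", fixed = TRUE)[[1L]])
  if (length(parts) != 2L || anyNA(parts))
    stop(sprintf("invalid promoter window '%s'", window))
  parts
}

.cfg_mcl_params <- function(cfg) {
  sl <- cfg$self_loop
  if (is.character(sl) && sl != "max") sl <- as.numeric(sl)
  mcl_params(inflation = cfg$inflation, self_loop = sl, tol = cfg$tol,
             max_iter = cfg$max_iter, prune = cfg$prune)
}

.need_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing input file '%s'", path))
  path
}

.read_inputs <- function(cfg) {
  d <- cfg$input_dir
  list(
    genome = as.character(Biostrings::readDNAStringSet(
      .need_file(file.path(d, "genome.fasta")))),
    annotations = read_annotations(.need_file(file.path(d, "annotations.tsv"))),
    pwms = read_transfac(.need_file(file.path(d, "pwms.transfac"))),
    library = read_composite_library(.need_file(file.path(d, "library.tsv"))),
    expression = read_expression(.need_file(file.path(d, "expression.tsv"))),
    tf_mapping = read_tf_mapping(.need_file(file.path(d, "tf_mapping.tsv")))
  )
}

.log_step <- function(cfg, name, inputs = character(0)) {
  log_path <- file.path(cfg$out_dir, "run_log.json")
  log <- if (file.exists(log_path))
    jsonlite::read_json(log_path, simplifyVector = FALSE) else list()
  digests <- as.list(tools::md5sum(inputs[file.exists(inputs)]))
  log[[name]] <- list(parameters = unclass(cfg),
                      package_version = as.character(
                        utils::packageVersion("tfbsnet")),
                      input_digests = digests)
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

.safe_name <- function(x) gsub("[^A-Za-z0-9_]+", "_", x)

#' Run one pipeline subcommand
#'
#' Subcommands, in pipeline order: `simulate` (write a synthetic fixture
#' into `input_dir`), `degs`, `promoters`, `scan`, `network`, `mcl`,
#' `stages`, `report`, and `all` (chain everything). Each subcommand
#' writes its module's outputs under `out_dir` plus a machine-readable
#' `run_log.json`; re-running with an identical configuration and seed
#' reproduces identical outputs.
#'
#' @param name Subcommand name.
#' @param cfg A `pipeline_config`.
#' @return Invisibly, the result list of the underlying computation (for
#'   `all`, the [analyze_fixture()] result).
#' @export
run_subcommand <- function(name, cfg = pipeline_config()) {
  valid <- c("simulate", "degs", "promoters", "scan", "network", "mcl",
             "stages", "report", "all")
  if (!name %in% valid)
    stop(sprintf("unknown subcommand '%s' (expected one of: %s)",
                 name, paste(valid, collapse = ", ")))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- stage_definitions()
  if (name == "simulate") {
    fix <- make_fixture(fixture_spec(seed = as.integer(cfg$seed),
                                     scan_threshold = cfg$scan_threshold))
    write_fixture(fix, cfg$input_dir)
    .log_step(cfg, "simulate")
    return(invisible(fix))
  }
  inputs <- .read_inputs(cfg)
  input_files <- file.path(cfg$input_dir,
                           c("genome.fasta", "annotations.tsv",
                             "pwms.transfac", "library.tsv",
                             "expression.tsv", "tf_mapping.tsv"))
  res <- analyze_fixture(inputs, params = .cfg_mcl_params(cfg),
                         p_max = cfg$p_max, fdr_max = cfg$fdr_max,
                         mode = cfg$mode, min_edges = cfg$min_edges,
                         window = .parse_window(cfg$window),
                         fpkm_threshold = cfg$fpkm_threshold)
  out <- function(f) file.path(cfg$out_dir, f)
  upto <- match(name, valid)
  if (upto >= match("degs", valid) || name == "all") {
    for (s in stages$stage)
      writeLines(res$deg_sets[[s]], out(sprintf("degs_%s.txt", s)))
  }
  if (name %in% c("promoters", "scan", "network", "mcl", "stages",
                  "report", "all")) {
    for (s in stages$stage) {
      seqs <- res$stage_sequences[[s]]
      if (length(seqs))
        Biostrings::writeXStringSet(
          Biostrings::DNAStringSet(unlist(seqs)),
          out(sprintf("promoters_%s.fasta", s)))
    }
  }
  if (name %in% c("scan", "network", "mcl", "stages", "report", "all")) {
    for (s in stages$stage) {
      seqs <- res$stage_sequences[[s]]
      occ <- if (length(seqs))
        detect_library_occurrences(inputs$library, seqs, inputs$pwms)
      else .empty_occurrences()
      write_occurrences(occ, out(sprintf("pairs_%s.tsv", s)))
    }
  }
  if (name %in% c("network", "mcl", "stages", "report", "all")) {
    for (s in names(res$networks))
      write_network(res$networks[[s]], out(sprintf("network_%s.tsv", s)))
  }
  if (name %in% c("mcl", "stages", "report", "all")) {
    for (s in names(res$clusters))
      write_clusters(res$clusters[[s]], s, .cfg_mcl_params(cfg),
                     out(sprintf("clusters_%s.json", s)))
  }
  if (name %in% c("stages", "report", "all")) {
    for (h in res$hubs)
      write_presence_table(res$tables[[h]],
                           out(sprintf("presence_%s.tsv", .safe_name(h))))
    jsonlite::write_json(res$annotations, out("annotations.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  if (name %in% c("report", "all")) {
    counts <- vapply(stages$stage, function(s)
      if (is.null(res$freqs[[s]])) 0L else nrow(res$freqs[[s]]), integer(1L))
    hg <- hourglass_profile(counts)
    lines <- c(
      sprintf("TFBS pairs per stage: %s",
              paste(sprintf("%s=%d", stages$stage, counts), collapse = ", ")),
      sprintf("Pair-count minimum at stage %d (%s); interior minimum: %s",
              hg$argmin_stage, stages$stage[hg$argmin_stage],
              hg$interior_min),
      sprintf("Reportable hubs: %s", paste(res$hubs, collapse = ", ")))
    for (h in res$hubs) {
      tab <- res$tables[[h]]
      lines <- c(lines, sprintf(
        "Hub %s: %d partner pair(s), %d present at all stages",
        h, count_union_pairs(tab), count_all_stage_pairs(tab)))
    }
    writeLines(lines, out("summary.txt"))
  }
  .log_step(cfg, name, input_files)
  invisible(res)
}

#' Run the complete pipeline (`all`)
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, the [analyze_fixture()] result.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  run_subcommand("all", cfg)
}
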