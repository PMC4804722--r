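#' Build a composite-module library entry
#'
#' A composite model pairs two PWMs with per-side score thresholds, an
#' edge-to-edge gap window (nucleotides strictly between the two site
#' spans), and a relative-orientation constraint. It is the machine-readable
#' form of an experimentally known co-binding TF pair.
#'
#' @param pair_id Identifier for the pair.
#' @param pwm_a,pwm_b PWM identifiers. Equal identifiers are permitted only
#'   for explicitly homotypic pairs.
#' @param threshold_a,threshold_b Match-score thresholds in `[0, 1]`.
#' @param min_gap,max_gap Gap window, `0 <= min_gap <= max_gap`.
#' @param orientation One of `"same"`, `"opposite"`, `"any"`.
#' @param ordered If `TRUE`, side A must lie upstream (5') of side B on the
#'   forward strand; by default both orders count as the same pair.
#' @return One-row `data.frame` usable as a library row.
#' @export
composite_model <- function(pair_id, pwm_a, pwm_b, threshold_a = 0.95,
                            threshold_b = 0.95, min_gap = 0, max_gap = 50,
                            orientation = c("any", "same", "opposite"),
                            ordered = FALSE) {
  orientation <- match.arg(orientation)
  if (threshold_a < 0 || threshold_a > 1 || threshold_b < 0 || threshold_b > 1)
    stop("thresholds must be in [0, 1]")
  if (min_gap < 0 || min_gap > max_gap)
    stop("need 0 <= min_gap <= max_gap")
  data.frame(pair_id = pair_id, pwm_a = pwm_a, pwm_b = pwm_b,
             threshold_a = threshold_a, threshold_b = threshold_b,
             min_gap = as.integer(min_gap), max_gap = as.integer(max_gap),
             orientation = orientation, ordered = ordered,
             stringsAsFactors = FALSE)
}

.check_library <- function(library) {
  need <- c("pair_id", "pwm_a", "pwm_b", "threshold_a", "threshold_b",
            "min_gap", "max_gap", "orientation", "ordered")
  missing <- setdiff(need, names(library))
  if (length(missing))
    stop("composite library lacks columns: ", paste(missing, collapse = ", "))
  invisible(library)
}

#' Read / write a composite-module library (TSV)
#'
#' Columns: `pair_id`, `pwm_a`, `pwm_b`, `threshold_a`, `threshold_b`,
#' `min_gap`, `max_gap`, `orientation`, `ordered`.
#'
#' @param path File path.
#' @return `data.frame` with one row per composite model.
#' @export
read_composite_library <- function(path) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  lib$ordered <- as.logical(lib$ordered)
  .check_library(lib)
}

#' @rdname read_composite_library
#' @param library Library `data.frame`.
#' @export
write_composite_library <- function(library, path) {
  .check_library(library)
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.EMPTY_OCC <- .fast_df(pair_id = character(0), seq_id = character(0),
                       start_a = integer(0), end_a = integer(0),
                       strand_a = character(0), score_a = numeric(0),
                       start_b = integer(0), end_b = integer(0),
                       strand_b = character(0), score_b = numeric(0),
                       gap = integer(0))

.empty_occurrences <- function() .EMPTY_OCC

# gap strictly between two 1-based inclusive spans; negative => overlap/abut
.span_gap <- function(s1, e1, s2, e2) {
  ifelse(e1 < s2, s2 - e1 - 1L, ifelse(e2 < s1, s1 - e2 - 1L, -1L))
}

#' Detect composite-pair occurrences in one sequence
#'
#' Pairs every hit of `pwm_a` with every hit of `pwm_b` (above the model's
#' thresholds) whose spans do not overlap, whose edge-to-edge gap lies in
#' `[min_gap, max_gap]`, and whose strands satisfy the orientation rule
#' (`same` = equal strands, `opposite` = unequal, `any` = unconstrained).
#' Unless the model is `ordered`, both genomic orders (A upstream of B or
#' vice versa) are reported as the same pair. All satisfying combinations
#' are returned.
#'
#' @param model One-row library `data.frame` (see [composite_model()]).
#' @param seq_id Sequence identifier.
#' @param sequence Nucleotide string.
#' @param pwms Named list of `pwm` objects covering the model's PWM ids.
#' @param hits Optional named list of precomputed hit tables (from
#'   [scan_pwm()] at a threshold no higher than the model's); scores are
#'   re-filtered per side.
#' @return Occurrence `data.frame` (one row per pair instance) with columns
#'   `pair_id`, `seq_id`, `start_a`, `end_a`, `strand_a`, `score_a`,
#'   `start_b`, `end_b`, `strand_b`, `score_b`, `gap`.
#' @export
detect_pairs <- function(model, seq_id, sequence, pwms, hits = NULL) {
  .check_library(model)
  stopifnot(nrow(model) == 1L)
  if (!is.na(sequence) && !nzchar(sequence)) stop("'sequence' must be non-empty")
  for (p in c(model$pwm_a, model$pwm_b))
    if (is.null(pwms[[p]]))
      stop(sprintf("unknown PWM id '%s' in composite model '%s'",
                   p, model$pair_id))
  side_hits <- function(pwm_id, thr) {
    h <- if (!is.null(hits) && !is.null(hits[[pwm_id]])) hits[[pwm_id]]
         else scan_pwm(pwms[[pwm_id]], seq_id, sequence, threshold = thr)
    h[h$score >= thr, , drop = FALSE]
  }
  ha <- side_hits(model$pwm_a, model$threshold_a)
  hb <- side_hits(model$pwm_b, model$threshold_b)
  na <- nrow(ha); nb <- nrow(hb)
  if (!na || !nb) return(.empty_occurrences())
  i <- rep(seq_len(na), nb)
  j <- rep(seq_len(nb), each = na)
  if (model$pwm_a == model$pwm_b) {
    # homotypic: avoid self-pairs and (i, j)/(j, i) double counting
    keep_ij <- i < j
    i <- i[keep_ij]; j <- j[keep_ij]
    if (!length(i)) return(.empty_occurrences())
  }
  gap <- .span_gap(ha$start[i], ha$end[i], hb$start[j], hb$end[j])
  keep <- gap >= model$min_gap & gap <= model$max_gap
  keep <- keep & switch(model$orientation,
                        same = ha$strand[i] == hb$strand[j],
                        opposite = ha$strand[i] != hb$strand[j],
                        any = TRUE)
  if (isTRUE(model$ordered)) keep <- keep & ha$end[i] < hb$start[j]
  if (!any(keep)) return(.empty_occurrences())
  i <- i[keep]; j <- j[keep]; gap <- gap[keep]
  o <- order(ha$start[i], hb$start[j])
  i <- i[o]; j <- j[o]; gap <- gap[o]
  .fast_df(pair_id = rep(model$pair_id, length(i)),
           seq_id = rep(seq_id, length(i)),
           start_a = ha$start[i], end_a = ha$end[i],
           strand_a = ha$strand[i], score_a = ha$score[i],
           start_b = hb$start[j], end_b = hb$end[j],
           strand_b = hb$strand[j], score_b = hb$score[j],
           gap = gap)
}

# Scan each PWM used by the library once per sequence, at the lowest
# threshold any model requires for it; score models are precomputed once
# (`.models`) when many sequences are scanned.
.library_hits <- function(library, seq_id, sequence, pwms, .models = NULL) {
  ids <- unique(c(library$pwm_a, library$pwm_b))
  thr <- vapply(ids, function(p) {
    min(c(library$threshold_a[library$pwm_a == p],
          library$threshold_b[library$pwm_b == p]))
  }, numeric(1L))
  hits <- lapply(seq_along(ids), function(k) {
    if (is.null(pwms[[ids[k]]]))
      stop(sprintf("unknown PWM id '%s' in composite library", ids[k]))
    scan_pwm(pwms[[ids[k]]], seq_id, sequence, threshold = thr[k],
             .model = .models[[ids[k]]])
  })
  names(hits) <- ids
  hits
}

#' Detect all library pair occurrences over a sequence set
#'
#' @param library Composite library `data.frame`.
#' @param sequences Named character vector or `DNAStringSet` of promoter
#'   sequences.
#' @param pwms Named list of `pwm` objects.
#' @return Combined occurrence `data.frame` over all models and sequences.
#' @export
detect_library_occurrences <- function(library, sequences, pwms) {
  .check_library(library)
  sequences <- .as_char_seqs(sequences)
  ids <- unique(c(library$pwm_a, library$pwm_b))
  models <- lapply(pwms[intersect(ids, names(pwms))], .score_model)
  res <- list()
  for (sid in names(sequences)) {
    hits <- .library_hits(library, sid, sequences[[sid]], pwms,
                          .models = models)
    for (k in seq_len(nrow(library))) {
      occ <- detect_pairs(library[k, , drop = FALSE], sid, sequences[[sid]],
                          pwms, hits = hits)
      if (nrow(occ)) res[[length(res) + 1L]] <- occ
    }
  }
  if (!length(res)) return(.empty_occurrences())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Aggregate pair frequencies over a promoter set
#'
#' Default counting mode (`"promoter"`) counts the number of distinct
#' promoters containing at least one occurrence of the pair; mode
#' `"occurrence"` counts total occurrences. Pairs with zero count are
#' omitted.
#'
#' @inheritParams detect_library_occurrences
#' @param mode `"promoter"` or `"occurrence"`.
#' @param stage Optional stage label attached to the result.
#' @return `data.frame` with columns `pair_id`, `weight` (all weights
#'   `>= 1`), with attribute `stage`; class `"pair_freq"`.
#' @export
aggregate_frequencies <- function(library, sequences, pwms,
                                  mode = c("promoter", "occurrence"),
                                  stage = NULL) {
  mode <- match.arg(mode)
  sequences <- .as_char_seqs(sequences)
  if (!length(sequences)) stop("promoter set must be non-empty")
  occ <- detect_library_occurrences(library, sequences, pwms)
  if (!nrow(occ)) {
    tab <- data.frame(pair_id = character(0), weight = integer(0),
                      stringsAsFactors = FALSE)
  } else if (mode == "promoter") {
    u <- unique(occ[c("pair_id", "seq_id")])
    agg <- table(u$pair_id)
    tab <- data.frame(pair_id = names(agg), weight = as.integer(agg),
                      stringsAsFactors = FALSE)
  } else {
    agg <- table(occ$pair_id)
    tab <- data.frame(pair_id = names(agg), weight = as.integer(agg),
                      stringsAsFactors = FALSE)
  }
  tab <- tab[order(tab$pair_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "stage") <- stage
  attr(tab, "mode") <- mode
  class(tab) <- c("pair_freq", "data.frame")
  tab
}

#' Write pair occurrences to TSV (0-based half-open coordinates)
#'
#' @param occurrences Occurrence `data.frame` from
#'   [detect_library_occurrences()].
#' @param path File path.
#' @export
write_occurrences <- function(occurrences, path) {
  out <- occurrences
  for (col in c("start_a", "start_b")) out[[col]] <- out[[col]] - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.as_char_seqs <- function(sequences) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  if (is.null(names(sequences)) && length(sequences))
    names(sequences) <- paste0("seq", seq_along(sequences))
  as.list(sequences)
}
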