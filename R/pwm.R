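
#' Construct a position weight matrix (PWM)
#'
#' A PWM models the per-position nucleotide preference of a transcription
#' factor binding motif as an `L x 4` matrix of non-negative counts over the
#' alphabet ACGT, plus a pseudocount and a background nucleotide distribution.
#'
#' @param id Matrix identifier string (e.g. `"V$AP1_01"`).
#' @param counts `L x 4` numeric matrix of non-negative counts, columns in
#'   A, C, G, T order (column names are overwritten accordingly).
#' @param pseudocount Non-negative scalar added to every cell before
#'   normalization. The default, 1% of the mean per-position count total,
#'   keeps log-probabilities finite for zero counts without materially
#'   flattening well-supported positions.
#' @param background Length-4 probability vector over ACGT; must sum to 1.
#' @return An object of class `"pwm"`.
#' @examples
#' m <- pwm("toy", matrix(c(10, 0, 0, 0, 0, 10, 0, 0), 2, 4, byrow = TRUE))
#' consensus_string(m)
#' @export
pwm <- function(id, counts, pseudocount = NULL, background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("'counts' must have 4 columns (A, C, G, T)")
  if (nrow(counts) < 1L)
    stop("PWM must have at least one position")
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("'counts' must be finite and non-negative")
  colnames(counts) <- DNA_BASES
  rownames(counts) <- NULL
  if (is.null(pseudocount))
    pseudocount <- 0.01 * mean(rowSums(counts))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("'pseudocount' must be a non-negative scalar")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background < 0))
    stop("'background' must be 4 non-negative probabilities")
  if (abs(sum(background) - 1) > 1e-9)
    stop("'background' must sum to 1")
  if (any(rowSums(counts) == 0) && pseudocount == 0)
    stop("degenerate matrix: all-zero position with zero pseudocount")
  structure(
    list(id = as.character(id), counts = counts,
         pseudocount = pseudocount, background = background),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s: %d positions, pseudocount %.4g, IC %.2f bits\n",
              x$id, nrow(x$counts), x$pseudocount, information_content(x)))
  invisible(x)
}

#' Width (number of positions) of a PWM
#' @param x A `pwm` object.
#' @export
pwm_width <- function(x) nrow(x$counts)

#' Normalize a PWM into per-position probabilities
#'
#' Each count has the pseudocount added and the row is normalized to sum
#' to 1: `p[i, j] = (c[i, j] + p) / (sum_j c[i, j] + 4 p)`.
#'
#' @param x A `pwm` object.
#' @return `L x 4` matrix of probabilities; every row sums to 1.
#' @export
normalize_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  cc <- x$counts + x$pseudocount
  tot <- rowSums(cc)
  if (any(tot == 0))
    stop("degenerate matrix: all-zero position with zero pseudocount")
  cc / tot
}

#' Information content of a PWM in bits
#'
#' Kullback-Leibler divergence of the per-position probabilities from the
#' background, summed over positions:
#' `IC = sum_i sum_j p[i, j] * log2(p[i, j] / q[j])`. Terms with
#' `p[i, j] == 0` contribute 0. Bounded by `2 * L` for a uniform background.
#'
#' @param x A `pwm` object with strictly positive background.
#' @return Non-negative scalar (bits).
#' @export
information_content <- function(x) {
  p <- normalize_pwm(x)
  q <- x$background
  if (any(q <= 0))
    stop("information content requires a strictly positive background")
  terms <- p * log2(sweep(p, 2, q, "/"))
  terms[p == 0] <- 0
  sum(terms)
}

#' Consensus word of a PWM
#'
#' The per-position most-probable letter (ties resolved to the first of
#' A, C, G, T).
#'
#' @param x A `pwm` object.
#' @return Character scalar of length `pwm_width(x)`.
#' @export
consensus_string <- function(x) {
  p <- normalize_pwm(x)
  paste(DNA_BASES[apply(p, 1L, which.max)], collapse = "")
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character scalar over A, C, G, T, N (case-insensitive).
#' @return Reverse-complemented upper-case string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

# Letters -> 1..4 index vector; N and other letters become NA.
.seq_index <- function(sequence) {
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]], DNA_BASES)
}

# log2 probability matrix plus min/max achievable window sums. Exact-zero
# probabilities (possible with zero pseudocount) are clamped to a tiny
# floor so scores stay finite; the consensus still scores 1 and the
# per-position worst word 0.
.score_model <- function(x) {
  p <- normalize_pwm(x)
  p[p == 0] <- 1e-6
  logp <- log2(p)
  list(logp = logp,
       smin = sum(apply(logp, 1L, min)),
       smax = sum(apply(logp, 1L, max)))
}

# Normalize raw log-prob sums to [0, 1]; degenerate flat matrices score 1
# at every window (smax == smin).
.minmax <- function(s, smin, smax) {
  if (smax - smin < 1e-12) return(rep(1, length(s)))
  (s - smin) / (smax - smin)
}

# Scores of all windows on one strand; idx is the forward-strand letter
# index vector. Windows containing N give NA. On the minus strand the
# forward window [s, s + L - 1] is scored as its reverse complement:
# position i of the motif reads the complement of idx[s + L - i].
.window_scores <- function(model, idx, strand) {
  L <- nrow(model$logp)
  n <- length(idx)
  nwin <- n - L + 1L
  if (nwin < 1L) return(numeric(0L))
  s <- numeric(nwin)
  offs <- seq_len(nwin) - 1L
  if (strand == "+") {
    for (i in seq_len(L)) s <- s + model$logp[i, ][idx[offs + i]]
  } else {
    comp <- 5L - idx
    for (i in seq_len(L)) s <- s + model$logp[i, ][comp[offs + L - i + 1L]]
  }
  .minmax(unname(s), model$smin, model$smax)
}

#' Score one sequence window against a PWM
#'
#' Computes the min-max-normalized log-probability ("MATCH-style") score of
#' the window of length `pwm_width(x)` starting at `start` (1-based):
#' `score = (S - Smin) / (Smax - Smin)`, where `S` is the summed per-position
#' log2 probability of the (strand-resolved) window and `Smin`/`Smax` the
#' minimal/maximal achievable sums. Windows containing `N` score 0.
#'
#' @param x A `pwm` object.
#' @param sequence Nucleotide string over A, C, G, T, N.
#' @param start 1-based start of the window on the forward strand.
#' @param strand `"+"` or `"-"`; on `"-"` the reverse complement of the
#'   window is scored (coordinates stay on the forward strand).
#' @return Score in `[0, 1]`.
#' @export
score_site <- function(x, sequence, start, strand = c("+", "-")) {
  strand <- match.arg(strand)
  L <- pwm_width(x)
  idx <- .seq_index(sequence)
  if (start < 1L || start + L - 1L > length(idx))
    stop("window out of sequence bounds")
  win <- idx[start:(start + L - 1L)]
  if (anyNA(win)) return(0)
  model <- .score_model(x)
  if (strand == "-") win <- rev(5L - win)
  s <- sum(model$logp[cbind(seq_len(L), win)])
  .minmax(s, model$smin, model$smax)
}

#' Scan a sequence (both strands) for PWM matches
#'
#' Every window on either strand with normalized score `>= threshold` is
#' reported. Minus-strand hits are reported in forward-strand coordinates.
#' Windows containing `N` are never hits.
#'
#' @param x A `pwm` object.
#' @param seq_id Sequence identifier carried into the output.
#' @param sequence Nucleotide string.
#' @param threshold Score threshold in `[0, 1]`.
#' @param .model Precomputed internal score model (for repeated scans of
#'   many sequences with the same PWM); normally left `NULL`.
#' @return `data.frame` with columns `pwm_id`, `seq_id`, `start`, `end`
#'   (1-based, inclusive), `strand`, `score`, sorted by `(start, strand)`.
#' @export
scan_pwm <- function(x, seq_id, sequence, threshold = 0.95, .model = NULL) {
  if (threshold < 0 || threshold > 1) stop("'threshold' must be in [0, 1]")
  if (is.na(sequence) || nchar(sequence) == 0L) return(.EMPTY_HITS)
  idx <- .seq_index(sequence)
  L <- nrow(x$counts)
  if (length(idx) < L) return(.EMPTY_HITS)
  model <- if (is.null(.model)) .score_model(x) else .model
  sp <- .window_scores(model, idx, "+")
  sm <- .window_scores(model, idx, "-")
  kp <- which(!is.na(sp) & sp >= threshold)
  km <- which(!is.na(sm) & sm >= threshold)
  if (!length(kp) && !length(km)) return(.EMPTY_HITS)
  start <- c(kp, km)
  strand <- rep(c("+", "-"), c(length(kp), length(km)))
  score <- c(sp[kp], sm[km])
  o <- order(start, strand)
  .fast_df(pwm_id = rep(x$id, length(start)),
           seq_id = rep(seq_id, length(start)),
           start = start[o], end = start[o] + L - 1L,
           strand = strand[o], score = score[o])
}

#' Read PWMs from a TRANSFAC-style flat file
#'
#' Records are delimited by `//`; each record carries an `ID` line with the
#' matrix identifier and numbered rows (`01` .. `NN`) with four
#' whitespace-separated counts in A, C, G, T order. Integer or real counts
#' are accepted; a trailing consensus-letter column and an optional
#' `P0 A C G T` header are tolerated.
#'
#' @param path File path.
#' @param pseudocount,background Passed to [pwm()] for every record.
#' @return Named list of `pwm` objects.
#' @export
read_transfac <- function(path, pseudocount = NULL, background = rep(0.25, 4)) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(grepl("^//", lines)))
  out <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^//", rec)]
    id_line <- grep("^ID\\s+", rec, value = TRUE)
    if (!length(id_line)) next
    id <- sub("^ID\\s+", "", id_line[[1L]])
    rows <- grep("^\\s*[0-9]+\\s+\\S", rec, value = TRUE)
    if (!length(rows)) stop(sprintf("record '%s' has no count rows", id))
    counts <- t(vapply(rows, function(r) {
      parts <- strsplit(trimws(r), "\\s+")[[1L]][-1L]
      vals <- suppressWarnings(as.numeric(parts))
      vals <- vals[!is.na(vals)]
      if (length(vals) < 4L)
        stop(sprintf("record '%s': row with fewer than 4 counts", id))
      vals[1:4]
    }, numeric(4L), USE.NAMES = FALSE))
    out[[id]] <- pwm(id, counts, pseudocount = pseudocount,
                     background = background)
  }
  out
}

#' Write PWMs to a TRANSFAC-style flat file
#'
#' @param pwms List of `pwm` objects.
#' @param path File path.
#' @export
write_transfac <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (x in pwms) {
    writeLines(c(sprintf("ID %s", x$id), "P0      A      C      G      T"),
               con)
    for (i in seq_len(pwm_width(x))) {
      writeLines(sprintf("%02d %6g %6g %6g %6g", i,
                         x$counts[i, 1L], x$counts[i, 2L],
                         x$counts[i, 3L], x$counts[i, 4L]), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
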