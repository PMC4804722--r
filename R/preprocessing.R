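#' Default developmental stage definitions
#'
#' Five stages spanning a six-timepoint (days 0, 3, 8, 13, 29, 60) cardiac
#' differentiation time course: mesoderm induction (0-3), early cardiac
#' specification (3-8), late cardiac specification (8-13), early cardiac
#' maturation (13-29), late cardiac maturation (29-60). Each stage is
#' bounded by two consecutive timepoints.
#'
#' @return `data.frame` with columns `stage`, `start`, `end` (days).
#' @export
stage_definitions <- function() {
  data.frame(
    stage = c("mesoderm_induction", "early_specification",
              "late_specification", "early_maturation", "late_maturation"),
    start = c(0, 3, 8, 13, 29),
    end = c(3, 8, 13, 29, 60),
    stringsAsFactors = FALSE
  )
}

# Column names follow "d<day>_r<rep>", e.g. "d0_r1".
.expr_cols <- function(expr) {
  m <- regmatches(colnames(expr),
                  regexec("^d([0-9]+)_r([0-9]+)$", colnames(expr)))
  bad <- vapply(m, length, integer(1L)) != 3L
  if (any(bad))
    stop("expression columns must be named d<day>_r<rep>; offending: ",
         paste(colnames(expr)[bad], collapse = ", "))
  data.frame(col = colnames(expr),
             day = as.numeric(vapply(m, `[`, character(1L), 2L)),
             rep = as.integer(vapply(m, `[`, character(1L), 3L)),
             stringsAsFactors = FALSE)
}

#' Read / write an FPKM expression matrix (TSV)
#'
#' Rows are genes; columns are `d<day>_r<replicate>` FPKM values.
#'
#' @param path File path.
#' @return Numeric matrix with gene row names.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  .expr_cols(m)
  m
}

#' @rdname read_expression
#' @param expr Expression matrix.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene mean FPKM by timepoint
#'
#' Replicates are averaged within each timepoint (the convention used for
#' expression thresholding).
#'
#' @param expr Expression matrix (see [read_expression()]).
#' @return Gene x timepoint matrix; columns named by day, ascending.
#' @export
timepoint_means <- function(expr) {
  cols <- .expr_cols(expr)
  days <- sort(unique(cols$day))
  out <- vapply(days, function(d) {
    rowMeans(expr[, cols$col[cols$day == d], drop = FALSE])
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr),
                dimnames = list(rownames(expr), days))
  out
}

#' Call differentially expressed genes for one stage
#'
#' Stand-in differential test between the stage's two bounding timepoints:
#' a per-gene two-sample location test across replicates on
#' `log2(FPKM + 1)`, with Benjamini-Hochberg FDR adjustment within the
#' stage. The test is pluggable; the default is Welch's t-test. A gene with
#' identical values in both groups gets `p = 1` and no direction.
#'
#' @param expr Expression matrix (see [read_expression()]).
#' @param stage One-row `data.frame` with `stage`, `start`, `end` (see
#'   [stage_definitions()]).
#' @param test Function `(x, y) -> p-value` applied to the two log2
#'   replicate vectors; defaults to a pooled-variance two-sample t-test.
#' @return `data.frame` with one row per gene: `gene`, `stage`, `p_value`,
#'   `fdr`, `direction` (`"up"`/`"down"`/`NA`).
#' @export
call_stage_degs <- function(expr, stage, test = NULL) {
  cols <- .expr_cols(expr)
  for (d in c(stage$start, stage$end))
    if (!any(cols$day == d))
      stop(sprintf("timepoint day %s missing from expression matrix", d))
  xa <- expr[, cols$col[cols$day == stage$start], drop = FALSE]
  xb <- expr[, cols$col[cols$day == stage$end], drop = FALSE]
  if (ncol(xa) < 2L || ncol(xb) < 2L)
    stop("the per-gene two-sample test requires >= 2 replicates per timepoint")
  la <- log2(xa + 1)
  lb <- log2(xb + 1)
  if (is.null(test)) {
    # Pooled-variance two-sample t (the moderated-t stand-in; Welch's df
    # collapses toward 2 with triplicates and floors attainable p-values).
    # Degenerate zero-variance groups: p = 1 when the group means agree
    # (no signal), p = 0 for a noiseless level shift.
    test <- function(x, y) {
      if (stats::var(x) == 0 && stats::var(y) == 0)
        return(if (mean(x) == mean(y)) 1 else 0)
      stats::t.test(x, y, var.equal = TRUE)$p.value
    }
  }
  p <- vapply(seq_len(nrow(expr)), function(i) test(la[i, ], lb[i, ]),
              numeric(1L))
  delta <- rowMeans(lb) - rowMeans(la)
  direction <- ifelse(delta > 0, "up", ifelse(delta < 0, "down", NA))
  direction[p >= 1] <- NA
  data.frame(gene = rownames(expr), stage = stage$stage, p_value = p,
             fdr = stats::p.adjust(p, method = "BH"),
             direction = direction, stringsAsFactors = FALSE)
}

#' Select stage-unique differentially expressed genes
#'
#' A gene is retained for a stage iff it passes `p <= p_max` and
#' `fdr <= fdr_max` in that stage and in no other stage (same thresholds),
#' is protein-coding, and is not itself a transcription factor gene.
#'
#' @param calls Named list of per-stage call `data.frame`s (see
#'   [call_stage_degs()]), one per stage.
#' @param annotations Gene annotation `data.frame` with columns `gene`,
#'   `biotype`, `is_tf` (see [read_annotations()]).
#' @param p_max,fdr_max Significance thresholds (defaults 0.05 and 0.01).
#' @return Named list (per stage) of character vectors of gene ids; the
#'   sets are disjoint by construction.
#' @export
filter_unique_degs <- function(calls, annotations, p_max = 0.05,
                               fdr_max = 0.01) {
  sig <- lapply(calls, function(cl) {
    cl$gene[cl$p_value <= p_max & cl$fdr <= fdr_max]
  })
  all_sig <- unlist(sig, use.names = FALSE)
  counts <- table(all_sig)
  unique_genes <- names(counts)[counts == 1L]
  coding <- annotations$gene[annotations$biotype == "protein_coding" &
                               !annotations$is_tf]
  lapply(sig, function(g) sort(intersect(intersect(g, unique_genes), coding)))
}

#' Read gene annotations (BED-like TSV)
#'
#' Columns: `chrom`, `start` (0-based TSS), `end` (`start + 1`), `gene`,
#' `biotype`, `strand`, `is_tf`.
#'
#' @param path File path.
#' @return `data.frame` with columns `gene`, `chrom`, `tss` (0-based),
#'   `strand`, `biotype`, `is_tf`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(gene = df$gene, chrom = df$chrom, tss = df$start,
             strand = df$strand, biotype = df$biotype,
             is_tf = as.logical(df$is_tf), stringsAsFactors = FALSE)
}

#' @rdname read_annotations
#' @param annotations Annotation `data.frame`.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(chrom = annotations$chrom, start = annotations$tss,
                   end = annotations$tss + 1L, gene = annotations$gene,
                   biotype = annotations$biotype, strand = annotations$strand,
                   is_tf = annotations$is_tf, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract upstream promoter regions
#'
#' For a plus-strand gene with 0-based TSS `t` and window `c(w1, w2)`
#' (default `c(-1000, 0)`), the promoter is the half-open interval
#' `[t + w1, t + w2)`; for a minus-strand gene it is the mirrored interval
#' `[t - w2, t - w1)` and the sequence is reverse-complemented, so that the
#' returned sequence always reads 5' to 3' toward the TSS. Regions are
#' truncated at chromosome edges and reported with their achieved length.
#' The alternative windows `c(-500, 0)` and `c(-500, 100)` are supported
#' configuration values.
#'
#' @param annotations Annotation `data.frame` (see [read_annotations()]).
#' @param genome Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param window Length-2 integer vector, promoter window relative to the
#'   TSS; `window[1] < window[2]`.
#' @return List with `regions` (a `data.frame`: `gene`, `chrom`, `start`,
#'   `end` 1-based inclusive, `strand`, `length`) and `sequences` (named
#'   character vector).
#' @export
extract_promoters <- function(annotations, genome, window = c(-1000, 0)) {
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("'window' must be two increasing offsets relative to the TSS")
  if (methods::is(genome, "XStringSet")) genome <- as.character(genome)
  chr_len <- nchar(genome)
  regions <- list()
  seqs <- character(0)
  for (i in seq_len(nrow(annotations))) {
    g <- annotations[i, ]
    if (!g$chrom %in% names(genome))
      stop(sprintf("unknown chromosome '%s' for gene '%s'", g$chrom, g$gene))
    # 0-based half-open region, then convert to 1-based inclusive
    if (g$strand == "+") {
      s0 <- g$tss + window[1L]; e0 <- g$tss + window[2L]
    } else {
      s0 <- g$tss - window[2L]; e0 <- g$tss - window[1L]
    }
    s1 <- max(s0 + 1L, 1L)
    e1 <- min(e0, chr_len[[g$chrom]])
    if (e1 < s1) next  # fully outside the chromosome
    sq <- substr(genome[[g$chrom]], s1, e1)
    if (g$strand == "-") sq <- revcomp(sq)
    regions[[length(regions) + 1L]] <-
      data.frame(gene = g$gene, chrom = g$chrom, start = s1, end = e1,
                 strand = g$strand, length = e1 - s1 + 1L,
                 stringsAsFactors = FALSE)
    seqs[[g$gene]] <- sq
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(gene = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0), length = integer(0))
  rownames(regions) <- NULL
  list(regions = regions, sequences = seqs)
}

#' Remove mutually overlapping promoter regions
#'
#' Every region that shares at least one base (same chromosome,
#' strand-agnostic) with any other region is removed; both members of an
#' overlapping pair are dropped. Idempotent.
#'
#' @param regions Region `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive), as produced by [extract_promoters()].
#' @return The subset of `regions` overlapping nothing else.
#' @export
remove_overlapping_promoters <- function(regions) {
  if (!nrow(regions)) return(regions)
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end)
  )
  n_ov <- GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE)
  out <- regions[n_ov == 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
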