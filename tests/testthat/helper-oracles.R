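# Independent brute-force oracles, deliberately written in a different
# style from the package implementation.

ORACLE_BASES <- c("A", "C", "G", "T")

# reverse complement without Biostrings
bf_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1L]]),
        collapse = "")
}

# per-position probabilities recomputed from first principles
bf_probs <- function(x) {
  cc <- x$counts + x$pseudocount
  t(apply(cc, 1L, function(r) r / sum(r)))
}

# min-max normalized log-probability score of one word (forward strand)
bf_score_word <- function(x, word) {
  p <- bf_probs(x)
  p[p == 0] <- 1e-6
  letters <- strsplit(word, "")[[1L]]
  if (any(!letters %in% ORACLE_BASES)) return(0)
  s <- 0; smin <- 0; smax <- 0
  for (i in seq_along(letters)) {
    lp <- log2(p[i, ])
    s <- s + lp[[letters[i]]]
    smin <- smin + min(lp)
    smax <- smax + max(lp)
  }
  if (smax - smin < 1e-12) return(1)
  (s - smin) / (smax - smin)
}

# exhaustive both-strand scan by scoring every window individually
bf_scan <- function(x, seq_id, sequence, threshold) {
  L <- nrow(x$counts)
  n <- nchar(sequence)
  rows <- list()
  if (n >= L) {
    for (start in 1:(n - L + 1L)) {
      word <- substr(sequence, start, start + L - 1L)
      for (st in c("+", "-")) {
        w <- if (st == "+") word else bf_revcomp(word)
        sc <- bf_score_word(x, w)
        if (grepl("[^ACGT]", toupper(word))) next  # N windows never hit
        if (sc >= threshold)
          rows[[length(rows) + 1L]] <- data.frame(
            pwm_id = x$id, seq_id = seq_id, start = start,
            end = start + L - 1L, strand = st, score = sc,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(pwm_id = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# temporal category via string pattern matching
bf_classify <- function(v) {
  s <- paste(ifelse(v, "T", "F"), collapse = "")
  if (!grepl("T", s)) stop("empty")
  if (!grepl("F", s)) return("all_stages")
  if (sum(v) == 1) return("stage_specific")
  if (grepl("T.*F.*T", s)) return("interrupted")
  "other"
}

# pairwise overlap filter by double loop
bf_overlap_filter <- function(regions) {
  n <- nrow(regions)
  drop <- rep(FALSE, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (regions$chrom[i] == regions$chrom[j] &&
          regions$start[i] <= regions$end[j] &&
          regions$start[j] <= regions$end[i]) {
        drop[i] <- TRUE; drop[j] <- TRUE
      }
    }
  }
  out <- regions[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# cubic-time matrix product
bf_matmul <- function(A, B) {
  n <- nrow(A); m <- ncol(B)
  out <- matrix(0, n, m, dimnames = dimnames(A))
  for (i in 1:n) for (j in 1:m) {
    acc <- 0
    for (k in 1:ncol(A)) acc <- acc + A[i, k] * B[k, j]
    out[i, j] <- acc
  }
  out
}

# entrywise-power inflation by explicit row loops
bf_inflate <- function(M, r) {
  out <- M
  for (i in 1:nrow(M)) {
    row <- M[i, ]^r
    out[i, ] <- row / sum(row)
  }
  out
}

# independent flow simulation: iterate expand/inflate with loop arithmetic
# and read clusters as connected components of the surviving flow graph
bf_mcl <- function(M, r = 2, iters = 100, eps = 1e-9) {
  for (t in 1:iters) {
    M2 <- bf_inflate(bf_matmul(M, M), r)
    if (max(abs(M2 - M)) < 1e-7) { M <- M2; break }
    M <- M2
  }
  nodes <- rownames(M)
  adj <- (M > eps) | (t(M) > eps)
  diag(adj) <- TRUE
  # components by repeated expansion
  comp <- seq_along(nodes)
  repeat {
    changed <- FALSE
    for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        tgt <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- tgt
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(nodes, comp), sort))
}

# canonical form for comparing partitions
canon_partition <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, `[`, character(1L), 1L))]
}

# random row-stochastic matrix
rand_stochastic <- function(n) {
  M <- matrix(stats::runif(n * n), n, n,
              dimnames = list(letters[1:n], letters[1:n]))
  M / rowSums(M)
}

# tiny helper: a sharply peaked PWM whose consensus is `word`
consensus_pwm <- function(id, word, strength = 100, pseudocount = NULL) {
  letters <- strsplit(word, "")[[1L]]
  counts <- matrix(1, length(letters), 4,
                   dimnames = list(NULL, ORACLE_BASES))
  for (i in seq_along(letters)) counts[i, letters[i]] <- strength
  pwm(id, counts, pseudocount = pseudocount)
}

# presence tables of the published hub clusters shipped with the package
cluster_table_path <- function(name) {
  system.file("extdata", "cluster_tables", paste0(name, ".tsv"),
              package = "tfbsnet", mustWork = TRUE)
}
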