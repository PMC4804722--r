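#' Random iid nucleotide sequence
#' @param n Length.
#' @param gc GC content (default 0.5).
#' @return Character scalar.
#' @keywords internal
.rand_seq <- function(n, gc = 0.5) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Shannon entropy (bits) of a probability vector; 0 * log(0) = 0.
.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# IC (uniform background, no pseudocount) of a single-peak position with
# major-letter probability p and the rest spread uniformly.
.peak_ic <- function(p) 2 - .entropy(c(p, rep((1 - p) / 3, 3)))

#' Generate random PWMs with a target information content
#'
#' Each matrix mixes sharply peaked ("hard") positions with, by default,
#' two two-letter "soft" positions, so that sites sampled from the matrix
#' vary while random sequence rarely reaches high scores. The per-position
#' peak probability is tuned (and the pseudocount shrinkage compensated
#' iteratively) so that the realized [information_content()] of each matrix
#' falls inside the target range. A target at the theoretical maximum
#' `2 * L` yields deterministic consensus count matrices.
#'
#' @param n Number of matrices.
#' @param length_range Length-2 range of motif lengths (sampled uniformly).
#' @param ic_range Length-2 target information-content range in bits.
#' @param seed Optional RNG seed (fixed seed gives identical matrices).
#' @param ids Optional character vector of matrix ids (default `S$MAT<k>`).
#' @param background Background passed to [pwm()].
#' @param n_soft Number of soft two-letter positions per matrix.
#' @param counts_total Per-position count total of the emitted matrices.
#' @param max_sim Maximum tolerated cross-score of one matrix's consensus
#'   under another; offending matrices are regenerated.
#' @return Named list of `pwm` objects.
#' @export
make_pwms <- function(n, length_range = c(8, 12), ic_range = c(10, 14),
                      seed = NULL, ids = NULL,
                      background = rep(0.25, 4), n_soft = 2L,
                      counts_total = 1000L, max_sim = 0.85) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ids)) ids <- sprintf("S$MAT%d", seq_len(n))
  stopifnot(length(ids) == n)
  if (ic_range[1L] > 2 * length_range[2L])
    stop("infeasible information-content target: IC cannot exceed 2 bits ",
         "per position")
  # two plausible letters; the remaining two are rare enough that any
  # non-top-2 letter costs more than the slack a high scan threshold leaves,
  # keeping near-consensus background matches out
  soft_profile <- c(0.50, 0.46, 0.02, 0.02)
  ic_soft <- 2 - .entropy(soft_profile)

  one <- function(id) {
    L <- if (length_range[1L] == length_range[2L]) length_range[1L]
         else sample(length_range[1L]:length_range[2L], 1L)
    target <- stats::runif(1L, ic_range[1L], ic_range[2L])
    if (target > 2 * L)
      stop("infeasible information-content target for motif length ", L)
    # soft positions only when the target leaves room for them: neither a
    # near-zero target nor one at the 2 bits/position ceiling can carry them
    ns <- if (target > n_soft * ic_soft + 0.2 && L > n_soft &&
              target < 2 * L - 0.5) n_soft else 0L
    soft_pos <- if (ns) sample(L, ns) else integer(0)
    cons <- sample(4L, L, replace = TRUE)
    second <- vapply(cons, function(c1) sample(setdiff(1:4, c1), 1L),
                     integer(1L))
    build <- function(eff) {
      hard_t <- (eff - ns * ic_soft) / (L - ns)
      hard_t <- min(max(hard_t, 0), 1.9999)
      f <- function(p) .peak_ic(p) - hard_t
      p_major <- if (hard_t >= 1.9999) 1 - 1e-9
                 else if (hard_t <= 1e-9) 0.25
                 else stats::uniroot(f, c(0.25, 1 - 1e-9), tol = 1e-9)$root
      probs <- matrix(0, L, 4L)
      for (i in seq_len(L)) {
        if (i %in% soft_pos) {
          probs[i, cons[i]] <- soft_profile[1L]
          probs[i, second[i]] <- soft_profile[2L]
          probs[i, setdiff(1:4, c(cons[i], second[i]))] <- soft_profile[3:4]
        } else {
          probs[i, ] <- (1 - p_major) / 3
          probs[i, cons[i]] <- p_major
        }
      }
      counts <- round(counts_total * probs)
      # generated matrices carry a small pseudocount (0.1% of the count
      # total): information content near the 2 bits/position ceiling stays
      # reachable, and zero-count letters still score finitely
      pwm(id, counts, pseudocount = 0.001 * counts_total,
          background = background)
    }
    eff <- target
    x <- build(eff)
    for (k in seq_len(15L)) {
      realized <- information_content(x)
      if (abs(realized - target) <= 0.3) break
      eff <- eff + (target - realized)
      if (eff >= 2 * L) { eff <- 2 * L; x <- build(eff); break }
      x <- build(eff)
    }
    x
  }

  pwms <- lapply(ids, one)
  names(pwms) <- ids
  # regenerate matrices whose consensus scores highly under another matrix
  cross <- function(a, b) {
    hits <- scan_pwm(b, "w", consensus_string(a), threshold = 0)
    if (nrow(hits)) max(hits$score) else 0
  }
  for (j in seq_len(n)) {
    tries <- 0L
    while (tries < 25L) {
      sims <- vapply(seq_len(n)[-j], function(i) {
        max(cross(pwms[[i]], pwms[[j]]), cross(pwms[[j]], pwms[[i]]))
      }, numeric(1L))
      if (!length(sims) || max(sims) <= max_sim) break
      pwms[[j]] <- one(ids[j])
      tries <- tries + 1L
    }
  }
  pwms
}

#' Sample a binding-site word from a PWM
#'
#' Letters are drawn per position from the PWM probabilities, with
#' rejection until the realized [score_site()] value reaches `floor`
#' (falling back to the consensus after `max_tries`), so planted sites
#' vary yet always clear scanner thresholds below the floor.
#'
#' @param x A `pwm` object.
#' @param floor Minimum realized normalized score (default 0.97).
#' @param max_tries Rejection-sampling cap.
#' @return List with `word` and `score`.
#' @export
sample_site <- function(x, floor = 0.97, max_tries = 200L) {
  p <- normalize_pwm(x)
  L <- nrow(p)
  model <- .score_model(x)
  span <- model$smax - model$smin
  score_of <- function(letter_idx) {
    s <- sum(model$logp[cbind(seq_len(L), letter_idx)])
    if (span < 1e-12) 1 else (s - model$smin) / span
  }
  for (k in seq_len(max_tries)) {
    letter_idx <- vapply(seq_len(L), function(i)
      sample.int(4L, 1L, prob = p[i, ]), integer(1L))
    sc <- score_of(letter_idx)
    if (sc >= floor)
      return(list(word = paste(DNA_BASES[letter_idx], collapse = ""),
                  score = sc))
  }
  word <- consensus_string(x)
  list(word = word, score = score_site(x, word, 1L, "+"))
}

#' Specification of a synthetic fixture
#'
#' Defines the study conditions the generator emulates: a six-timepoint
#' (days 0, 3, 8, 13, 29, 60) FPKM time course with three replicates,
#' per-stage unique differentially expressed genes, 1-kb promoters carrying
#' planted composite TFBS pairs organized as hub-and-spoke groups (dense
#' intra-hub pair frequencies, sparse cross-hub noise pairs), and TF gene
#' expression series crossing the FPKM-10 threshold in designed stage
#' patterns (including an all-stages synergistic and an early/late
#' antagonistic pair).
#'
#' @param seed RNG seed; a fixed seed gives byte-identical outputs.
#' @param n_genes Total genes (default 300).
#' @param promoter_length Promoter window length in nt (default 1000).
#' @param n_hubs Number of planted hub TFBSs (default 4).
#' @param partners_per_hub Length-2 range of partners per hub (default
#'   4-6); the first three partners of every hub are present at all stages
#'   so per-stage hub clusters keep at least three interactions.
#' @param pair_frequency Promoters per stage carrying each present
#'   hub-partner pair (default 6).
#' @param n_noise_pairs,noise_frequency Weak cross-hub pairs and their
#'   per-stage promoter count (defaults 3 and 1).
#' @param gc Background GC content.
#' @param n_de_per_stage Unique DE genes planted per stage (default 40).
#' @param n_multi_de Decoy genes differentially expressed in two stages
#'   (default 6; must appear in no unique set).
#' @param n_overlap_decoys Pairs of genes with mutually overlapping
#'   promoters (default 2; dropped by the overlap filter).
#' @param n_noncoding Non-protein-coding genes with DE-like profiles
#'   (default 4; excluded by the biotype filter).
#' @param effect_size Log2 fold change of planted DE steps (default 4).
#' @param noise_sd Lognormal (log2 scale) expression noise sd (default
#'   0.25).
#' @param replicates Replicates per timepoint (default 3).
#' @param site_score_floor Minimum realized score of planted sites
#'   (default 0.97, above the default scan threshold).
#' @param scan_threshold Scanner/library score threshold (default 0.95).
#' @param min_gap,max_gap Composite gap window in nt (defaults 5 and 30).
#' @param pwm_length,pwm_ic Length and information-content ranges of the
#'   synthetic PWM library (defaults 12 nt and 16-20 bits; sharply peaked
#'   matrices keep the false-composite rate negligible at the default
#'   threshold).
#' @param fpkm_threshold Expression threshold (default 10).
#' @param timepoints Measurement days (default 0, 3, 8, 13, 29, 60).
#' @return List of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 300L, promoter_length = 1000L,
                         n_hubs = 4L, partners_per_hub = c(4L, 6L),
                         pair_frequency = 6L, n_noise_pairs = 3L,
                         noise_frequency = 1L, gc = 0.5,
                         n_de_per_stage = 40L, n_multi_de = 6L,
                         n_overlap_decoys = 2L, n_noncoding = 4L,
                         effect_size = 4, noise_sd = 0.25, replicates = 3L,
                         site_score_floor = 0.97, scan_threshold = 0.95,
                         min_gap = 5L, max_gap = 30L,
                         pwm_length = c(12L, 12L), pwm_ic = c(16, 20),
                         fpkm_threshold = 10,
                         timepoints = c(0, 3, 8, 13, 29, 60)) {
  spec <- as.list(environment())
  if (spec$pair_frequency < 1 || spec$noise_frequency < 1)
    stop("planted frequencies must be >= 1")
  if (spec$effect_size <= 0) stop("effect size must be positive")
  if (length(spec$timepoints) != 6L || is.unsorted(spec$timepoints,
                                                  strictly = TRUE))
    stop("'timepoints' must be 6 strictly increasing days")
  if (spec$n_de_per_stage < spec$pair_frequency)
    stop("need at least 'pair_frequency' DE genes per stage to plant into")
  structure(spec, class = "fixture_spec")
}

# Designed presence pattern for partner j of hub i (5 stages).
.partner_pattern <- function(i, j) {
  if (j <= 3L) rep(TRUE, 5L)
  else if (j == 4L) c(TRUE, TRUE, FALSE, TRUE, TRUE)
  else if (j == 5L) replace(rep(FALSE, 5L), ((i - 1L) %% 5L) + 1L, TRUE)
  else {
    repeat {
      v <- stats::runif(5L) < 0.6
      if (any(v)) return(v)
    }
  }
}

#' Generate a complete synthetic fixture
#'
#' Produces, under a fixed seed, every input the pipeline consumes --
#' genome FASTA, TSS annotations, PWM library, composite-pair library,
#' FPKM expression matrix, TF gene mapping, per-stage promoter sets --
#' together with a `ground_truth` record (planted occurrences, per-stage
#' pair weights, unique DE gene sets, hub memberships and presence
#' patterns, TF expressed-timepoint sets, designed annotation modes) so
#' that every pipeline stage has an oracle.
#'
#' @param spec A [fixture_spec()].
#' @return List of class `"tfbs_fixture"` with elements `spec`, `pwms`,
#'   `library`, `genome`, `annotations`, `expression`, `tf_mapping`,
#'   `promoters` (per-stage named sequence lists), `ground_truth`.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  stages <- stage_definitions()
  n_stage <- nrow(stages)

  ## --- PWM library -------------------------------------------------------
  n_partners <- if (spec$partners_per_hub[1L] == spec$partners_per_hub[2L])
    rep(spec$partners_per_hub[1L], spec$n_hubs)
  else sample(spec$partners_per_hub[1L]:spec$partners_per_hub[2L],
              spec$n_hubs, replace = TRUE)
  hub_ids <- sprintf("S$HUB%d", seq_len(spec$n_hubs))
  partner_ids <- lapply(seq_len(spec$n_hubs), function(i)
    sprintf("S$H%dP%d", i, seq_len(n_partners[i])))
  all_ids <- c(hub_ids, unlist(partner_ids))
  pwms <- make_pwms(length(all_ids), length_range = spec$pwm_length,
                    ic_range = spec$pwm_ic, ids = all_ids)

  ## --- composite library + presence design ------------------------------
  lib_rows <- list()
  presence <- list()  # pair_id -> logical(5)
  hubs_truth <- list()
  orientations <- c("any", "same", "opposite")
  for (i in seq_len(spec$n_hubs)) {
    pres_mat <- matrix(FALSE, n_partners[i], n_stage,
                       dimnames = list(partner_ids[[i]], stages$stage))
    for (j in seq_len(n_partners[i])) {
      pid <- sprintf("P_H%dJ%d", i, j)
      pat <- .partner_pattern(i, j)
      pres_mat[j, ] <- pat
      presence[[pid]] <- pat
      lib_rows[[pid]] <- composite_model(
        pid, hub_ids[i], partner_ids[[i]][j],
        threshold_a = spec$scan_threshold, threshold_b = spec$scan_threshold,
        min_gap = spec$min_gap, max_gap = spec$max_gap,
        orientation = orientations[(j - 1L) %% 3L + 1L])
    }
    hubs_truth[[hub_ids[i]]] <- list(partners = partner_ids[[i]],
                                     presence = pres_mat)
  }
  for (k in seq_len(spec$n_noise_pairs)) {
    h1 <- (k - 1L) %% spec$n_hubs + 1L
    h2 <- k %% spec$n_hubs + 1L
    # partner 2 of each hub: all-stage partners, but never the designated
    # synergistic partner 1 (whose TF expression design must stay intact)
    pid <- sprintf("P_NOISE%d", k)
    lib_rows[[pid]] <- composite_model(
      pid, partner_ids[[h1]][2L], partner_ids[[h2]][2L],
      threshold_a = spec$scan_threshold, threshold_b = spec$scan_threshold,
      min_gap = spec$min_gap, max_gap = spec$max_gap, orientation = "any")
    presence[[pid]] <- if (k == 1L) c(TRUE, FALSE, FALSE, FALSE, TRUE)
                       else rep(TRUE, n_stage)
  }
  library <- do.call(rbind, lib_rows)
  rownames(library) <- NULL

  ## --- gene roles --------------------------------------------------------
  tf_genes <- sub("^S\\$", "TFG_", all_ids)
  names(tf_genes) <- all_ids
  extra_tf_gene <- "TFG_HUB2B"  # second, silent gene mapped to hub 2
  de_genes <- lapply(seq_len(n_stage), function(s)
    sprintf("GENE_S%d_%02d", s, seq_len(spec$n_de_per_stage)))
  names(de_genes) <- stages$stage
  multi_genes <- sprintf("GENE_MULTI_%02d", seq_len(spec$n_multi_de))
  decoy_genes <- sprintf("GENE_OVL_%02d", seq_len(2L * spec$n_overlap_decoys))
  nc_genes <- sprintf("LINC_%02d", seq_len(spec$n_noncoding))
  n_used <- length(unlist(de_genes)) + length(multi_genes) +
    length(decoy_genes) + length(nc_genes)
  n_bg <- spec$n_genes - n_used - length(tf_genes) - 1L
  if (n_bg < 0)
    stop("'n_genes' too small for the requested DE/decoy/TF gene layout")
  bg_genes <- sprintf("GENE_BG_%03d", seq_len(n_bg))
  genes <- c(unlist(de_genes, use.names = FALSE), multi_genes, decoy_genes,
             nc_genes, unname(tf_genes), extra_tf_gene, bg_genes)

  ## --- genome layout and promoter sequences ------------------------------
  PL <- spec$promoter_length
  block <- PL + 600L
  prom_seq <- stats::setNames(
    vapply(genes, function(g) .rand_seq(PL, spec$gc), character(1L)),
    genes)

  ## --- plant composite sites into per-stage DE promoters -----------------
  cursor <- stats::setNames(rep(20L, length(genes)), genes)
  occ_rows <- list()
  weight_rows <- list()
  plant_one <- function(model, gene, stage_name) {
    pa <- pwms[[model$pwm_a]]; pb <- pwms[[model$pwm_b]]
    wa <- sample_site(pa, spec$site_score_floor)
    wb <- sample_site(pb, spec$site_score_floor)
    gap <- sample(spec$min_gap:spec$max_gap, 1L)
    strands <- switch(model$orientation,
      same = rep(sample(c("+", "-"), 1L), 2L),
      opposite = sample(c("+", "-"), 2L, replace = FALSE),
      any = sample(c("+", "-"), 2L, replace = TRUE))
    a_first <- isTRUE(model$ordered) || stats::runif(1L) < 0.5
    la <- pwm_width(pa); lb <- pwm_width(pb)
    len1 <- if (a_first) la else lb
    len2 <- if (a_first) lb else la
    pos1 <- cursor[[gene]] + 1L
    pos2 <- pos1 + len1 + gap
    if (pos2 + len2 - 1L > PL - 10L)
      stop(sprintf("over-constrained planting: promoter of '%s' is full",
                   gene))
    # spacing between plantings must exceed the gap window, so sites from
    # different plantings can never assemble into a spurious library pair
    cursor[[gene]] <<- pos2 + len2 - 1L + spec$max_gap + 10L
    put <- function(word, strand, pos) {
      ins <- if (strand == "+") word else revcomp(word)
      substr(prom_seq[[gene]], pos, pos + nchar(word) - 1L) <<- ins
    }
    if (a_first) {
      put(wa$word, strands[1L], pos1); put(wb$word, strands[2L], pos2)
      sa <- pos1; sb <- pos2
    } else {
      put(wb$word, strands[2L], pos1); put(wa$word, strands[1L], pos2)
      sb <- pos1; sa <- pos2
    }
    occ_rows[[length(occ_rows) + 1L]] <<- data.frame(
      stage = stage_name, pair_id = model$pair_id, gene = gene,
      start_a = sa, end_a = sa + la - 1L, strand_a = strands[1L],
      start_b = sb, end_b = sb + lb - 1L, strand_b = strands[2L],
      gap = gap, score_a = wa$score, score_b = wb$score,
      stringsAsFactors = FALSE)
  }
  for (s in seq_len(n_stage)) {
    stage_name <- stages$stage[s]
    proms <- de_genes[[s]]
    slot <- 0L
    for (pid in library$pair_id) {
      if (!presence[[pid]][s]) next
      model <- library[library$pair_id == pid, , drop = FALSE]
      w <- if (grepl("^P_NOISE", pid)) spec$noise_frequency
           else spec$pair_frequency
      for (r in seq_len(w)) {
        gene <- proms[(slot %% length(proms)) + 1L]
        slot <- slot + 1L
        plant_one(model, gene, stage_name)
      }
      weight_rows[[length(weight_rows) + 1L]] <- data.frame(
        stage = stage_name, pair_id = pid, weight = w,
        stringsAsFactors = FALSE)
    }
  }
  occurrences <- do.call(rbind, occ_rows)
  pair_weights <- do.call(rbind, weight_rows)

  ## --- assemble genome and annotations -----------------------------------
  ann_rows <- list()
  chrom_parts <- list()
  offset <- 0L  # 0-based start of the next block
  add_gene <- function(gene, strand, biotype, is_tf) {
    blk <- .rand_seq(block, spec$gc)
    if (strand == "+") {
      tss0 <- offset + PL + 100L
      substr(blk, 101L, 100L + PL) <- prom_seq[[gene]]
    } else {
      tss0 <- offset + 100L
      substr(blk, 101L, 100L + PL) <- revcomp(prom_seq[[gene]])
    }
    chrom_parts[[length(chrom_parts) + 1L]] <<- blk
    ann_rows[[length(ann_rows) + 1L]] <<- data.frame(
      gene = gene, chrom = "chr1", tss = tss0, strand = strand,
      biotype = biotype, is_tf = is_tf, stringsAsFactors = FALSE)
    offset <<- offset + block
  }
  strand_cycle <- c("+", "-")
  si <- 0L
  for (g in setdiff(genes, decoy_genes)) {
    si <- si + 1L
    add_gene(g, strand_cycle[(si %% 2L) + 1L],
             biotype = if (g %in% nc_genes) "lincRNA" else "protein_coding",
             is_tf = g %in% c(tf_genes, extra_tf_gene))
  }
  # overlapping decoy promoter pairs: two plus-strand genes 300 nt apart
  for (d in seq_len(spec$n_overlap_decoys)) {
    g1 <- decoy_genes[2L * d - 1L]; g2 <- decoy_genes[2L * d]
    blk <- .rand_seq(block + 300L, spec$gc)
    tss1 <- offset + PL + 100L
    tss2 <- tss1 + 300L
    substr(blk, 101L, 100L + PL) <- prom_seq[[g1]]
    chrom_parts[[length(chrom_parts) + 1L]] <- blk
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      gene = c(g1, g2), chrom = "chr1", tss = c(tss1, tss2),
      strand = "+", biotype = "protein_coding", is_tf = FALSE,
      stringsAsFactors = FALSE)
    offset <- offset + block + 300L
  }
  genome <- c(chr1 = paste(unlist(chrom_parts), collapse = ""))
  annotations <- do.call(rbind, ann_rows)
  rownames(annotations) <- NULL

  ## --- expression matrix -------------------------------------------------
  tp <- spec$timepoints
  mu <- matrix(NA_real_, length(genes), 6L,
               dimnames = list(genes, tp))
  flat <- function() rep(stats::rlnorm(1L, log(10), 1), 6L)
  step_profile <- function(base, step_at, lfc) {
    prof <- rep(base, 6L)
    prof[step_at:6L] <- base * 2^lfc
    prof
  }
  for (g in bg_genes) mu[g, ] <- flat()
  for (g in decoy_genes) mu[g, ] <- flat()
  for (s in seq_len(n_stage)) {
    for (g in de_genes[[s]]) {
      base <- stats::rlnorm(1L, log(15), 0.5)
      lfc <- sample(c(-1, 1), 1L) * spec$effect_size
      mu[g, ] <- step_profile(base, s + 1L, lfc)
    }
  }
  for (k in seq_along(multi_genes)) {
    ss <- sort(sample(n_stage, 2L))
    base <- stats::rlnorm(1L, log(15), 0.5)
    prof <- rep(base, 6L)
    prof[(ss[1L] + 1L):6L] <- base * 2^spec$effect_size
    prof[(ss[2L] + 1L):6L] <- base  # step back down at the second stage
    mu[multi_genes[k], ] <- prof
  }
  for (k in seq_along(nc_genes)) {
    s <- (k - 1L) %% n_stage + 1L
    base <- stats::rlnorm(1L, log(15), 0.5)
    mu[nc_genes[k], ] <- step_profile(base, s + 1L, spec$effect_size)
  }
  ## designed TF expression patterns
  hi <- 3 * spec$fpkm_threshold
  lo <- 0.2 * spec$fpkm_threshold
  tf_expressed <- list()
  anti_sides <- c(library$pwm_a[library$pair_id == "P_NOISE1"],
                  library$pwm_b[library$pair_id == "P_NOISE1"])
  for (id in all_ids) {
    expressed <- if (id %in% hub_ids) rep(TRUE, 6L)
      else if (id == anti_sides[1L]) tp %in% tp[1:2]
      else if (id == anti_sides[2L]) tp %in% tp[5:6]
      else if (grepl("P1$", id)) rep(TRUE, 6L)  # synergistic partners
      else {
        repeat {
          v <- stats::runif(6L) < 0.7
          if (any(v)) break
        }
        v
      }
    mu[tf_genes[[id]], ] <- ifelse(expressed, hi, lo)
    tf_expressed[[id]] <- tp[expressed]
  }
  mu[extra_tf_gene, ] <- rep(lo, 6L)  # silent second gene of hub 2
  expr <- matrix(NA_real_, length(genes), 6L * spec$replicates,
                 dimnames = list(genes, paste0(
                   rep(sprintf("d%g", tp), each = spec$replicates),
                   "_r", rep(seq_len(spec$replicates), 6L))))
  for (t in seq_len(6L)) {
    for (r in seq_len(spec$replicates)) {
      expr[, (t - 1L) * spec$replicates + r] <-
        mu[, t] * 2^stats::rnorm(length(genes), 0, spec$noise_sd)
    }
  }

  tf_mapping <- data.frame(
    pwm_id = c(all_ids, "S$HUB2"),
    gene_id = c(unname(tf_genes), extra_tf_gene),
    stringsAsFactors = FALSE)

  ground_truth <- list(
    deg_sets = lapply(de_genes, sort),
    multi_de_genes = multi_genes,
    pair_weights = pair_weights,
    occurrences = occurrences,
    hubs = hubs_truth,
    pair_presence = presence,
    tf_expressed = tf_expressed,
    designed_modes = list(
      synergistic = list(pair_id = "P_H1J1",
                         sides = c("S$HUB1", partner_ids[[1L]][1L])),
      antagonistic = list(pair_id = "P_NOISE1", sides = anti_sides))
  )

  promoters <- lapply(seq_len(n_stage), function(s)
    prom_seq[de_genes[[s]]])
  names(promoters) <- stages$stage

  structure(list(spec = spec, pwms = pwms, library = library,
                 genome = genome, annotations = annotations,
                 expression = expr, tf_mapping = tf_mapping,
                 promoters = promoters, ground_truth = ground_truth),
            class = "tfbs_fixture")
}

#' Write a fixture to disk in the formats the pipeline consumes
#'
#' Emits `genome.fasta`, `annotations.tsv` (BED-like, 0-based),
#' `pwms.transfac`, `library.tsv`, `expression.tsv`, `tf_mapping.tsv`,
#' `promoters_<stage>.fasta`, and `ground_truth.json`. Output is
#' byte-identical for a fixed fixture seed.
#'
#' @param fixture A `tfbs_fixture` (see [make_fixture()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(fixture$genome), p("genome.fasta"))
  write_annotations(fixture$annotations, p("annotations.tsv"))
  write_transfac(fixture$pwms, p("pwms.transfac"))
  write_composite_library(fixture$library, p("library.tsv"))
  write_expression(fixture$expression, p("expression.tsv"))
  write_tf_mapping(fixture$tf_mapping, p("tf_mapping.tsv"))
  for (s in names(fixture$promoters)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(fixture$promoters[[s]])),
      p(sprintf("promoters_%s.fasta", s)))
  }
  gt <- fixture$ground_truth
  json <- list(
    deg_sets = gt$deg_sets,
    multi_de_genes = gt$multi_de_genes,
    pair_weights = gt$pair_weights,
    hubs = lapply(gt$hubs, function(h)
      list(partners = h$partners,
           presence = as.data.frame(h$presence))),
    tf_expressed = gt$tf_expressed,
    designed_modes = gt$designed_modes)
  jsonlite::write_json(json, p("ground_truth.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}
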