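stage_names <- stage_definitions()$stage

test_that("find_hub picks the maximal weighted-degree node", {
  lib <- data.frame(pair_id = paste0("e", 1:3), pwm_a = "c",
                    pwm_b = c("s1", "s2", "s3"))
  star <- build_network(data.frame(pair_id = paste0("e", 1:3), weight = 1),
                        lib)
  expect_equal(find_hub(c("c", "s1", "s2", "s3"), star), "c")
  # two-node cluster: equal degrees, lexicographic tie-break
  duo <- build_network(data.frame(pair_id = "e1", weight = 2),
                       data.frame(pair_id = "e1", pwm_a = "zz",
                                  pwm_b = "aa"))
  expect_equal(find_hub(c("zz", "aa"), duo), "aa")
  # weighted degrees (7, 5, 5, 3) by hand: a-b 4, a-c 3, b-d 1, c-d 2
  lib2 <- data.frame(pair_id = paste0("e", 1:4),
                     pwm_a = c("a", "a", "b", "c"),
                     pwm_b = c("b", "c", "d", "d"))
  net2 <- build_network(data.frame(pair_id = paste0("e", 1:4),
                                   weight = c(4, 3, 1, 2)), lib2)
  expect_equal(find_hub(net2$nodes, net2), "a")
  expect_error(find_hub(character(0), net2), "empty")
})

test_that("reportable clusters need >= 3 induced edges", {
  lib <- data.frame(pair_id = paste0("e", 1:5),
                    pwm_a = c("a", "b", "c", "d", "x"),
                    pwm_b = c("b", "c", "a", "a", "y"))
  net <- build_network(data.frame(pair_id = paste0("e", 1:5), weight = 1),
                       lib)
  # triangle kept, 4-node star kept (3 edges), single edge dropped,
  # singleton dropped
  out <- filter_reportable_clusters(
    list(c("a", "b", "c"), c("x", "y"), "d"), net)
  expect_equal(out, list(c("a", "b", "c")))
  star_lib <- data.frame(pair_id = paste0("s", 1:3), pwm_a = "h",
                         pwm_b = c("p", "q", "r"))
  star <- build_network(data.frame(pair_id = paste0("s", 1:3), weight = 1),
                        star_lib)
  expect_equal(filter_reportable_clusters(list(c("h", "p", "q", "r")),
                                          star),
               list(c("h", "p", "q", "r")))
})

test_that("temporal classification reproduces the published patterns", {
  expect_equal(classify_temporal(rep(TRUE, 5)), "all_stages")
  expect_equal(classify_temporal(c(TRUE, TRUE, FALSE, TRUE, TRUE)),
               "interrupted")
  expect_equal(classify_temporal(c(TRUE, FALSE, FALSE, FALSE, FALSE)),
               "stage_specific")
  expect_equal(classify_temporal(c(FALSE, TRUE, TRUE, FALSE, FALSE)),
               "other")
  expect_error(classify_temporal(rep(FALSE, 5)), "TRUE")
})

test_that("temporal classification matches brute force on all 31 vectors", {
  for (code in 1:31) {
    v <- as.logical(bitwAnd(code, 2^(0:4)))
    expect_equal(classify_temporal(v), bf_classify(v), info = code)
  }
})

test_that("hub tracking reconstructs a known cluster across stages", {
  # hub H with partners p, q; p adjacent in stages 1 and 3, q in stage 1
  mknet <- function(pairs, w = 5) {
    lib <- data.frame(pair_id = paste0("e", seq_len(nrow(pairs))),
                      pwm_a = pairs[, 1], pwm_b = pairs[, 2])
    build_network(data.frame(pair_id = lib$pair_id, weight = w), lib)
  }
  full <- mknet(rbind(c("H", "p"), c("H", "q"), c("H", "r")))
  only_pr <- mknet(rbind(c("H", "p"), c("H", "r"), c("H", "s")))
  nets <- list(full, only_pr, full, full, full)
  names(nets) <- stage_names
  cls <- lapply(nets, function(n) list(n$nodes))
  tab <- track_hub_across_stages(cls, nets, "H")
  expect_s3_class(tab, "stage_presence")
  expect_setequal(rownames(tab$presence), c("p", "q", "r", "s"))
  expect_equal(unname(tab$presence["q", ]), c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(unname(tab$presence["s", ]), c(FALSE, TRUE, FALSE, FALSE,
                                              FALSE))
  expect_error(track_hub_across_stages(cls, nets, "nosuch"), "never")
})

test_that("the published NFAT cluster table is reconstructed from
           per-stage hub-adjacent edge lists", {
  nfat <- read_presence_table(cluster_table_path("nfat"))
  hub <- nfat$hub
  partners <- rownames(nfat$presence)
  nets <- list(); cls <- list()
  for (s in seq_len(5)) {
    present <- partners[nfat$presence[, s]]
    lib <- data.frame(pair_id = paste0("e", seq_along(present)),
                      pwm_a = hub, pwm_b = present)
    nets[[s]] <- build_network(data.frame(pair_id = lib$pair_id,
                                          weight = 3), lib)
    cls[[s]] <- list(nets[[s]]$nodes)
  }
  names(nets) <- names(cls) <- colnames(nfat$presence)
  rebuilt <- track_hub_across_stages(cls, nets, hub)
  ord <- order(rownames(nfat$presence))
  expect_equal(rebuilt$presence[rownames(nfat$presence)[ord], ],
               nfat$presence[ord, ])
  expect_true(rebuilt$presence["V$AP1_C", "day0_3"])
  expect_false(hub %in% rownames(rebuilt$presence))
})

test_that("pair counting matches the published cluster tables", {
  nfat <- read_presence_table(cluster_table_path("nfat"))
  smad <- read_presence_table(cluster_table_path("smad"))
  hmgiy <- read_presence_table(cluster_table_path("hmgiy"))
  expect_equal(count_union_pairs(nfat), 6)
  expect_equal(count_union_pairs(smad), 3)
  expect_equal(count_union_pairs(hmgiy), 5)
  expect_equal(count_all_stage_pairs(nfat), 3)
  # a table without all-true rows counts zero
  t0 <- stage_presence_table("h", matrix(c(TRUE, rep(FALSE, 4)), 1,
                                         dimnames = list("p", NULL)))
  expect_equal(count_all_stage_pairs(t0), 0)
  expect_lte(count_all_stage_pairs(nfat), count_union_pairs(nfat))
})

test_that("expression annotation thresholds and modes behave", {
  tp <- c(0, 3, 8, 13, 29, 60)
  mk <- function(profiles) {
    cols <- paste0(rep(sprintf("d%g", tp), each = 2), "_r", 1:2)
    m <- matrix(NA_real_, length(profiles), 12,
                dimnames = list(names(profiles), cols))
    for (g in names(profiles)) m[g, ] <- rep(profiles[[g]], each = 2)
    m
  }
  mapping <- data.frame(pwm_id = c("A", "B", "C", "C"),
                        gene_id = c("ga", "gb", "gc1", "gc2"))
  # both sides >= 10 at all timepoints: synergistic
  expr <- mk(list(ga = rep(30, 6), gb = rep(20, 6),
                  gc1 = rep(2, 6), gc2 = rep(2, 6)))
  ann <- annotate_expression("A", "B", rep(TRUE, 5), mapping, expr)
  expect_equal(ann$mode, "synergistic_candidate")
  expect_equal(ann$expressed_a, tp)
  # A early only, B late only, pair present in stages 1 and 5
  expr2 <- mk(list(ga = c(30, 30, 2, 2, 2, 2), gb = c(2, 2, 2, 2, 30, 30),
                   gc1 = rep(2, 6), gc2 = rep(2, 6)))
  ann2 <- annotate_expression("A", "B", c(TRUE, FALSE, FALSE, FALSE, TRUE),
                              mapping, expr2)
  expect_equal(ann2$mode, "antagonistic_candidate")
  # FPKM exactly at the threshold counts as expressed (inclusive)
  expr3 <- mk(list(ga = rep(10, 6), gb = rep(10, 6), gc1 = rep(2, 6),
                   gc2 = rep(2, 6)))
  ann3 <- annotate_expression("A", "B", rep(TRUE, 5), mapping, expr3)
  expect_equal(ann3$expressed_a, tp)
  expect_equal(ann3$mode, "synergistic_candidate")
  # the max over a side's mapped genes drives the expressed set
  expr4 <- mk(list(ga = rep(30, 6), gb = rep(30, 6),
                   gc1 = c(30, 2, 2, 2, 2, 2), gc2 = c(2, 2, 2, 2, 2, 30)))
  ann4 <- annotate_expression("A", "C", rep(TRUE, 5), mapping, expr4)
  expect_equal(ann4$expressed_b, c(0, 60))
  # unmapped side errors with the PWM id
  expect_error(annotate_expression("A", "Z", rep(TRUE, 5), mapping, expr),
               "'Z'")
})

test_that("raising the threshold never promotes a pair to synergistic", {
  tp <- c(0, 3, 8, 13, 29, 60)
  set.seed(77)
  mapping <- data.frame(pwm_id = c("A", "B"), gene_id = c("ga", "gb"))
  rank_mode <- c(indeterminate = 1, antagonistic_candidate = 1,
                 synergistic_candidate = 2)
  for (k in 1:10) {
    prof <- list(ga = runif(6, 0, 40), gb = runif(6, 0, 40))
    cols <- paste0(rep(sprintf("d%g", tp), each = 2), "_r", 1:2)
    expr <- matrix(rep(unlist(prof), each = 2), 2, 12, byrow = TRUE,
                   dimnames = list(c("ga", "gb"), cols))
    presence <- as.logical(rbinom(5, 1, 0.6))
    if (!any(presence)) presence[1] <- TRUE
    modes <- vapply(c(5, 15, 30), function(thr) {
      tryCatch(annotate_expression("A", "B", presence, mapping, expr,
                                   threshold = thr)$mode,
               error = function(e) "indeterminate")
    }, character(1))
    expect_true(all(diff(rank_mode[modes]) <= 0))
  }
})

test_that("hourglass profile locates interior minima", {
  hg <- hourglass_profile(c(63, 82, 24, 52, 76))
  expect_equal(hg$argmin_stage, 3)
  expect_true(hg$interior_min)
  mono <- hourglass_profile(c(1, 2, 3, 4, 5))
  expect_equal(mono$argmin_stage, 1)
  expect_false(mono$interior_min)
  degs <- hourglass_profile(c(429, 1233, 36, 205, 964))
  expect_equal(degs$argmin_stage, 3)
  # first occurrence wins on ties
  expect_equal(hourglass_profile(c(5, 2, 2, 3, 4))$argmin_stage, 2)
  expect_error(hourglass_profile(c(1, 2, 3)), "5")
})

test_that("presence tables round trip through the +/- TSV format", {
  tab <- read_presence_table(cluster_table_path("ap1"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_presence_table(tab, path)
  back <- read_presence_table(path)
  expect_equal(back$presence, tab$presence)
  expect_equal(back$hub, "V$AP1_01")
})
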