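# small helper: build a network from an edge list matrix
edge_net <- function(a, b, w) {
  lib <- data.frame(pair_id = sprintf("e%d", seq_along(a)), pwm_a = a,
                    pwm_b = b, stringsAsFactors = FALSE)
  freq <- data.frame(pair_id = lib$pair_id, weight = w,
                     stringsAsFactors = FALSE)
  build_network(freq, lib)
}

test_that("build_network maps pairs to weighted undirected edges", {
  net <- edge_net(c("a", "a"), c("b", "c"), c(3, 1))
  expect_equal(net$nodes, c("a", "b", "c"))
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$weight[net$edges$node_b == "b"], 3)
  # empty table -> empty network
  empty <- edge_net(character(0), character(0), numeric(0))
  expect_equal(length(empty$nodes), 0)
  # two pairs on the same unordered node pair: weights summed
  dup <- edge_net(c("a", "b"), c("b", "a"), c(2, 5))
  expect_equal(dup$edges$weight, 7)
  # homotypic pairs are dropped with a warning
  expect_warning(h <- edge_net(c("a", "a"), c("a", "b"), c(1, 1)),
                 "homotypic")
  expect_equal(h$edges$node_a, "a")
  # unmapped pair id errors
  lib <- data.frame(pair_id = "p1", pwm_a = "a", pwm_b = "b")
  expect_error(build_network(data.frame(pair_id = "zz", weight = 1), lib),
               "unmapped")
})

test_that("to_markov adds self-loops and row-normalizes", {
  net <- edge_net("a", "b", 5)
  M <- to_markov(net, mcl_params(self_loop = 5))
  expect_equal(unname(M), matrix(0.5, 2, 2))
  # default self-loop = max incident weight gives the same here
  M2 <- to_markov(net)
  expect_equal(M, M2)
  # star a-b, a-c with unit weights and unit self-loops
  star <- edge_net(c("a", "a"), c("b", "c"), c(1, 1))
  M3 <- to_markov(star, mcl_params(self_loop = 1))
  expect_equal(unname(M3["a", ]), c(1/3, 1/3, 1/3))
  expect_equal(rowSums(M3), c(a = 1, b = 1, c = 1))
  # a lone node gets M = [1] via its self-loop
  lone <- structure(list(nodes = "x",
                         edges = data.frame(node_a = character(0),
                                            node_b = character(0),
                                            weight = numeric(0))),
                    class = "tfbs_network")
  expect_equal(unname(to_markov(lone)), matrix(1, 1, 1))
})

test_that("expand and inflate match brute-force matrix arithmetic", {
  expect_equal(mcl_expand(diag(4)), diag(4))
  flat <- matrix(0.5, 2, 2)
  expect_equal(mcl_expand(flat), flat)
  # inflate worked examples
  expect_equal(unname(mcl_inflate(matrix(c(1, 0), 1), 3)),
               matrix(c(1, 0), 1))
  expect_equal(unname(mcl_inflate(matrix(c(0.5, 0.5), 1), 2)),
               matrix(c(0.5, 0.5), 1))
  expect_equal(unname(mcl_inflate(matrix(c(0.8, 0.2), 1), 2)),
               matrix(c(0.64, 0.04) / 0.68, 1))
  set.seed(41)
  for (k in 1:10) {
    M <- rand_stochastic(4)
    expect_equal(mcl_expand(M), bf_matmul(M, M), tolerance = 1e-9)
    r <- runif(1, 1.2, 3)
    expect_equal(mcl_inflate(M, r), bf_inflate(M, r), tolerance = 1e-9)
    # row stochasticity is preserved by both operations
    expect_equal(rowSums(mcl_expand(M)), rep(1, 4), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(rowSums(mcl_inflate(M, r)), rep(1, 4), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_error(mcl_inflate(matrix(c(1e-12, 1e-12), 1), 2), "all-zero")
})

test_that("run_mcl separates disconnected components and pairs", {
  tri2 <- edge_net(c("a", "b", "c", "d", "e", "f"),
                   c("b", "c", "a", "e", "f", "d"), rep(1, 6))
  res <- run_mcl(to_markov(tri2))
  expect_equal(canon_partition(res$clusters),
               list(c("a", "b", "c"), c("d", "e", "f")))
  # single edge graph: one cluster {a, b}
  res2 <- run_mcl(to_markov(edge_net("a", "b", 5)))
  expect_equal(res2$clusters, list(c("a", "b")))
  expect_true(res2$converged)
  expect_error(run_mcl(matrix(c(NaN, 1, 1, 0), 2)), "non-finite")
})

test_that("a weak bridge between two cliques splits at the bridge", {
  a <- c("a1", "a1", "a1", "a2", "a2", "a3")
  b <- c("a2", "a3", "a4", "a3", "a4", "a4")
  net <- edge_net(c(a, sub("a", "b", a), "a1"),
                  c(b, sub("a", "b", b), "b1"),
                  c(rep(5, 12), 0.1))
  M <- to_markov(net)
  res <- run_mcl(M)
  expect_equal(canon_partition(res$clusters),
               list(paste0("a", 1:4), paste0("b", 1:4)))
  # independent flow-simulation oracle agrees
  oracle <- bf_mcl(M, r = 2)
  expect_equal(canon_partition(res$clusters), canon_partition(oracle))
})

test_that("clustering is invariant under node permutation", {
  set.seed(51)
  a <- c("n1", "n1", "n2", "n4", "n4", "n5")
  b <- c("n2", "n3", "n3", "n5", "n6", "n6")
  w <- c(4, 3, 5, 4, 2, 6)
  net <- edge_net(a, b, w)
  res1 <- run_mcl(to_markov(net))
  perm <- c(n1 = "m3", n2 = "m6", n3 = "m1", n4 = "m5", n5 = "m2",
            n6 = "m4")
  net2 <- edge_net(unname(perm[a]), unname(perm[b]), w)
  res2 <- run_mcl(to_markov(net2))
  relabeled <- canon_partition(lapply(res1$clusters,
                                      function(cl) unname(perm[cl])))
  expect_equal(relabeled, canon_partition(res2$clusters))
})

test_that("disconnected components never share a cluster", {
  set.seed(61)
  for (k in 1:5) {
    # two random connected components built as spanning trees plus extras
    make_comp <- function(prefix, n) {
      nodes <- paste0(prefix, 1:n)
      a <- nodes[1:(n - 1)]; b <- nodes[2:n]
      extra <- sample(n, 2)
      list(a = c(a, nodes[extra[1]]), b = c(b, nodes[extra[2]]))
    }
    c1 <- make_comp("x", sample(3:5, 1))
    c2 <- make_comp("y", sample(3:5, 1))
    keep <- c1$a != c1$b
    keep2 <- c2$a != c2$b
    net <- edge_net(c(c1$a[keep], c2$a[keep2]),
                    c(c1$b[keep], c2$b[keep2]),
                    runif(sum(keep) + sum(keep2), 1, 5))
    res <- run_mcl(to_markov(net))
    for (cl in res$clusters) {
      expect_true(all(startsWith(cl, "x")) || all(startsWith(cl, "y")))
    }
    # clusters partition the node set
    expect_setequal(unlist(res$clusters), net$nodes)
    expect_equal(anyDuplicated(unlist(res$clusters)), 0)
  }
})

test_that("cluster extraction handles attractor systems and ties", {
  # converged block-diagonal uniform blocks: one cluster per block
  M <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  M[1:3, 1:3] <- 1/3
  M[4:5, 4:5] <- 1/2
  expect_equal(canon_partition(extract_clusters(M)),
               list(c("a", "b", "c"), c("d", "e")))
  # idempotent single-column matrix: one cluster around the attractor
  M2 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  M2[, "a"] <- 1
  expect_equal(extract_clusters(M2), list(c("a", "b", "c")))
  # supporter tied between two attractors goes to the lexicographically
  # smaller one (with a message)
  M3 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  M3["a", "a"] <- 1
  M3["b", "b"] <- 1
  M3["c", c("a", "b")] <- 0.5
  expect_message(cl <- extract_clusters(M3), "ties")
  expect_equal(canon_partition(cl), list(c("a", "c"), "b"))
})

test_that("row stochasticity is preserved through full MCL runs", {
  set.seed(71)
  for (k in 1:5) {
    n <- sample(4:8, 1)
    nodes <- paste0("v", 1:n)
    a <- c(nodes[-n], sample(nodes, 3, TRUE))
    b <- c(nodes[-1], sample(nodes, 3, TRUE))
    keep <- a != b
    net <- edge_net(a[keep], b[keep], runif(sum(keep), 0.5, 6))
    M <- to_markov(net)
    for (i in 1:4) {
      M <- mcl_inflate(mcl_expand(M), 2)
      expect_equal(rowSums(M), rep(1, nrow(M)), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("cluster JSON round trips with stage and parameters", {
  path <- withr::local_tempfile(fileext = ".json")
  cl <- list(c("a", "b"), "c")
  write_clusters(cl, "stage1", mcl_params(), path)
  back <- read_clusters(path)
  expect_equal(back$stage, "stage1")
  expect_equal(back$clusters, cl)
  expect_equal(back$params$inflation, 2)
})
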