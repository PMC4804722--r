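#' Build a weighted TFBS co-occurrence network
#'
#' Nodes are TFBS (PWM) identifiers; an undirected edge between the two
#' PWMs of a pair carries the pair's observed frequency as weight.
#' Homotypic pairs (both sides the same PWM) cannot form an edge and are
#' dropped with a warning; multiple pairs mapping to the same unordered
#' node pair have their weights summed. Nodes with no edges are absent.
#'
#' @param freq Pair frequency table (`pair_id`, `weight`), e.g. from
#'   [aggregate_frequencies()].
#' @param library Composite library `data.frame` mapping `pair_id` to
#'   `pwm_a`, `pwm_b`.
#' @return Object of class `"tfbs_network"`: list with `nodes` (sorted
#'   character vector) and `edges` (`data.frame` `node_a`, `node_b`,
#'   `weight`, with `node_a < node_b`).
#' @export
build_network <- function(freq, library) {
  idx <- match(freq$pair_id, library$pair_id)
  if (anyNA(idx))
    stop("unmapped pair id(s): ",
         paste(freq$pair_id[is.na(idx)], collapse = ", "))
  a <- library$pwm_a[idx]
  b <- library$pwm_b[idx]
  homo <- a == b
  if (any(homo)) {
    warning("dropping homotypic pair(s) from network: ",
            paste(freq$pair_id[homo], collapse = ", "))
  }
  a2 <- pmin(a[!homo], b[!homo])
  b2 <- pmax(a[!homo], b[!homo])
  w <- freq$weight[!homo]
  if (length(w)) {
    key <- paste(a2, b2, sep = "\r")
    agg <- rowsum(w, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    edges <- data.frame(node_a = vapply(parts, `[`, character(1L), 1L),
                        node_b = vapply(parts, `[`, character(1L), 2L),
                        weight = as.numeric(agg[, 1L]),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  } else {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  if (any(edges$weight <= 0)) stop("edge weights must be positive")
  structure(list(nodes = sort(unique(c(edges$node_a, edges$node_b))),
                 edges = edges),
            class = "tfbs_network")
}

#' @export
print.tfbs_network <- function(x, ...) {
  cat(sprintf("TFBS network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read / write a weighted edge list (TSV: node_a, node_b, weight)
#' @param path File path.
#' @return A `tfbs_network`.
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lib <- data.frame(pair_id = sprintf("e%d", seq_len(nrow(df))),
                    pwm_a = df$node_a, pwm_b = df$node_b,
                    stringsAsFactors = FALSE)
  freq <- data.frame(pair_id = lib$pair_id, weight = df$weight,
                     stringsAsFactors = FALSE)
  build_network(freq, cbind(lib, threshold_a = 1, threshold_b = 1,
                            min_gap = 0L, max_gap = 0L, orientation = "any",
                            ordered = FALSE))
}

#' @rdname read_network
#' @param net A `tfbs_network`.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Markov clustering parameters
#'
#' @param inflation Inflation exponent `r > 1` (default 2); larger values
#'   give finer clusters.
#' @param self_loop Self-loop weight added to each node before row
#'   normalization: `"max"` (default) uses the node's maximum incident edge
#'   weight (1 for an isolated node), or a non-negative number (0 recovers
#'   the literal `M = Delta^-1 A` normalization, without the convergence
#'   guarantee self-loops provide).
#' @param tol Convergence tolerance on the maximum absolute entrywise
#'   change between iterations (default 1e-6).
#' @param max_iter Iteration cap (default 200); non-convergence is warned.
#' @param prune Entries below this are zeroed during inflation and ignored
#'   in attractor detection (default 1e-9).
#' @return List of class `"mcl_params"`.
#' @export
mcl_params <- function(inflation = 2, self_loop = "max", tol = 1e-6,
                       max_iter = 200L, prune = 1e-9) {
  if (!is.numeric(inflation) || inflation <= 1)
    stop("'inflation' must be > 1")
  if (tol <= 0) stop("'tol' must be positive")
  if (is.numeric(self_loop) && self_loop < 0)
    stop("'self_loop' must be non-negative")
  structure(list(inflation = inflation, self_loop = self_loop, tol = tol,
                 max_iter = as.integer(max_iter), prune = prune),
            class = "mcl_params")
}

#' Convert a network to a row-stochastic Markov matrix
#'
#' Builds the symmetric adjacency matrix `A` of edge weights, adds
#' self-loops to the diagonal, and row-normalizes (`M = Delta^-1 A`, with
#' `Delta` the diagonal row-sum matrix).
#'
#' @param net A `tfbs_network`.
#' @param params [mcl_params()] (controls the self-loop weight).
#' @return Row-stochastic numeric matrix with node-id dimnames.
#' @export
to_markov <- function(net, params = mcl_params()) {
  nodes <- sort(net$nodes)
  n <- length(nodes)
  if (!n) stop("network is empty")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(net$edges)) {
    ia <- match(net$edges$node_a, nodes)
    ib <- match(net$edges$node_b, nodes)
    A[cbind(ia, ib)] <- A[cbind(ia, ib)] + net$edges$weight
    A[cbind(ib, ia)] <- A[cbind(ib, ia)] + net$edges$weight
  }
  loop <- if (identical(params$self_loop, "max")) {
    mx <- apply(A, 1L, max)
    ifelse(mx > 0, mx, 1)
  } else {
    rep(params$self_loop, n)
  }
  diag(A) <- diag(A) + loop
  rs <- rowSums(A)
  if (any(rs == 0))
    stop("cannot normalize: node(s) with zero total weight ",
         "(use a positive self-loop)")
  A / rs
}

#' MCL Expand operation: matrix squaring
#'
#' @param M Row-stochastic matrix.
#' @return `M %*% M` (row-stochastic within numerical tolerance).
#' @export
mcl_expand <- function(M) M %*% M

#' MCL Inflate operation: entrywise power and row renormalization
#'
#' Each entry is raised to the inflation exponent, entries below the prune
#' epsilon are zeroed, and rows are renormalized to sum to 1:
#' `M[i, j] <- M[i, j]^r / sum_k M[i, k]^r`.
#'
#' @param M Row-stochastic matrix.
#' @param r Inflation exponent (`> 1`).
#' @param prune Entries below this are set to 0 before renormalization.
#' @return Row-stochastic matrix.
#' @export
mcl_inflate <- function(M, r = 2, prune = 1e-9) {
  if (r <= 1) stop("inflation exponent must be > 1")
  P <- M^r
  P[P < prune] <- 0
  rs <- rowSums(P)
  if (any(rs == 0))
    stop("all-zero row after pruning: cannot renormalize")
  P / rs
}

#' Run the Markov clustering algorithm
#'
#' Iterates Expand (matrix squaring) then Inflate (entrywise power and
#' row renormalization) until the maximum absolute entrywise change falls
#' below the tolerance or the iteration cap is reached (warned), then
#' extracts clusters from the converged flow matrix.
#'
#' @param M Row-stochastic matrix (see [to_markov()]).
#' @param params [mcl_params()].
#' @return List with `M` (converged matrix), `clusters` (list of sorted
#'   node-id character vectors, a partition of the nodes), `iterations`,
#'   `converged`.
#' @export
run_mcl <- function(M, params = mcl_params()) {
  stopifnot(is.matrix(M))
  if (any(!is.finite(M))) stop("non-finite entries in Markov matrix")
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    M2 <- mcl_inflate(mcl_expand(M), params$inflation, params$prune)
    if (any(!is.finite(M2))) stop("non-finite entries during MCL iteration")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < params$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("MCL did not converge within %d iterations",
                    params$max_iter))
  list(M = M, clusters = extract_clusters(M, prune = params$prune),
       iterations = iter, converged = converged)
}

#' Extract clusters from a converged MCL flow matrix
#'
#' Attractors are nodes with diagonal entry above the prune epsilon.
#' Attractors with direct mutual flow form one cluster; every other node
#' joins the cluster of the attractor it sends maximal flow to
#' (lexicographically smaller attractor id on ties, with a message).
#'
#' @param M Converged (or iteration-capped) flow matrix with dimnames.
#' @param prune Flow threshold for attractor detection and merging.
#' @return List of sorted node-id character vectors partitioning the nodes.
#' @export
extract_clusters <- function(M, prune = 1e-9) {
  nodes <- rownames(M)
  n <- length(nodes)
  attr_idx <- which(diag(M) > prune)
  if (!length(attr_idx)) attr_idx <- seq_len(n)  # degenerate: no attractors
  # union-find over attractors connected by direct flow
  parent <- seq_along(attr_idx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ii in seq_along(attr_idx)) {
    for (jj in seq_along(attr_idx)) {
      if (ii < jj) {
        a <- attr_idx[ii]; b <- attr_idx[jj]
        if (M[a, b] > prune || M[b, a] > prune) {
          ra <- find(ii); rb <- find(jj)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
  }
  comp <- vapply(seq_along(attr_idx), find, integer(1L))
  cluster_of <- integer(n)
  cluster_of[attr_idx] <- comp
  for (i in setdiff(seq_len(n), attr_idx)) {
    flows <- M[i, attr_idx]
    best <- which(flows == max(flows))
    if (length(best) > 1L) {
      # tie: lexicographically smallest attractor id
      best <- best[order(nodes[attr_idx[best]])][1L]
      message(sprintf("node '%s' ties between attractors; assigned to '%s'",
                      nodes[i], nodes[attr_idx[best]]))
    }
    cluster_of[i] <- comp[best]
  }
  cl <- split(nodes, cluster_of)
  cl <- lapply(unname(cl), sort)
  cl[order(vapply(cl, `[`, character(1L), 1L))]
}

#' Write / read a per-stage cluster set (JSON)
#'
#' @param clusters List of node-id character vectors.
#' @param stage Stage label.
#' @param params [mcl_params()] used to produce the clusters.
#' @param path File path.
#' @export
write_clusters <- function(clusters, stage, params, path) {
  obj <- list(stage = stage, clusters = clusters,
              params = unclass(params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$clusters <- lapply(obj$clusters, as.character)
  obj
}
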