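#' Stage presence table for a hub-centered cluster
#'
#' Rows are hub-partner TFBS pairs; columns are the five developmental
#' stages; cells record whether the hub-partner edge lay inside the hub's
#' cluster at that stage.
#'
#' @param hub Hub TFBS id.
#' @param presence Logical matrix, partners x stages (partner ids as row
#'   names); every row must have at least one `TRUE`, and the hub must not
#'   appear among the partners.
#' @param stages Character vector of stage names (columns).
#' @return Object of class `"stage_presence"`.
#' @export
stage_presence_table <- function(hub, presence,
                                 stages = stage_definitions()$stage) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "logical"
  if (ncol(presence) != length(stages))
    stop("presence matrix must have one column per stage")
  colnames(presence) <- stages
  if (is.null(rownames(presence)))
    stop("presence matrix must have partner row names")
  if (hub %in% rownames(presence))
    stop("hub must not appear among its partners")
  if (nrow(presence) && any(rowSums(presence) == 0))
    stop("every partner row must be present in at least one stage")
  structure(list(hub = hub, presence = presence, stages = stages),
            class = "stage_presence")
}

#' @export
print.stage_presence <- function(x, ...) {
  cat(sprintf("Hub %s: %d partner pair(s) over %d stages\n",
              x$hub, nrow(x$presence), length(x$stages)))
  m <- ifelse(x$presence, "+", "-")
  rownames(m) <- paste(x$hub, "-", rownames(x$presence))
  print(as.data.frame(m))
  invisible(x)
}

#' Find the hub (center) of a cluster
#'
#' The hub is the cluster node with maximal within-cluster weighted degree
#' (sum of incident edge weights to other cluster members); ties are
#' resolved to the lexicographically smallest id.
#'
#' @param cluster Character vector of node ids (non-empty, a subset of the
#'   network's nodes).
#' @param net A `tfbs_network`.
#' @return Single node id.
#' @export
find_hub <- function(cluster, net) {
  if (!length(cluster)) stop("cluster is empty")
  if (!all(cluster %in% net$nodes))
    stop("cluster contains nodes absent from the network")
  deg <- stats::setNames(numeric(length(cluster)), sort(cluster))
  e <- net$edges
  inside <- e$node_a %in% cluster & e$node_b %in% cluster
  for (k in which(inside)) {
    deg[e$node_a[k]] <- deg[e$node_a[k]] + e$weight[k]
    deg[e$node_b[k]] <- deg[e$node_b[k]] + e$weight[k]
  }
  names(deg)[which.max(deg)]  # names sorted, so ties go lexicographic
}

#' Keep clusters with at least a minimum number of interactions
#'
#' A cluster is reportable when its induced subgraph contains at least
#' `min_edges` edges (default 3, matching the smallest reported hub
#' cluster); singletons are always dropped.
#'
#' @param clusters List of node-id character vectors (from [run_mcl()]).
#' @param net A `tfbs_network`.
#' @param min_edges Minimum induced edge count.
#' @return Filtered list of clusters.
#' @export
filter_reportable_clusters <- function(clusters, net, min_edges = 3L) {
  keep <- vapply(clusters, function(cl) {
    if (length(cl) < 2L) return(FALSE)
    sum(net$edges$node_a %in% cl & net$edges$node_b %in% cl) >= min_edges
  }, logical(1L))
  clusters[keep]
}

#' Track a hub-centered cluster across stages
#'
#' For each stage, the hub's partners are the nodes adjacent to the hub
#' within the hub's (reportable) cluster at that stage; a partner's
#' presence vector is `TRUE` exactly in the stages where that hub-partner
#' edge lies inside the hub's cluster. Partners are the union over all
#' stages.
#'
#' @param clusters_by_stage Named list (per stage) of cluster lists.
#' @param nets_by_stage Named list (per stage) of `tfbs_network`s.
#' @param hub Hub TFBS id; must be clustered in at least one stage.
#' @param reportable_only Apply [filter_reportable_clusters()] per stage
#'   before looking the hub up (default `TRUE`).
#' @param min_edges Passed to [filter_reportable_clusters()].
#' @return A [stage_presence_table()].
#' @export
track_hub_across_stages <- function(clusters_by_stage, nets_by_stage, hub,
                                    reportable_only = TRUE, min_edges = 3L) {
  stages <- names(clusters_by_stage)
  partner_sets <- list()
  for (s in stages) {
    cls <- clusters_by_stage[[s]]
    net <- nets_by_stage[[s]]
    if (reportable_only) cls <- filter_reportable_clusters(cls, net, min_edges)
    hit <- which(vapply(cls, function(cl) hub %in% cl, logical(1L)))
    partner_sets[[s]] <- if (length(hit)) {
      cl <- cls[[hit[1L]]]
      e <- net$edges
      adj <- c(e$node_b[e$node_a == hub], e$node_a[e$node_b == hub])
      sort(intersect(adj, setdiff(cl, hub)))
    } else character(0)
  }
  partners <- sort(unique(unlist(partner_sets)))
  if (!length(partners) && !any(lengths(partner_sets) > 0))
    stop(sprintf("hub '%s' is never part of a reportable cluster", hub))
  presence <- vapply(stages, function(s) partners %in% partner_sets[[s]],
                     logical(length(partners)))
  presence <- matrix(presence, nrow = length(partners),
                     dimnames = list(partners, stages))
  stage_presence_table(hub, presence, stages)
}

#' Classify the temporal pattern of a presence vector
#'
#' Categories: `all_stages` (present throughout), `interrupted` (any
#' present-absent-present pattern, i.e. present early and late but absent
#' in at least one intervening stage), `stage_specific` (present in exactly
#' one stage), `other` (everything else, e.g. plain early or late blocks).
#'
#' @param presence Logical vector (length 5 for the default stages) with at
#'   least one `TRUE`.
#' @return One of `"all_stages"`, `"interrupted"`, `"stage_specific"`,
#'   `"other"`.
#' @export
classify_temporal <- function(presence) {
  presence <- as.logical(presence)
  if (anyNA(presence)) stop("presence vector contains NA")
  if (!any(presence)) stop("presence vector must contain at least one TRUE")
  if (all(presence)) return("all_stages")
  if (sum(presence) == 1L) return("stage_specific")
  first_t <- min(which(presence))
  last_t <- max(which(presence))
  if (any(!presence[first_t:last_t])) return("interrupted")
  "other"
}

#' Number of partner pairs in a presence table
#' @param table A `stage_presence` object.
#' @return Integer row count (the union of partners over all stages).
#' @export
count_union_pairs <- function(table) {
  stopifnot(inherits(table, "stage_presence"))
  nrow(table$presence)
}

#' Number of partner pairs present at every stage
#' @param table A `stage_presence` object.
#' @return Integer count of all-`TRUE` rows.
#' @export
count_all_stage_pairs <- function(table) {
  stopifnot(inherits(table, "stage_presence"))
  sum(rowSums(table$presence) == ncol(table$presence))
}

#' Read / write a TF gene mapping (TSV: pwm_id, gene_id)
#' @param path File path.
#' @export
read_tf_mapping <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_tf_mapping
#' @param mapping Mapping `data.frame`.
#' @export
write_tf_mapping <- function(mapping, path) {
  utils::write.table(mapping, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Annotate a TFBS pair with TF gene expression
#'
#' A side's expressed-timepoint set contains the timepoints where the
#' maximum mean FPKM (replicates averaged) over its mapped TF genes is at
#' or above the threshold (default 10, the value separating robustly
#' expressed from low/unexpressed TF genes). The pair is a
#' `synergistic_candidate` when the two sides' expressed sets share at
#' least one timepoint inside every stage where the pair is present, an
#' `antagonistic_candidate` when both sides are expressed somewhere but
#' their sets are disjoint within every present stage, and `indeterminate`
#' otherwise. This is a screening heuristic over co-expression patterns,
#' reported alongside the raw expressed sets.
#'
#' @param pwm_a,pwm_b PWM ids of the two sides.
#' @param presence Logical stage-presence vector for the pair.
#' @param tf_mapping `data.frame` with `pwm_id`, `gene_id`.
#' @param expr Expression matrix (see [read_expression()]).
#' @param threshold FPKM threshold (inclusive; default 10).
#' @param stages Stage definitions (see [stage_definitions()]).
#' @return List with `pair` (the two ids), `expressed_a`, `expressed_b`
#'   (numeric timepoint vectors), and `mode`.
#' @export
annotate_expression <- function(pwm_a, pwm_b, presence, tf_mapping, expr,
                                threshold = 10,
                                stages = stage_definitions()) {
  tp <- timepoint_means(expr)
  days <- as.numeric(colnames(tp))
  side_set <- function(pwm_id) {
    genes <- tf_mapping$gene_id[tf_mapping$pwm_id == pwm_id]
    genes <- intersect(genes, rownames(tp))
    if (!length(genes))
      stop(sprintf("no mapped TF gene with expression data for PWM '%s'",
                   pwm_id))
    prof <- apply(tp[genes, , drop = FALSE], 2L, max)
    days[prof >= threshold]
  }
  ea <- side_set(pwm_a)
  eb <- side_set(pwm_b)
  present <- which(as.logical(presence))
  per_stage <- vapply(present, function(s) {
    bounds <- c(stages$start[s], stages$end[s])
    a_s <- intersect(ea, bounds)
    b_s <- intersect(eb, bounds)
    if (length(intersect(a_s, b_s))) "overlap"
    else "disjoint"
  }, character(1L))
  mode <- if (length(per_stage) && all(per_stage == "overlap"))
    "synergistic_candidate"
  else if (length(ea) && length(eb) && length(per_stage) &&
           all(per_stage == "disjoint"))
    "antagonistic_candidate"
  else "indeterminate"
  list(pair = c(pwm_a, pwm_b), expressed_a = ea, expressed_b = eb,
       mode = mode)
}

#' Hourglass profile of per-stage counts
#'
#' Locates the minimum of a five-stage count profile (first occurrence on
#' ties) and reports whether it lies strictly inside the time course
#' (stages 2-4), the signature of an hourglass-shaped developmental
#' divergence profile.
#'
#' @param counts Numeric vector of 5 non-negative per-stage counts.
#' @return List with `argmin_stage` (1-5) and `interior_min` (logical).
#' @export
hourglass_profile <- function(counts) {
  if (length(counts) != 5L || any(counts < 0))
    stop("'counts' must be 5 non-negative values")
  argmin <- which.min(counts)
  list(argmin_stage = as.integer(argmin),
       interior_min = argmin >= 2L && argmin <= 4L)
}

#' Write / read a stage presence table (TSV with +/- cells)
#'
#' Columns: `hub`, `partner`, then one `+`/`-` column per stage.
#'
#' @param table A `stage_presence` object.
#' @param path File path.
#' @export
write_presence_table <- function(table, path) {
  stopifnot(inherits(table, "stage_presence"))
  df <- data.frame(hub = table$hub, partner = rownames(table$presence),
                   ifelse(table$presence, "+", "-"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_table
#' @export
read_presence_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  stages <- setdiff(names(df), c("hub", "partner"))
  presence <- as.matrix(df[stages]) == "+"
  rownames(presence) <- df$partner
  stage_presence_table(unique(df$hub), presence, stages)
}
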