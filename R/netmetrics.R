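# The five graph metrics on thresholded weighted brain graphs: mean
# weighted degree (DE), density (DS), modularity (M), clustering
# coefficient (CC), characteristic path length (CPL).
#
# All metrics are computed on the weighted supra-threshold graph by
# default; `binary = TRUE` replaces retained weights by 1.

coerce_graph <- function(g, binary = FALSE) {
  if (inherits(g, "brain_graph")) adj <- g$adj
  else if (is.matrix(g)) { adj <- g; diag(adj) <- 0 }
  else stop("expected a brain_graph or adjacency matrix")
  if (binary) adj <- (adj > 0) * 1
  adj
}

#' Mean weighted degree and density
#'
#' DE is the mean over nodes of the summed incident edge weights
#' (node strength); DS is the number of edges divided by the maximum
#' possible `n(n-1)/2`.
#'
#' @param g a `brain_graph` or weighted adjacency matrix
#' @param binary compute on the binarised graph
#' @return named numeric vector `c(DE, DS)`
#' @export
degree_density <- function(g, binary = FALSE) {
  adj <- coerce_graph(g, binary)
  n <- nrow(adj)
  c(DE = mean(rowSums(adj)),
    DS = (sum(adj > 0) / 2) / (n * (n - 1) / 2))
}

#' Mean weighted clustering coefficient
#'
#' Onnela geometric-mean formulation: with weights rescaled by the maximum
#' weight, a node's coefficient is the sum of the cube-rooted triangle
#' weight products around it divided by `k (k - 1)`; nodes with degree
#' below 2 contribute 0; CC is the mean over all nodes.
#'
#' @inheritParams degree_density
#' @return scalar in \[0, 1\]
#' @export
clustering_coef <- function(g, binary = FALSE) {
  adj <- coerce_graph(g, binary)
  if (max(adj) == 0) return(0)
  W <- (adj / max(adj))^(1 / 3)
  num <- diag(W %*% W %*% W)           # 2 x sum of triangle products
  k <- rowSums(adj > 0)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(cc)
}

#' Characteristic path length
#'
#' Shortest paths on distances `1/weight`; CPL is the mean shortest-path
#' length over *connected* node pairs only. Returns `NA` (with a warning)
#' when no pair is connected.
#'
#' @inheritParams degree_density
#' @return scalar, or `NA` for an edgeless graph
#' @export
char_path_length <- function(g, binary = FALSE) {
  adj <- coerce_graph(g, binary)
  if (all(adj == 0)) {
    warning("edgeless graph: CPL undefined")
    return(NA_real_)
  }
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  D <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  vals <- D[upper.tri(D)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Louvain modularity and module map
#'
#' Greedy multi-level maximisation of weighted Newman modularity
#' (resolution 1) with seeded tie-breaking; an edgeless graph has
#' undefined modularity and every node in its own module.
#'
#' @inheritParams degree_density
#' @param seed RNG seed for reproducible module maps
#' @return list with `M` (modularity, `NA` if edgeless) and `modules`
#'   (named node -> module id vector)
#' @export
modularity_partition <- function(g, seed = 1, binary = FALSE) {
  adj <- coerce_graph(g, binary)
  labels <- rownames(adj)
  if (is.null(labels)) labels <- paste0("node", seq_len(nrow(adj)))
  if (all(adj == 0)) {
    return(list(M = NA_real_,
                modules = stats::setNames(seq_len(nrow(adj)), labels)))
  }
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  cl <- run_seeded(seed, function()
    igraph::cluster_louvain(ig, weights = igraph::E(ig)$weight))
  list(M = igraph::modularity(cl),
       modules = stats::setNames(igraph::membership(cl), labels))
}

#' Metric rows over time for a condition's PLV tensor
#'
#' Thresholds the PLV matrix at the window nearest each requested time and
#' computes all five metrics. Default query times are -1, 0 and 1.4 s
#' (planning phase, movement onset, typical peak time).
#'
#' @param plv a trial-averaged `plv_tensor`
#' @param condition label stored in the output rows
#' @param times query times in seconds (nearest window centre is used;
#'   times outside the covered range are an error)
#' @param threshold edge threshold (default 0.65)
#' @param seed Louvain seed
#' @param binary compute metrics on the binarised graph
#' @return data frame with one row per time: `condition`, `time_s`, `DE`,
#'   `DS`, `M`, `CC`, `CPL`, `n_edges`, `n_modules`
#' @export
metrics_timecourse <- function(plv, condition = "all",
                               times = c(-1, 0, 1.4), threshold = 0.65,
                               seed = 1, binary = FALSE) {
  stopifnot(inherits(plv, "plv_tensor"), isTRUE(plv$averaged))
  ctr <- plv$window_centers
  rows <- lapply(times, function(tt) {
    if (tt < min(ctr) - plv$window_s / 2 || tt > max(ctr) + plv$window_s / 2)
      stop("query time ", tt, " s outside PLV coverage")
    w <- which.min(abs(ctr - tt))
    g <- threshold_graph(plv$values[w, , ], threshold, labels = plv$roi)
    dd <- degree_density(g, binary)
    mp <- modularity_partition(g, seed, binary)
    data.frame(condition = condition, time_s = tt,
               DE = dd[["DE"]], DS = dd[["DS"]], M = mp$M,
               CC = clustering_coef(g, binary),
               CPL = char_path_length(g, binary),
               n_edges = sum(g$adj > 0) / 2,
               n_modules = length(unique(mp$modules)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
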