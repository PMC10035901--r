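#' @title Whole-network (global) measures
#' @description Network-level summaries of a SIN. Distance-based measures
#'   (average shortest path length, diameter, global efficiency) follow the
#'   largest-component convention: when the network has several connected
#'   components they are evaluated on the largest one only. Quantities that
#'   are undefined on a given network (e.g. the diameter of an edgeless
#'   network, or the assortativity of a regular one) are returned as `NA`,
#'   never silently as 0.
#' @name measures_global
NULL

#' Average shortest path length
#'
#' Mean hop distance over all ordered pairs of the largest connected
#' component.
#'
#' @param sin A `sin` object.
#' @return A single number, or `NA` if the largest component has fewer
#'   than 2 nodes.
#' @export
avg_shortest_path <- function(sin) {
  lc <- largest_component(sin$graph)
  if (igraph::vcount(lc$sub) < 2L) return(NA_real_)
  igraph::mean_distance(lc$sub, directed = FALSE)
}

#' Network diameter
#'
#' Longest shortest path on the largest connected component.
#'
#' @inheritParams avg_shortest_path
#' @return A single number, or `NA` if undefined.
#' @export
net_diameter <- function(sin) {
  lc <- largest_component(sin$graph)
  if (igraph::vcount(lc$sub) < 2L) return(NA_real_)
  as.numeric(igraph::diameter(lc$sub, directed = FALSE, weights = NA))
}

#' Global efficiency
#'
#' Mean of `1/d_ij` over ordered pairs of the largest connected component;
#' 1 exactly when that component is complete.
#'
#' @inheritParams avg_shortest_path
#' @return A single number in `[0, 1]`, or `NA` if undefined.
#' @export
global_efficiency <- function(sin) {
  lc <- largest_component(sin$graph)
  n <- igraph::vcount(lc$sub)
  if (n < 2L) return(NA_real_)
  d <- igraph::distances(lc$sub, weights = NA)
  mean(1 / d[upper.tri(d) | lower.tri(d)])
}

#' Average clustering coefficient
#'
#' Mean of the local clustering coefficient over all `N` roster nodes
#' (isolated flies contribute 0).
#'
#' @inheritParams avg_shortest_path
#' @param weight `"none"`, `"count"` or `"duration"` (passed to
#'   [local_clustering()]).
#' @return A single number in `[0, 1]`.
#' @export
avg_clustering <- function(sin, weight = "none") {
  mean(local_clustering(sin, weight))
}

#' Network transitivity
#'
#' Global clustering: `3 x triangles / triads`, where a triad is a path of
#' two edges sharing a node. 0 by convention when the network has no
#' triads.
#'
#' @inheritParams avg_shortest_path
#' @return A single number in `[0, 1]`.
#' @export
net_transitivity <- function(sin) {
  t <- igraph::transitivity(sin$graph, type = "globalundirected")
  if (is.nan(t)) 0 else t
}

#' Network density
#'
#' Realised fraction of the `N(N-1)/2` possible edges: `2K / (N(N-1))`.
#'
#' @inheritParams avg_shortest_path
#' @return A single number in `[0, 1]`, or `NA` when `N < 2`.
#' @export
net_density <- function(sin) {
  n <- igraph::vcount(sin$graph)
  if (n < 2L) return(NA_real_)
  2 * igraph::ecount(sin$graph) / (n * (n - 1))
}

#' Degree heterogeneity
#'
#' Population standard deviation of the degree sequence divided by the
#' mean degree; 0 for regular networks, `NA` when no fly interacts.
#'
#' @inheritParams avg_shortest_path
#' @return A single non-negative number, or `NA` if undefined.
#' @export
degree_heterogeneity <- function(sin) {
  k <- igraph::degree(sin$graph)
  if (mean(k) == 0) return(NA_real_)
  sqrt(mean((k - mean(k))^2)) / mean(k)
}

#' Degree assortativity
#'
#' Pearson correlation of the excess degrees (degree minus one) at the two
#' endpoints of every edge, counting both orientations. Negative values
#' mean hubs preferentially attach to low-degree flies. `NA` when the
#' correlation is undefined (no edges, or zero variance as in regular
#' networks).
#'
#' @inheritParams avg_shortest_path
#' @return A single number in `[-1, 1]`, or `NA` if undefined.
#' @export
net_assortativity <- function(sin) {
  if (igraph::ecount(sin$graph) < 1L) return(NA_real_)
  r <- suppressWarnings(igraph::assortativity_degree(sin$graph, directed = FALSE))
  if (is.nan(r)) NA_real_ else r
}

#' Global summary of one network
#'
#' One row of global measures for a SIN: node and edge counts, average
#' degree `2K/N`, average strengths under both weights, links per node
#' `K/N`, density, average shortest path length, diameter, global
#' efficiency, average clustering, transitivity, degree heterogeneity and
#' assortativity.
#'
#' @inheritParams avg_shortest_path
#' @return A one-row data.frame with columns `N, K, avg_degree,
#'   avg_strength_count, avg_strength_duration, avg_links_per_node,
#'   density, L, D, E_glob, avg_clustering, transitivity, heterogeneity,
#'   assortativity`.
#' @export
global_summary <- function(sin) {
  g <- sin$graph
  n <- igraph::vcount(g)
  k <- igraph::ecount(g)
  data.frame(
    N = n, K = k,
    avg_degree = if (n > 0) 2 * k / n else NA_real_,
    avg_strength_count = if (n > 0) mean(node_strength(sin, "count")) else NA_real_,
    avg_strength_duration = if (n > 0) mean(node_strength(sin, "duration")) else NA_real_,
    avg_links_per_node = if (n > 0) k / n else NA_real_,
    density = net_density(sin),
    L = avg_shortest_path(sin),
    D = net_diameter(sin),
    E_glob = global_efficiency(sin),
    avg_clustering = avg_clustering(sin),
    transitivity = net_transitivity(sin),
    heterogeneity = degree_heterogeneity(sin),
    assortativity = net_assortativity(sin))
}
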