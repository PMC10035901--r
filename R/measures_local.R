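#' @title Local (per-fly) network measures
#' @description Per-node centrality and clustering measures for a SIN.
#'   Distance-based measures (closeness, betweenness, eigenvector,
#'   information centrality) follow the largest-component convention:
#'   they are computed on the largest connected component, with component
#'   size as the normalising `N`, and every node outside that component
#'   scores 0. Degree, strength and clustering are defined on the full
#'   graph. Weighted shortest-path variants use edge length `1/w`, so a
#'   stronger social tie is a shorter distance.
#' @name measures_local
NULL

largest_component <- function(g) {
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  list(sub = igraph::induced_subgraph(g, keep),
       members = igraph::V(g)$name[keep])
}

# distribute values computed on the largest component back over the roster
fill_component <- function(sin, values, members) {
  out <- stats::setNames(rep(0, igraph::vcount(sin$graph)), sin_nodes(sin))
  out[members] <- values
  out
}

#' Degree centrality
#'
#' Number of distinct interaction partners, normalised by the maximum
#' possible `N - 1`.
#'
#' @param sin A `sin` object with at least 2 nodes.
#' @return Named numeric vector over the roster, values in `[0, 1]`.
#' @export
degree_centrality <- function(sin) {
  n <- igraph::vcount(sin$graph)
  if (n < 2L) stop("degree centrality needs at least 2 nodes", call. = FALSE)
  igraph::degree(sin$graph) / (n - 1)
}

#' Node strength
#'
#' Sum of the chosen edge weight over a fly's edges: with `"count"` the
#' total number of its interaction events, with `"duration"` the total
#' time (s) it spent interacting.
#'
#' @param sin A `sin` object.
#' @param weight `"count"` or `"duration"`.
#' @return Named numeric vector over the roster.
#' @export
node_strength <- function(sin, weight = c("count", "duration")) {
  weight <- match.arg(weight)
  igraph::strength(sin$graph, weights = sin_weight(sin, weight))
}

#' Closeness centrality
#'
#' `(N - 1) / sum_j d_ij` on the largest connected component (`N` = its
#' size); nodes outside the largest component score 0.
#'
#' @inheritParams node_strength
#' @param weight `"none"` (hop counts, default), `"count"` or `"duration"`
#'   (shortest paths over edge lengths `1/w`).
#' @return Named numeric vector over the roster.
#' @export
closeness_centrality <- function(sin, weight = c("none", "count", "duration")) {
  weight <- match.arg(weight)
  lc <- largest_component(sin$graph)
  if (igraph::vcount(lc$sub) < 2L)
    return(fill_component(sin, numeric(0), character(0)))
  w <- sin_weight(new_sin(lc$sub), weight)
  cc <- igraph::closeness(lc$sub, normalized = TRUE,
                          weights = if (is.null(w)) NA else 1 / w)
  fill_component(sin, cc, lc$members)
}

#' Betweenness centrality
#'
#' Fraction of shortest paths between other flies passing through each
#' fly, normalised by `(N - 1)(N - 2) / 2` pair choices on the largest
#' component; nodes outside it score 0.
#'
#' @inheritParams closeness_centrality
#' @return Named numeric vector over the roster, values in `[0, 1]`.
#' @export
betweenness_centrality <- function(sin, weight = c("none", "count", "duration")) {
  weight <- match.arg(weight)
  lc <- largest_component(sin$graph)
  n <- igraph::vcount(lc$sub)
  if (n < 3L) return(fill_component(sin, rep(0, n), lc$members))
  w <- sin_weight(new_sin(lc$sub), weight)
  bc <- igraph::betweenness(lc$sub, directed = FALSE,
                            weights = if (is.null(w)) NA else 1 / w)
  fill_component(sin, bc / ((n - 1) * (n - 2) / 2), lc$members)
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the adjacency matrix of the largest connected
#' component, computed by power iteration (tolerance 1e-10, at most 1000
#' iterations), returned non-negative with unit Euclidean norm over the
#' component; nodes outside it score 0.
#'
#' @inheritParams closeness_centrality
#' @param weight `"none"` (binary adjacency), `"count"` or `"duration"`.
#' @return Named numeric vector over the roster.
#' @export
eigenvector_centrality <- function(sin, weight = c("none", "count", "duration"),
                                   tol = 1e-10, max_iter = 1000L) {
  weight <- match.arg(weight)
  lc <- largest_component(sin$graph)
  n <- igraph::vcount(lc$sub)
  if (n < 2L) return(fill_component(sin, rep(0, n), lc$members))
  w <- sin_weight(new_sin(lc$sub), weight)
  A <- igraph::as_adjacency_matrix(lc$sub, sparse = FALSE,
                                   attr = if (weight == "none") NULL
                                          else c(count = "w_count",
                                                 duration = "w_duration")[[weight]])
  # iterate on A + I: same eigenvectors, but the spectral shift makes the
  # Perron eigenvalue strictly dominant (plain iteration can cycle on
  # bipartite components)
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    nv <- as.numeric(A %*% v) + v
    nv <- nv / sqrt(sum(nv^2))
    if (max(abs(nv - v)) < tol) {
      return(fill_component(sin, abs(nv), lc$members))
    }
    v <- nv
  }
  stop(sprintf("eigenvector power iteration did not converge in %d iterations",
               max_iter), call. = FALSE)
}

#' Information centrality
#'
#' Current-flow closeness: for node `i` of the largest component,
#' `1 / sum_j r_ij` where `r_ij` is the effective resistance between `i`
#' and `j` when each edge conducts with its weight (unit conductance when
#' unweighted), obtained from the Moore-Penrose pseudoinverse of the graph
#' Laplacian. Nodes outside the largest component score 0.
#'
#' @inheritParams closeness_centrality
#' @return Named numeric vector over the roster.
#' @export
information_centrality <- function(sin, weight = c("none", "count", "duration")) {
  weight <- match.arg(weight)
  lc <- largest_component(sin$graph)
  n <- igraph::vcount(lc$sub)
  if (n < 2L) return(fill_component(sin, rep(0, n), lc$members))
  w <- sin_weight(new_sin(lc$sub), weight)
  L <- igraph::laplacian_matrix(lc$sub, sparse = FALSE,
                                weights = if (is.null(w)) NA else w)
  P <- MASS::ginv(L)
  dP <- diag(P)
  # r_ij = P_ii + P_jj - 2 P_ij; row sums of the resistance matrix
  rsum <- n * dP + sum(dP) - 2 * rowSums(P)
  fill_component(sin, 1 / rsum, lc$members)
}

#' Local clustering coefficient
#'
#' Fraction of a fly's neighbour pairs that interact with each other;
#' flies with fewer than two partners score 0. The weighted variant uses
#' geometric-mean triangle intensities with weights scaled by the network
#' maximum, so it stays in `[0, 1]`.
#'
#' @inheritParams closeness_centrality
#' @return Named numeric vector over the roster, values in `[0, 1]`.
#' @export
local_clustering <- function(sin, weight = c("none", "count", "duration")) {
  weight <- match.arg(weight)
  g <- sin$graph
  n <- igraph::vcount(g)
  ids <- sin_nodes(sin)
  if (weight == "none") {
    cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    return(stats::setNames(cc, ids))
  }
  if (igraph::ecount(g) == 0L) return(stats::setNames(rep(0, n), ids))
  W <- igraph::as_adjacency_matrix(g, sparse = FALSE,
                                   attr = c(count = "w_count",
                                            duration = "w_duration")[[weight]])
  k <- igraph::degree(g)
  if (max(W) > 0) W <- W / max(W)
  Wc <- W^(1 / 3)
  tri <- diag(Wc %*% Wc %*% Wc)  # 2x geometric-mean triangle intensity sum
  out <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  stats::setNames(out, ids)
}

#' Table of all local measures
#'
#' Assembles every per-fly measure into one data.frame, one row per roster
#' node, plus the per-network median and mean of each measure (the
#' quantities used when comparing groups of networks).
#'
#' @param sin A `sin` object.
#' @return A list with `per_node` (data.frame with columns `fly_id, dc,
#'   s_count, s_duration, cc, bc, ec, ic, C, C_wcount, C_wduration`),
#'   `median` and `mean` (named numeric vectors over the measure columns).
#' @export
local_measure_table <- function(sin) {
  n <- igraph::vcount(sin$graph)
  tab <- data.frame(
    fly_id = sin_nodes(sin),
    dc = if (n >= 2) degree_centrality(sin) else rep(0, n),
    s_count = node_strength(sin, "count"),
    s_duration = node_strength(sin, "duration"),
    cc = closeness_centrality(sin),
    bc = betweenness_centrality(sin),
    ec = eigenvector_centrality(sin),
    ic = information_centrality(sin),
    C = local_clustering(sin, "none"),
    C_wcount = local_clustering(sin, "count"),
    C_wduration = local_clustering(sin, "duration"),
    stringsAsFactors = FALSE, row.names = NULL)
  num <- tab[, -1, drop = FALSE]
  list(per_node = tab,
       median = vapply(num, stats::median, numeric(1)),
       mean = vapply(num, mean, numeric(1)))
}
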