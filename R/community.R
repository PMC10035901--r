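#' Louvain community detection
#'
#' Partitions a SIN into communities by greedy modularity optimisation
#' (Louvain: local node moves followed by community aggregation, repeated
#' until no gain). Duration weights are the default for middle-level
#' analysis because interaction time is the more informative tie strength;
#' the run is made deterministic by seeding the RNG. Isolated flies always
#' end up as singleton communities.
#'
#' @param sin A `sin` object.
#' @param weight `"none"`, `"count"` or `"duration"` (default).
#' @param seed Integer RNG seed (Louvain is order-dependent).
#' @param resolution Resolution parameter of the modularity objective
#'   (default 1).
#' @return An object of class `sin_partition`: list with `membership`
#'   (named integer vector, consecutive ids starting at 1), `weight`,
#'   `seed`, `resolution`.
#' @export
louvain_partition <- function(sin, weight = c("duration", "count", "none"),
                              seed = 0L, resolution = 1.0) {
  weight <- match.arg(weight)
  w <- sin_weight(sin, weight)
  memb <- withr::with_seed(seed, {
    cl <- igraph::cluster_louvain(sin$graph,
                                  weights = if (is.null(w)) NA else w,
                                  resolution = resolution)
    igraph::membership(cl)
  })
  structure(list(membership = stats::setNames(as.integer(memb), sin_nodes(sin)),
                 weight = weight, seed = as.integer(seed),
                 resolution = resolution),
            class = "sin_partition")
}

as_membership_vector <- function(sin, partition) {
  memb <- if (inherits(partition, "sin_partition")) partition$membership
          else partition
  ids <- sin_nodes(sin)
  if (!all(ids %in% names(memb)))
    stop("partition does not cover node(s): ",
         paste(setdiff(ids, names(memb)), collapse = ", "), call. = FALSE)
  memb[ids]
}

#' Modularity of a partition
#'
#' Quality of a community partition: `Q = sum_i (e_ii - a_i^2)`, where
#' `e_ii` is the fraction of total edge weight inside community `i` and
#' `a_i` the fraction of edge endpoints attached to it. Range
#' `[-0.5, 1]`; higher values mean denser within-community ties.
#'
#' @param sin A `sin` object with at least one edge.
#' @param partition A `sin_partition` or a named membership vector
#'   covering every node.
#' @param weight `"none"`, `"count"` or `"duration"`; defaults to the
#'   weight the partition was built with (or `"none"` for a bare vector).
#' @return A single number.
#' @export
sin_modularity <- function(sin, partition, weight = NULL) {
  if (is.null(weight)) {
    weight <- if (inherits(partition, "sin_partition")) partition$weight
              else "none"
  }
  memb <- as_membership_vector(sin, partition)
  edges <- sin_edges(sin)
  w <- switch(weight, none = rep(1, nrow(edges)),
              count = as.numeric(edges$w_count),
              duration = edges$w_duration,
              stop("unknown weight kind: ", weight, call. = FALSE))
  m <- sum(w)
  if (m == 0) return(NA_real_)
  ca <- memb[edges$fly_a]
  cb <- memb[edges$fly_b]
  groups <- sort(unique(memb))
  e_ii <- vapply(groups, function(g) sum(w[ca == g & cb == g]) / m, numeric(1))
  # a_i: fraction of endpoint weight attached to community i
  a_i <- vapply(groups, function(g)
    (sum(w[ca == g]) + sum(w[cb == g])) / (2 * m), numeric(1))
  sum(e_ii - a_i^2)
}

#' Connected components
#'
#' @param sin A `sin` object.
#' @return A list with `n_components` and `sizes` (sorted decreasing).
#' @export
sin_components <- function(sin) {
  comp <- igraph::components(sin$graph)
  list(n_components = comp$no,
       sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}

#' Middle-level community statistics
#'
#' The community-level summary of one network: community counts and
#' sizes, singleton (isolated-fly) communities, connected components and
#' modularity.
#'
#' @param sin A `sin` object.
#' @param partition A `sin_partition` from [louvain_partition()]; built
#'   with the default settings when omitted.
#' @param pct_single_denominator Denominator of the percentage of single
#'   element communities: `"communities"` (default) or `"nodes"`.
#' @return A one-row data.frame with columns `n_nodes, n_communities,
#'   n_single_element, pct_single_element, n_communities_without_single,
#'   biggest_size, second_biggest_size, avg_size_without_single,
#'   n_components, biggest_component_size, modularity`.
#' @export
community_stats <- function(sin, partition = NULL,
                            pct_single_denominator = c("communities", "nodes")) {
  pct_single_denominator <- match.arg(pct_single_denominator)
  if (is.null(partition)) partition <- louvain_partition(sin)
  memb <- as_membership_vector(sin, partition)
  sizes <- sort(as.integer(table(memb)), decreasing = TRUE)
  n_single <- sum(sizes == 1L)
  comp <- sin_components(sin)
  denom <- if (pct_single_denominator == "communities") length(sizes)
           else length(memb)
  data.frame(
    n_nodes = length(memb),
    n_communities = length(sizes),
    n_single_element = n_single,
    pct_single_element = 100 * n_single / denom,
    n_communities_without_single = sum(sizes > 1L),
    biggest_size = sizes[1],
    second_biggest_size = if (length(sizes) >= 2L) sizes[2] else NA_integer_,
    avg_size_without_single = if (any(sizes > 1L)) mean(sizes[sizes > 1L])
                              else NA_real_,
    n_components = comp$n_components,
    biggest_component_size = comp$sizes[1],
    modularity = if (igraph::ecount(sin$graph) > 0)
      sin_modularity(sin, partition) else NA_real_)
}

#' Write a partition and a community-coloured GEXF
#'
#' `write_partition()` stores the node-to-community assignment as CSV
#' (`fly_id,community`); `export_community_gexf()` writes the network in
#' GEXF with each node's community as a node attribute, ready for
#' community-coloured rendering in Gephi.
#'
#' @param partition A `sin_partition`.
#' @param path Output file.
#' @param sin A `sin` object.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  utils::write.csv(
    data.frame(fly_id = names(partition$membership),
               community = as.integer(partition$membership)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
export_community_gexf <- function(sin, partition, path) {
  memb <- as_membership_vector(sin, partition)
  write_gexf(sin, path, node_class = as.list(memb))
  invisible(path)
}
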