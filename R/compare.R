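#' Welch-corrected two-sample t-test
#'
#' Independent-samples t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), the test used throughout the
#' group comparisons because group sizes differ.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 2 finite
#'   values; at least one sample must have positive variance.
#' @return A list with `t`, `df` and two-sided `p`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
welch_t_test <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample needs at least 2 finite values", call. = FALSE)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b))
      return(list(t = 0, df = length(sample_a) + length(sample_b) - 2, p = 1))
    stop("both samples have zero variance; the Welch statistic is undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# one row of per-network summary values at the requested level
network_summary_row <- function(sin, level, local_stat) {
  switch(level,
    `local-medians` = {
      lt <- local_measure_table(sin)
      as.data.frame(t(if (local_stat == "median") lt$median else lt$mean))
    },
    global = global_summary(sin)[, -(1:2)],  # drop raw N, K counts
    middle = {
      cs <- community_stats(sin)
      cs[, c("n_communities", "n_single_element", "pct_single_element",
             "biggest_size", "second_biggest_size", "avg_size_without_single",
             "n_components", "biggest_component_size", "modularity")]
    })
}

#' Compare two populations of networks
#'
#' Runs one Welch-corrected t-test per measure between two groups of SINs
#' (e.g. control vs drug-fed), with the network as the unit of analysis.
#' At the local level each network is first reduced to its per-node median
#' (or mean) of every measure; at the global and middle levels the
#' per-network measure values are compared directly. Significance is
#' `p < alpha` per measure with no multiple-testing correction by
#' default (a Benjamini-Hochberg option is available).
#'
#' @param networks_a,networks_b Lists of `sin` objects, at least 2 each.
#' @param level `"local-medians"`, `"global"` or `"middle"`.
#' @param local_stat Per-network summary of local measures: `"median"`
#'   (default) or `"mean"`.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return A data.frame of class `sin_comparison` with one row per
#'   measure: `measure, mean_a, sd_a, mean_b, sd_b, t, df, p, significant`,
#'   plus attribute `n_dropped` counting per-measure network values
#'   dropped as undefined. Measures degenerate in both groups are reported
#'   with `NA` statistics.
#' @export
compare_measures <- function(networks_a, networks_b,
                             level = c("global", "local-medians", "middle"),
                             local_stat = c("median", "mean"),
                             alpha = 0.05, p_adjust = c("none", "BH")) {
  level <- match.arg(level)
  local_stat <- match.arg(local_stat)
  p_adjust <- match.arg(p_adjust)
  if (length(networks_a) < 2L || length(networks_b) < 2L)
    stop("need at least 2 networks per group", call. = FALSE)
  rows_a <- do.call(rbind, lapply(networks_a, network_summary_row,
                                  level = level, local_stat = local_stat))
  rows_b <- do.call(rbind, lapply(networks_b, network_summary_row,
                                  level = level, local_stat = local_stat))
  dropped <- integer(0)
  out <- do.call(rbind, lapply(names(rows_a), function(m) {
    a <- rows_a[[m]][is.finite(rows_a[[m]])]
    b <- rows_b[[m]][is.finite(rows_b[[m]])]
    dropped[[m]] <<- (nrow(rows_a) - length(a)) + (nrow(rows_b) - length(b))
    res <- tryCatch(welch_t_test(a, b),
                    error = function(e) list(t = NA_real_, df = NA_real_,
                                             p = NA_real_))
    data.frame(measure = m,
               mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               t = res$t, df = res$df, p = res$p,
               stringsAsFactors = FALSE)
  }))
  if (p_adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  class(out) <- c("sin_comparison", "data.frame")
  out
}

#' Correlation matrix of local measures
#'
#' Pearson correlations between the local measures, pooling flies across
#' a population of networks (the per-fly rows of every network stacked
#' together). Entries are `NA` when a measure is constant over the pool.
#'
#' @param networks List of `sin` objects (pooled rows must cover at least
#'   3 flies).
#' @return A symmetric correlation matrix with unit diagonal over the
#'   columns of [local_measure_table()].
#' @export
measure_correlations <- function(networks) {
  pooled <- do.call(rbind, lapply(networks,
                                  function(s) local_measure_table(s)$per_node))
  if (nrow(pooled) < 3L)
    stop("need at least 3 pooled flies for correlations", call. = FALSE)
  x <- as.matrix(pooled[, -1, drop = FALSE])
  keep_sd <- apply(x, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[keep_sd == 0, ] <- NA_real_
  r[, keep_sd == 0] <- NA_real_
  diag(r) <- 1
  r
}

#' Arena occupancy heat map
#'
#' Bins every observed fly position of one or more recordings onto a
#' `grid_cells x grid_cells` grid covering the arena's bounding square.
#' Each entry counts fly-frames spent in that cell, so the matrix sums to
#' the total number of observed positions; cells lying entirely outside
#' the arena disc (which can never receive mass) are `NA`.
#'
#' @param trajs A [trajectory_table()] or a list of them (same arena
#'   geometry).
#' @param grid_cells Number of cells per axis (default 60, i.e. 2 mm
#'   cells for the standard arena).
#' @return A `grid_cells x grid_cells` numeric matrix; rows index y (from
#'   -radius to +radius), columns x.
#' @export
occupancy_heatmap <- function(trajs, grid_cells = 60) {
  if (inherits(trajs, "trajectory_table")) trajs <- list(trajs)
  if (grid_cells < 2) stop("`grid_cells` must be >= 2", call. = FALSE)
  radius <- if (length(trajs)) trajs[[1]]$arena$radius_mm else 60
  breaks <- seq(-radius, radius, length.out = grid_cells + 1L)
  h <- matrix(0, grid_cells, grid_cells)
  for (tr in trajs) {
    d <- tr$data
    ok <- is.finite(d$x) & is.finite(d$y)
    ix <- pmin(pmax(findInterval(d$x[ok], breaks, rightmost.closed = TRUE),
                    1L), grid_cells)
    iy <- pmin(pmax(findInterval(d$y[ok], breaks, rightmost.closed = TRUE),
                    1L), grid_cells)
    for (k in seq_along(ix)) h[iy[k], ix[k]] <- h[iy[k], ix[k]] + 1
  }
  # mask cells with no point closer to the centre than the radius
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  half <- diff(breaks[1:2]) / 2
  nearest_x <- pmax(abs(mids) - half, 0)
  corner <- outer(nearest_x^2, nearest_x^2, "+")  # [y, x] squared distance
  h[corner > radius^2] <- NA_real_
  h
}
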