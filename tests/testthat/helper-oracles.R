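# Brute-force oracles, independent of the package's igraph-backed paths.
# All operate on a plain symmetric adjacency matrix (0/1 or weights).

sin_adjacency <- function(sin, weight = "none") {
  ids <- sin_nodes(sin)
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- sin_edges(sin)
  if (nrow(e)) {
    w <- switch(weight, none = rep(1, nrow(e)), count = e$w_count,
                duration = e$w_duration)
    for (i in seq_len(nrow(e))) {
      A[e$fly_a[i], e$fly_b[i]] <- w[i]
      A[e$fly_b[i], e$fly_a[i]] <- w[i]
    }
  }
  A
}

# all-pairs hop distances by Floyd-Warshall
bf_distances <- function(A) {
  n <- nrow(A)
  d <- ifelse(A > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# membership of the largest connected component (ties: first found)
bf_largest_component <- function(A) {
  d <- bf_distances(A)
  n <- nrow(A)
  seen <- rep(FALSE, n)
  best <- integer(0)
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- which(is.finite(d[i, ]))
    seen[comp] <- TRUE
    if (length(comp) > length(best)) best <- comp
  }
  best
}

# number of shortest paths between every pair (unweighted)
bf_path_counts <- function(A, d) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (v in ord) {
      if (v == s || !is.finite(d[s, v])) next
      pred <- which(A[, v] > 0 & d[s, ] == d[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  sigma
}

# normalized betweenness on a connected adjacency matrix
bf_betweenness <- function(A) {
  n <- nrow(A)
  if (n < 3) return(rep(0, n))
  d <- bf_distances(A)
  sigma <- bf_path_counts(A, d)
  bc <- numeric(n)
  for (i in seq_len(n)) {
    tot <- 0
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      if (j == i || k == i || !is.finite(d[j, k])) next
      if (is.finite(d[j, i]) && is.finite(d[i, k]) &&
          d[j, i] + d[i, k] == d[j, k])
        tot <- tot + sigma[j, i] * sigma[i, k] / sigma[j, k]
    }
    bc[i] <- tot / ((n - 1) * (n - 2) / 2)
  }
  bc
}

bf_closeness <- function(A) {
  n <- nrow(A)
  d <- bf_distances(A)
  vapply(seq_len(n), function(i) (n - 1) / sum(d[i, -i]), numeric(1))
}

bf_local_clustering <- function(A) {
  n <- nrow(A)
  B <- A > 0
  vapply(seq_len(n), function(i) {
    nb <- which(B[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(B[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
}

bf_transitivity <- function(A) {
  B <- (A > 0) + 0
  triangles <- sum(diag(B %*% B %*% B)) / 6
  k <- rowSums(B)
  triads <- sum(k * (k - 1) / 2)
  if (triads == 0) 0 else 3 * triangles / triads
}

bf_avg_path <- function(A) {
  d <- bf_distances(A)
  mean(d[row(d) != col(d)])
}

bf_efficiency <- function(A) {
  d <- bf_distances(A)
  mean(1 / d[row(d) != col(d)])
}

bf_heterogeneity <- function(A) {
  k <- rowSums(A > 0)
  sqrt(mean((k - mean(k))^2)) / mean(k)
}

# Pearson correlation of excess degrees over edge endpoints (both
# orientations)
bf_assortativity <- function(A) {
  k <- rowSums(A > 0)
  e <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  xs <- c(k[e[, 1]], k[e[, 2]]) - 1
  ys <- c(k[e[, 2]], k[e[, 1]]) - 1
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

# effective resistance between node 1-grounded linear solves (independent
# of the pseudoinverse route used by the package)
bf_effective_resistance <- function(A, i, j) {
  L <- diag(rowSums(A)) - A
  b <- rep(0, nrow(A)); b[i] <- 1; b[j] <- -1
  x <- c(0, solve(L[-1, -1], b[-1]))
  x[i] - x[j]
}

# modularity by edge-by-edge accumulation (independent of the e_ii/a_i
# grouping used by the package)
bf_modularity <- function(A, memb) {
  w <- A[upper.tri(A)]
  m <- sum(w)
  e <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  q <- 0
  for (r in seq_len(nrow(e)))
    if (memb[e[r, 1]] == memb[e[r, 2]]) q <- q + A[e[r, 1], e[r, 2]] / m
  deg_w <- rowSums(A)
  for (g in unique(memb))
    q <- q - (sum(deg_w[memb == g]) / (2 * m))^2
  q
}

# frame-scan interaction detector: naive per-pair state machine
bf_detect_events <- function(traj, criteria) {
  ids <- traj$roster
  fps <- traj$arena$fps
  min_frames <- ceiling(criteria$min_duration_s * fps - 1e-9)
  thr <- criteria$distance_threshold_bl * criteria$body_length_mm
  out <- list()
  for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
    dser <- pairwise_distance_series(traj, ids[i], ids[j])
    state <- ifelse(is.na(dser), "miss", ifelse(dser <= thr, "in", "out"))
    runs <- list()
    f <- 1
    while (f <= length(state)) {
      if (state[f] == "in") {
        g <- f
        while (g < length(state) && state[g + 1] == "in") g <- g + 1
        runs[[length(runs) + 1]] <- c(f, g)
        f <- g + 1
      } else f <- f + 1
    }
    # bridge all-out gaps <= tolerance
    if (criteria$gap_tolerance_frames > 0 && length(runs) > 1) {
      merged <- list(runs[[1]])
      for (r in runs[-1]) {
        last <- merged[[length(merged)]]
        gap <- (last[2] + 1):(r[1] - 1)
        if (length(gap) <= criteria$gap_tolerance_frames &&
            all(state[gap] == "out")) {
          merged[[length(merged)]][2] <- r[2]
        } else merged[[length(merged) + 1]] <- r
      }
      runs <- merged
    }
    for (r in runs) {
      len <- r[2] - r[1] + 1
      if (len >= min_frames)
        out[[length(out) + 1]] <- data.frame(
          fly_a = ids[i], fly_b = ids[j],
          start_frame = r[1] - 1L, end_frame = r[2],
          duration_s = len / fps, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(fly_a = character(), fly_b = character(),
                      start_frame = integer(), end_frame = integer(),
                      duration_s = numeric(), stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, out)
  ev[order(ev$fly_a, ev$fly_b, ev$start_frame), ]
}

# small trajectory builder: one row per fly per frame from coordinate lists
make_traj <- function(coords, fps = 24, radius = 60) {
  rows <- do.call(rbind, lapply(names(coords), function(id) {
    m <- coords[[id]]
    data.frame(fly_id = id, frame = seq_len(nrow(m)) - 1L,
               x = m[, 1], y = m[, 2], stringsAsFactors = FALSE)
  }))
  trajectory_table(rows, arena_spec(radius_mm = radius, fps = fps))
}

# random trajectories for property tests: bounded random walks
random_traj <- function(n_flies, n_frames, seed, radius = 20, fps = 24) {
  withr::with_seed(seed, {
    coords <- lapply(seq_len(n_flies), function(i) {
      x <- cumsum(c(stats::runif(1, -10, 10), stats::rnorm(n_frames - 1, 0, 1.5)))
      y <- cumsum(c(stats::runif(1, -10, 10), stats::rnorm(n_frames - 1, 0, 1.5)))
      cbind(pmax(pmin(x, radius), -radius), pmax(pmin(y, radius), -radius))
    })
    names(coords) <- sprintf("f%02d", seq_len(n_flies))
    make_traj(coords, fps = fps, radius = radius)
  })
}

expect_sin_equal <- function(a, b) {
  expect_identical(sin_nodes(a), sin_nodes(b))
  ea <- sin_edges(a); eb <- sin_edges(b)
  expect_equal(ea$fly_a, eb$fly_a)
  expect_equal(ea$fly_b, eb$fly_b)
  expect_equal(ea$w_count, eb$w_count)
  expect_equal(ea$w_duration, eb$w_duration, tolerance = 1e-12)
}
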