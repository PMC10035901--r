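#' Simulation configuration
#'
#' Parameterises the synthetic arena: a group of flies performing a
#' correlated random walk on the arena disc, with a wall-following
#' (thigmotaxis) bias, social attraction towards perceived neighbours,
#' social dwell (pausing while near another fly, which lengthens
#' interactions), and a fraction of immobile individuals that never move
#' (emulating isolated, non-interacting flies). The defaults mirror the
#' standard recording design: 30 flies, 120 mm arena, 24 fps, 10 minutes.
#'
#' @param n_flies Number of flies (default 30).
#' @param arena An [arena_spec()] (default 60 mm radius, 24 fps).
#' @param duration_s Recording length in seconds (default 600).
#' @param step_speed_mean,step_speed_sd Step length distribution in
#'   mm/frame during walking bouts (defaults 0.3 and 0.1, i.e. about
#'   7 mm/s at 24 fps, a typical walking speed).
#' @param heading_persistence Weight of the previous heading in the
#'   heading update, in `[0, 1]` (default 0.9).
#' @param heading_noise_sd Circular noise added to the heading each frame,
#'   radians (default 0.25).
#' @param thigmotaxis_bias Weight of the outward (wall-seeking) pull, in
#'   `[0, 1]` (default 0.25).
#' @param attraction Weight of the pull towards the centroid of perceived
#'   neighbours, `>= 0` (default 0.5).
#' @param perception_radius_mm Radius within which other flies are
#'   perceived and attract (default 8 mm).
#' @param repulsion_radius_mm Personal-space radius (default 5 mm): a
#'   walking fly with a neighbour this close either stops to interact
#'   (see `pause_prob`) or turns away and disengages.
#' @param pause_prob Per-frame probability of pausing when at least one
#'   neighbour is within perception range — the social dwell that
#'   stretches interaction episodes (default 0.1).
#' @param activity Fraction of time a mobile fly spends in walking bouts
#'   (default 0.25): flies alternate between walking and standing bouts
#'   with mean bout length `bout_mean_s`, matching the intermittent
#'   locomotion of real flies rather than continuous travel.
#' @param bout_mean_s Mean length of a walking or standing bout in
#'   seconds (default 2).
#' @param immobile_fraction Fraction of flies that never move (default
#'   0.05).
#' @param seed Integer seed; every random draw of the simulation comes
#'   from one generator seeded with it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_flies = 30, arena = arena_spec(), duration_s = 600,
                       step_speed_mean = 0.3, step_speed_sd = 0.1,
                       heading_persistence = 0.9, heading_noise_sd = 0.3,
                       thigmotaxis_bias = 0.15, attraction = 0.2,
                       perception_radius_mm = 8, repulsion_radius_mm = 5,
                       pause_prob = 0.1,
                       activity = 0.25, bout_mean_s = 2,
                       immobile_fraction = 0.05, seed = 1L) {
  cfg <- list(n_flies = as.integer(n_flies), arena = arena,
              duration_s = duration_s, step_speed_mean = step_speed_mean,
              step_speed_sd = step_speed_sd,
              heading_persistence = heading_persistence,
              heading_noise_sd = heading_noise_sd,
              thigmotaxis_bias = thigmotaxis_bias, attraction = attraction,
              perception_radius_mm = perception_radius_mm,
              repulsion_radius_mm = repulsion_radius_mm,
              pause_prob = pause_prob, activity = activity,
              bout_mean_s = bout_mean_s,
              immobile_fraction = immobile_fraction,
              seed = as.integer(seed))
  for (p in c("heading_persistence", "thigmotaxis_bias", "pause_prob",
              "activity", "immobile_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("`", p, "` must be in [0, 1]", call. = FALSE)
  }
  if (cfg$n_flies < 1L) stop("`n_flies` must be >= 1", call. = FALSE)
  if (cfg$attraction < 0) stop("`attraction` must be >= 0", call. = FALSE)
  if (cfg$duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Population presets
#'
#' Two ready-made configurations emulating the contrast between an
#' untreated population and a psychostimulant-fed one: `"ctrl_like"` has
#' moderate social attraction, little dwell and few immobile flies;
#' `"coc_like"` has stronger attraction, much longer dwell near other
#' flies (so interactions last longer and groups compact) and more
#' immobile, isolated individuals.
#'
#' @param name `"ctrl_like"` or `"coc_like"`.
#' @param seed Seed stored in the returned config.
#' @return A [sim_config()].
#' @export
preset <- function(name = c("ctrl_like", "coc_like"), seed = 1L) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("ctrl_like", "coc_like"))
    stop("unknown preset: ", paste(name, collapse = ", "), call. = FALSE)
  switch(name,
    ctrl_like = sim_config(activity = 0.2, attraction = 0.1,
                           pause_prob = 0.1, immobile_fraction = 0.03,
                           seed = seed),
    coc_like = sim_config(activity = 0.3, attraction = 0.3,
                          pause_prob = 0.25, immobile_fraction = 0.22,
                          seed = seed))
}

#' Simulate a group recording
#'
#' Runs the correlated random walk defined by a [sim_config()]: each
#' mobile fly updates its heading as a weighted combination of its
#' previous heading, an outward wall pull, and the direction towards the
#' centroid of neighbours within perception range, plus circular noise;
#' it then advances one step, or pauses (social dwell) with probability
#' `pause_prob` when a neighbour is in range. The arena boundary is
#' reflective, so positions always satisfy `x^2 + y^2 <= radius^2`.
#' Immobile flies emit a constant position. Fully reproducible given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A [trajectory_table()] with ids `fly_01`, `fly_02`, ... and one
#'   row per fly and frame.
#' @export
simulate_arena <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_flies
  R <- config$arena$radius_mm
  n_frames <- as.integer(round(config$duration_s * config$arena$fps))
  withr::with_seed(config$seed, {
    n_imm <- round(config$immobile_fraction * n)
    immobile <- seq_len(n) %in% sample.int(n, n_imm)
    # start positions uniform over the disc (slightly inside the wall)
    r0 <- 0.95 * R * sqrt(stats::runif(n))
    th0 <- stats::runif(n, 0, 2 * pi)
    x <- r0 * cos(th0); y <- r0 * sin(th0)
    h <- stats::runif(n, 0, 2 * pi)
    X <- matrix(NA_real_, n_frames, n)
    Y <- matrix(NA_real_, n_frames, n)
    X[1, ] <- x; Y[1, ] <- y
    mob <- which(!immobile)
    # two-state bout kinetics: walking <-> standing; mean walking bout
    # bout_mean_s, stationary walking fraction = activity
    p_stop <- min(1, 1 / (config$bout_mean_s * config$arena$fps))
    p_go <- if (config$activity >= 1) 1
            else p_stop * config$activity / (1 - config$activity)
    walking <- stats::runif(n) < config$activity
    for (f in seq_len(n_frames - 1L)) {
      if (length(mob)) {
        dx <- outer(x, x[mob], "-")   # n x n_mob: x_i - x_j (j mobile)
        dy <- outer(y, y[mob], "-")
        d <- sqrt(dx^2 + dy^2)
        d[cbind(mob, seq_along(mob))] <- Inf  # self
        close <- d <= config$repulsion_radius_mm
        near <- d <= config$perception_radius_mm & !close
        any_close <- colSums(close) > 0
        # unit pull towards the centroid of perceived neighbours
        # (dx[i, j] = x_i - x_j points from mobile fly j towards fly i)
        ax <- colSums(dx * near); ay <- colSums(dy * near)
        nrm <- sqrt(ax^2 + ay^2)
        ax <- ifelse(nrm > 0, ax / nrm, 0)
        ay <- ifelse(nrm > 0, ay / nrm, 0)
        # unit push away from close neighbours (social spacing: a walking
        # fly that does not stop to interact turns away and disengages)
        rx <- -colSums(dx * close); ry <- -colSums(dy * close)
        rnrm <- sqrt(rx^2 + ry^2)
        rx <- ifelse(rnrm > 0, rx / rnrm, 0)
        ry <- ifelse(rnrm > 0, ry / rnrm, 0)
        # outward wall pull
        r <- sqrt(x[mob]^2 + y[mob]^2)
        wx <- ifelse(r > 0, x[mob] / r, 0)
        wy <- ifelse(r > 0, y[mob] / r, 0)
        # bout transitions with social modulation: pause_prob scales how
        # readily a walker stops next to a neighbour and how long a
        # stander dwells there; without dwell a stander with a close
        # neighbour is aroused and walks off (social spacing)
        wmob <- walking[mob]
        u <- stats::runif(length(mob))
        p_stop_eff <- p_stop + any_close * config$pause_prob / 12
        arouse <- 0.04  # per-frame leave rate when crowded, ~1 s dwell
        p_go_eff <- ifelse(any_close,
                           pmax(p_go, arouse) * (1 - config$pause_prob),
                           p_go)
        stop_now <- wmob & u < p_stop_eff
        go_now <- !wmob & u < p_go_eff
        walking[mob][stop_now] <- FALSE
        walking[mob][go_now] <- TRUE
        # a fly that stops because of a neighbour closes in to body
        # contact (~2.5 mm) before standing — the touch that makes the
        # pair register as interacting
        touch <- which(stop_now & any_close)
        for (j in touch) {
          i <- which.min(d[, j])
          gap <- d[i, j]
          if (is.finite(gap) && gap > 2.5) {
            f_to <- c(x[mob[j]] - x[i], y[mob[j]] - y[i]) / gap
            px <- x[i] + 2.5 * f_to[1]
            py <- y[i] + 2.5 * f_to[2]
            pr <- sqrt(px^2 + py^2)
            if (pr > R) { px <- px * R / pr; py <- py * R / pr }
            x[mob[j]] <- px
            y[mob[j]] <- py
          }
        }
        wmob <- walking[mob]
        ux <- config$heading_persistence * cos(h[mob]) +
          config$thigmotaxis_bias * wx + config$attraction * ax + 1.2 * rx
        uy <- config$heading_persistence * sin(h[mob]) +
          config$thigmotaxis_bias * wy + config$attraction * ay + 1.2 * ry
        h[mob] <- atan2(uy, ux) +
          stats::rnorm(length(mob), 0, config$heading_noise_sd)
        step <- pmax(stats::rnorm(length(mob), config$step_speed_mean,
                                  config$step_speed_sd), 0)
        step[!wmob] <- 0
        nx <- x[mob] + step * cos(h[mob])
        ny <- y[mob] + step * sin(h[mob])
        # reflective boundary: fold the radial overshoot back inside and
        # turn the fly towards where it actually ended up
        rn <- sqrt(nx^2 + ny^2)
        out <- rn > R
        if (any(out)) {
          scale <- (2 * R - rn[out]) / rn[out]
          scale[scale < 0] <- 0
          refx <- nx[out] * scale; refy <- ny[out] * scale
          h[mob][out] <- atan2(refy - y[mob][out], refx - x[mob][out])
          nx[out] <- refx; ny[out] <- refy
        }
        x[mob] <- nx; y[mob] <- ny
      }
      X[f + 1L, ] <- x; Y[f + 1L, ] <- y
    }
    ids <- sprintf("fly_%02d", seq_len(n))
    trajectory_table(
      data.frame(fly_id = rep(ids, each = n_frames),
                 frame = rep(seq_len(n_frames) - 1L, n),
                 x = as.vector(X), y = as.vector(Y),
                 stringsAsFactors = FALSE),
      config$arena)
  })
}

#' Canonical graph fixtures
#'
#' Small SINs with unit edge weights and known measure values, used to
#' exercise and validate the network measures: `path3` (A-B-C), `star5`
#' (hub plus 4 leaves), `k3`, `k5`, `cycle6`, `two_triangles` (two
#' disjoint K3s), `k5_plus_isolates` (a K5 together with 5 isolated
#' nodes), and `random` (Erdos-Renyi `G(n, p)`, reproducible given
#' `seed`).
#'
#' @param name Fixture name (see above).
#' @param n,p,seed Parameters of the `random` fixture.
#' @return A `sin` object with `w_count = 1` and `w_duration = 1` on every
#'   edge.
#' @export
graph_fixture <- function(name = c("path3", "star5", "k3", "k5", "cycle6",
                                   "two_triangles", "k5_plus_isolates",
                                   "random"),
                          n = 8, p = 0.3, seed = 1L) {
  if (!is.character(name) || length(name) != 1L)
    stop("`name` must be a single fixture name", call. = FALSE)
  name <- match.arg(name)
  pairs <- switch(name,
    path3 = list(c("A", "B"), c("B", "C")),
    star5 = list(c("H", "L1"), c("H", "L2"), c("H", "L3"), c("H", "L4")),
    k3 = utils::combn(LETTERS[1:3], 2, simplify = FALSE),
    k5 = utils::combn(LETTERS[1:5], 2, simplify = FALSE),
    cycle6 = lapply(1:6, function(i) c(sprintf("N%d", i),
                                       sprintf("N%d", i %% 6 + 1))),
    two_triangles = c(utils::combn(c("A1", "A2", "A3"), 2, simplify = FALSE),
                      utils::combn(c("B1", "B2", "B3"), 2, simplify = FALSE)),
    k5_plus_isolates = utils::combn(LETTERS[1:5], 2, simplify = FALSE),
    random = withr::with_seed(seed, {
      all_pairs <- utils::combn(sprintf("N%02d", seq_len(n)), 2,
                                simplify = FALSE)
      all_pairs[stats::runif(length(all_pairs)) < p]
    }))
  roster <- switch(name,
    k5_plus_isolates = c(LETTERS[1:5], paste0("iso", 1:5)),
    random = sprintf("N%02d", seq_len(n)),
    sort(unique(unlist(pairs))))
  if (length(pairs)) {
    ev <- data.frame(fly_a = vapply(pairs, `[`, "", 1),
                     fly_b = vapply(pairs, `[`, "", 2),
                     duration_s = 1, stringsAsFactors = FALSE)
  } else {
    ev <- data.frame(fly_a = character(), fly_b = character(),
                     duration_s = numeric(), stringsAsFactors = FALSE)
  }
  build_sin(ev, roster = roster, label = name, fps = 24)
}
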