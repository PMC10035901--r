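two_fly_traj <- function(dists, fps = 24) {
  make_traj(list(A = cbind(rep(0, length(dists)), 0),
                 B = cbind(dists, 0)), fps = fps)
}

test_that("distance and duration criteria gate event emission", {
  # 24 frames at 3 mm -> one event of 1 s
  ev <- detect_events(two_fly_traj(rep(3, 24)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_s, 1)
  # 10 frames (0.417 s) -> below the minimum duration
  expect_equal(nrow(detect_events(two_fly_traj(rep(3, 10)))), 0L)
  # always beyond 4 mm -> nothing
  expect_equal(nrow(detect_events(two_fly_traj(rep(4.5, 50)))), 0L)
  # exactly 12 frames = 0.5 s qualifies (inclusive threshold)
  expect_equal(nrow(detect_events(two_fly_traj(rep(3, 12)))), 1L)
})

test_that("gap tolerance fuses runs split by a brief excursion", {
  dists <- c(rep(3, 20), rep(6, 2), rep(3, 20))
  tr <- two_fly_traj(dists)
  ev0 <- detect_events(tr, interaction_criteria(gap_tolerance_frames = 0))
  expect_equal(nrow(ev0), 2L)
  expect_equal(ev0$start_frame, c(0L, 22L))
  ev2 <- detect_events(tr, interaction_criteria(gap_tolerance_frames = 2))
  expect_equal(nrow(ev2), 1L)
  expect_equal(c(ev2$start_frame, ev2$end_frame), c(0L, 42L))
})

test_that("missing frames break runs even with gap tolerance", {
  dists <- rep(3, 40)
  tr <- two_fly_traj(dists)
  d <- tr$data
  d <- d[!(d$fly_id == "B" & d$frame %in% 19:20), ]
  tr2 <- trajectory_table(d, tr$arena)
  ev <- detect_events(tr2, interaction_criteria(gap_tolerance_frames = 5))
  expect_equal(nrow(ev), 2L)
})

test_that("merge_events fuses close events and is idempotent", {
  ev <- detect_events(two_fly_traj(c(rep(3, 20), rep(6, 2), rep(3, 20))))
  m <- merge_events(ev, 2)
  expect_equal(nrow(m), 1L)
  expect_equal(m$duration_s, (42 - 0) / 24)
  expect_equal(merge_events(m, 2), m)
  expect_equal(merge_events(ev, 0), ev)
  expect_error(merge_events(ev, -1), "gap_tolerance")
  empty <- detect_events(two_fly_traj(rep(10, 30)))
  expect_equal(nrow(merge_events(empty, 3)), 0L)
})

test_that("per-fly body length column overrides the fixed body length", {
  tr <- two_fly_traj(rep(5, 24))  # 5 mm apart: outside 2 x 2 mm
  expect_equal(nrow(detect_events(tr)), 0L)
  tr$data$body_length <- ifelse(tr$data$fly_id == "A", 3, 2.5)
  # mean body length 2.75 -> threshold 5.5 mm: now interacting
  expect_equal(nrow(detect_events(tr)), 1L)
})

test_that("events summary sums counts and durations per pair", {
  ev <- data.frame(fly_a = c("A", "A", "A"), fly_b = c("B", "B", "C"),
                   start_frame = c(0L, 50L, 0L), end_frame = c(24L, 98L, 14L),
                   duration_s = c(1, 2, 0.6))
  attr(ev, "fps") <- 24
  s <- events_summary(ev)
  expect_equal(s$pairs$n_events, c(2L, 1L))
  expect_equal(s$pairs$total_duration_s, c(3, 0.6))
  expect_equal(s$totals$n_events, 3L)
  expect_equal(s$totals$total_duration_s, 3.6)
  e0 <- events_summary(detect_events(two_fly_traj(rep(9, 20))))
  expect_equal(nrow(e0$pairs), 0L)
  expect_equal(e0$totals$total_duration_s, 0)
})

test_that("detector equals the frame-scan oracle on random trajectories", {
  settings <- list(
    interaction_criteria(),
    interaction_criteria(min_duration_s = 0.25),
    interaction_criteria(min_duration_s = 1),
    interaction_criteria(distance_threshold_bl = 1),
    interaction_criteria(distance_threshold_bl = 3, min_duration_s = 0.75),
    interaction_criteria(gap_tolerance_frames = 3))
  for (rep_i in 1:20) {
    tr <- random_traj(5, 200, seed = 1000 + rep_i)
    for (cr in settings) {
      got <- detect_events(tr, cr)
      want <- bf_detect_events(tr, cr)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(got$fly_a, want$fly_a)
        expect_equal(got$start_frame, want$start_frame)
        expect_equal(got$end_frame, want$end_frame)
      }
    }
  }
})

test_that("thresholds are monotone and time reversal preserves durations", {
  for (s in 1:5) {
    tr <- random_traj(4, 150, seed = 2000 + s)
    base <- detect_events(tr, interaction_criteria())
    wider <- detect_events(tr, interaction_criteria(distance_threshold_bl = 3))
    shorter <- detect_events(tr, interaction_criteria(min_duration_s = 0.25))
    expect_gte(nrow(wider), nrow(base))
    expect_gte(nrow(shorter), nrow(base))
    expect_true(all(base$duration_s >= 0.5 - 1e-12))
    # reverse time
    d <- tr$data
    d$frame <- max(d$frame) - d$frame
    rev_tr <- trajectory_table(d, tr$arena)
    rev_ev <- detect_events(rev_tr, interaction_criteria())
    expect_equal(sort(rev_ev$duration_s), sort(base$duration_s))
  }
})

test_that("events survive a CSV round trip", {
  ev <- detect_events(two_fly_traj(rep(3, 30)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, f)
  back <- read_events(f)
  expect_equal(attr(back, "fps"), 24)
  expect_equal(back$start_frame, ev$start_frame)
  expect_equal(back$duration_s, ev$duration_s)
})
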