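rc <- residence_config(radius = 0.23, min_frames = 3, frame_interval = 0.041)

test_that("hand-traceable static intervals are found exactly", {
  # all points identical: one interval spanning the whole track
  ts <- make_track(0:11, rep(0, 12), rep(0, 12))
  iv <- find_static_intervals(ts, rc)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$n_frames, 12L)
  expect_equal(iv$duration, 12 * 0.041)

  # alternating between two points 1 um apart: nothing within 0.23 um
  far <- make_track(0:9, rep(c(0, 1), 5), rep(0, 10))
  expect_equal(nrow(find_static_intervals(far, rc)), 0L)

  # frames 0-5 within 0.1 um of the origin, frames 6-9 scattered far apart
  mixed <- make_track(0:9,
                      c(0, 0.05, -0.05, 0.08, 0.02, -0.06, 1, 2, 3, 4),
                      c(0, 0.04, 0.06, -0.05, -0.08, 0.03, 5, -5, 9, -9))
  iv2 <- find_static_intervals(mixed, rc)
  expect_equal(nrow(iv2), 1L)
  expect_equal(iv2$start_frame, 0L)
  expect_equal(iv2$end_frame, 5L)
  expect_equal(iv2$duration, 6 * 0.041)
})

test_that("frame gaps break static intervals", {
  gap <- make_track(c(0, 1, 2, 4, 5, 6), rep(0, 6), rep(0, 6))
  iv <- find_static_intervals(gap, rc)
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$start_frame, c(0L, 4L))
  expect_equal(iv$n_frames, c(3L, 3L))
})

test_that("selected intervals are disjoint and re-validate their predicate", {
  mdl <- diffusion_model(c(0, 0.51), c(0.5, 0.5),
                         switching = list(mean_static_dwell = 0.15,
                                          mean_mobile_dwell = 0.15))
  ts <- simulate_brownian_tracks(
    mdl, 60, cfg41(31, track_length_law = list(distribution = "fixed",
                                               mean = 30, min = 2)))
  for (tr in split(ts$tracks, ts$tracks$track_id)) {
    iv <- find_static_intervals(tr, rc)
    if (!nrow(iv)) next
    expect_gte(min(iv$n_frames), rc$min_frames)
    # non-overlap
    if (nrow(iv) > 1)
      expect_true(all(iv$start_frame[-1] > iv$end_frame[-nrow(iv)]))
    # every member point within radius of the anchor
    for (j in seq_len(nrow(iv))) {
      pts <- tr[tr$frame >= iv$start_frame[j] & tr$frame <= iv$end_frame[j], ]
      dist <- sqrt((pts$x - iv$anchor_x[j])^2 + (pts$y - iv$anchor_y[j])^2)
      expect_lte(max(dist), rc$radius + 1e-12)
    }
  }
})

test_that("residence summary pools intervals and reports ms", {
  ts <- simulate_brownian_tracks(
    diffusion_model(0), 30,
    cfg41(32, track_length_law = list(distribution = "fixed",
                                      mean = 5, min = 2)))
  rs <- residence_summary(ts, rc)
  expect_equal(rs$n_intervals, 30L)
  expect_equal(rs$mean_residence, 5 * 41)   # all-stationary, 5 frames
  expect_equal(tail(rs$cdf$cumulative_probability, 1), 1)
  expect_true(all(diff(rs$cdf$cumulative_probability) >= 0))

  # an empty pool is flagged, not an error
  mobile <- simulate_brownian_tracks(
    diffusion_model(30), 10,
    cfg41(33, track_length_law = list(distribution = "fixed",
                                      mean = 6, min = 2)))
  empty <- residence_summary(mobile, rc)
  expect_equal(empty$n_intervals, 0L)
})

test_that("restricting to long tracks shifts mean residence upward", {
  mdl <- diffusion_model(c(0, 0.51), c(0.5, 0.5),
                         switching = list(mean_static_dwell = 0.2,
                                          mean_mobile_dwell = 0.2))
  ts <- simulate_brownian_tracks(
    mdl, 1200,
    cfg41(34, track_length_law = list(distribution = "geometric",
                                      mean = 8, min = 3)))
  all_tracks <- residence_summary(ts, rc)
  long_only <- residence_summary(ts, rc, min_track_frames = 10)
  expect_gt(long_only$mean_residence, all_tracks$mean_residence)
})

test_that("two-state dwell recovery works after truncation correction", {
  mdl <- diffusion_model(c(0, 0.51), c(0.5, 0.5),
                         switching = list(mean_static_dwell = 0.2,
                                          mean_mobile_dwell = 0.2))
  ts <- simulate_brownian_tracks(
    mdl, 500,
    cfg41(35, track_length_law = list(distribution = "fixed",
                                      mean = 25, min = 2)))
  rs <- residence_summary(ts, rc)
  tau_hat <- correct_residence_truncation(rs, rc)
  expect_equal(tau_hat, 200, tolerance = 0.15)
})

test_that("KS comparison is exact for identical data and calibrated under the null", {
  a <- summary_from_durations(c(0.1, 0.2, 0.2, 0.3, 0.4, 0.5))
  same <- residence_cdf_compare(a, a)
  expect_equal(same$ks_statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(41)
  rej <- mean(replicate(300, {
    x <- summary_from_durations(rexp(60, 1 / 0.2))
    y <- summary_from_durations(rexp(60, 1 / 0.2))
    residence_cdf_compare(x, y)$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)

  # power at a Table-like contrast (200 ms vs 260 ms, realistic n)
  set.seed(42)
  pw <- mean(replicate(200, {
    x <- summary_from_durations(rexp(300, 1 / 0.2))
    y <- summary_from_durations(rexp(300, 1 / 0.26))
    residence_cdf_compare(x, y)$p_value < 0.05
  }))
  expect_gt(pw, 0.5)

  small <- summary_from_durations(c(0.1, 0.2, 0.3))
  expect_match(residence_cdf_compare(small, a)$warning, "unreliable")
})

test_that("stop_probability matches its closed form and a Monte-Carlo step fraction", {
  expect_equal(stop_probability(0, 0.041, 0.23), 1)
  expect_equal(stop_probability(0.5, 0.041, 0), 0)
  expect_equal(stop_probability(0.51, 0.041, 0.23),
               1 - exp(-0.23^2 / (4 * 0.51 * 0.041)))
  expect_error(stop_probability(-1, 0.041, 0.23), "domain")

  # Monte-Carlo oracle: fraction of 2D Gaussian steps shorter than r_max
  set.seed(51)
  n <- 2e5
  s <- sqrt(2 * 0.68 * 0.041)
  frac <- mean(sqrt(rnorm(n, 0, s)^2 + rnorm(n, 0, s)^2) < 0.23)
  p <- stop_probability(0.68, 0.041, 0.23)
  expect_equal(frac, p, tolerance = 3 * sqrt(p * (1 - p) / n) / p)
})

test_that("run_probability reproduces the hand-expanded terms", {
  expect_equal(run_probability(3, 0.4), 0.4^3)
  expect_equal(run_probability(4, 0.5), 0.1875)    # 2p^3(1-p) + p^4
  expect_equal(run_probability(5, 0.5), 0.21875)   # 3p^3q^2 + 3p^4q + p^5
  expect_equal(run_probability(2, 0.9), 0)         # too short
  expect_equal(run_probability(10, 1), 1)
  expect_equal(run_probability(10, 0), 0)
  # jumps convention evaluates at n - 1
  expect_equal(run_probability(4, 0.5, convention = "jumps"),
               run_probability(3, 0.5))
})

test_that("run_probability is monotone in n and p and stable at large n", {
  ps <- c(0.05, 0.2, 0.4, 0.6, 0.9)
  for (p in ps) {
    vals <- run_probability(3:200, p)
    expect_true(all(diff(vals) >= -1e-12))
    expect_true(all(vals >= 0 & vals <= 1))
  }
  for (n in c(5, 20, 100)) {
    byp <- vapply(ps, function(p) run_probability(n, p), numeric(1))
    expect_true(all(diff(byp) > 0))
  }
  expect_true(is.finite(run_probability(10000, 0.3777)))
  expect_lte(run_probability(10000, 0.3777), 1)
})

test_that("the combinatorial formula is exact for n <= 4 and undercounts beyond", {
  p <- 0.3777
  for (n in 3:4)
    expect_equal(run_probability(n, p), bernoulli_run_prob_enum(n, p),
                 tolerance = 1e-12)
  for (n in 5:12) {
    exact <- bernoulli_run_prob_enum(n, p)
    approxv <- run_probability(n, p)
    expect_lt(approxv, exact)              # documented undercount
    expect_equal(approxv, exact, tolerance = 0.35)  # but of the right order
  }
  # the enumeration oracle agrees with the O(n) DP oracle
  for (n in c(6, 9, 12))
    expect_equal(bernoulli_run_prob_enum(n, 0.5),
                 bernoulli_run_prob_dp(n, 0.5), tolerance = 1e-12)
})

test_that("false-positive limits behave as the model predicts", {
  expect_equal(false_positive_rate(c(2, 2, 2), 0.5, rc)$rate, 0)
  # d -> 0: every long-enough track is counted
  lens <- c(2, 3, 5, 8)
  expect_equal(false_positive_rate(lens, 1e-12, rc)$rate, 0.75,
               tolerance = 1e-6)
  # worked example: n = 5 at the whole-data D* of 0.68
  fp5 <- false_positive_rate(rep(5L, 3), 0.68, rc)
  expect_equal(fp5$p, 0.3777, tolerance = 1e-3)
  expect_equal(fp5$rate, run_probability(5, fp5$p))
  expect_equal(fp5$rate, 0.108, tolerance = 0.01)
})

test_that("Monte-Carlo mode approximates the analytic rate and decreases with d", {
  set.seed(61)
  lens <- 3 + rgeom(2000, 1 / 3.7)   # geometric, mean 5.7, min 3
  rate_an <- false_positive_rate(lens, 0.68, rc)$rate
  rate_mc <- false_positive_rate(lens, 0.68, rc, method = "monte-carlo",
                                 n_tracks_mc = 20000, seed = 62)$rate
  expect_lt(abs(rate_an - rate_mc), 0.02)
  # the Monte-Carlo rate decreases monotonically with d
  rates <- vapply(c(0.2, 0.68, 2, 8), function(d)
    false_positive_rate(lens, d, rc, method = "monte-carlo",
                        n_tracks_mc = 5000, seed = 63)$rate, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("the analytic rate bounds the exact moving-circle probability only for short tracks", {
  # exact moving-circle probability of an n-frame track: a DP over the
  # n - 1 jump indicators, the independent oracle for the Monte-Carlo mode
  p <- stop_probability(0.68, 0.041, 0.23)
  for (n in 4:6)
    expect_gte(run_probability(n, p), bernoulli_run_prob_dp(n - 1, p))
  # from n = 7 the formula's undercount outweighs the moving-circle
  # relaxation: the claimed overestimate no longer holds
  for (n in 7:12)
    expect_lt(run_probability(n, p), bernoulli_run_prob_dp(n - 1, p))
})

test_that("heat map peaks follow the geometric-series closed form", {
  single <- data.frame(x = 0, y = 0)
  hm1 <- heat_map(single)
  expect_equal(max(hm1$temperatures), 1.0, tolerance = 1e-9)

  for (k in c(3, 7, 12)) {
    still <- data.frame(x = rep(0.5, k), y = rep(-0.2, k))
    hmk <- heat_map(still, damping = 0.8)
    expect_equal(max(hmk$temperatures), (1 - 0.8^k) / (1 - 0.8),
                 tolerance = 1e-9)
  }

  # fast crossing: steps far exceed the mask sd, no heat accumulates
  fast <- data.frame(x = seq(0, 5, by = 0.5), y = rep(0, 11))
  hmf <- heat_map(fast, mask_sd = 0.08, damping = 0.8)
  expect_lt(max(hmf$temperatures), 1.01)
})

test_that("oversize heat-map grids are refused with advice", {
  long <- data.frame(x = c(0, 1000), y = c(0, 1000))
  expect_error(heat_map(long, grid_spacing = 0.02), "coarser")
})
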