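test_that("single normalization divides by the control and pre-bleach level", {
  # constant control, zero background, ROI halved at the bleach
  tr <- frap_trace(times = 0:9 / 10,
                   roi = c(1, 1, 1, rep(0.5, 7)),
                   background = rep(0, 10),
                   control_cell = rep(2, 10),
                   whole_cell = rep(2, 10),
                   bleach_index = 4L)
  nt <- single_normalize(tr)
  expect_equal(nt$values, c(1, 1, 1, rep(0.5, 7)))
  expect_equal(nt$times[4], 0)            # first post-bleach frame at t = 0
  expect_equal(mean(nt$values[1:3]), 1)   # pre-bleach mean is 1
})

test_that("a decay shared by ROI and control cancels exactly", {
  t <- 0:19 / 5
  decay <- exp(-0.3 * t)
  roi <- c(rep(1, 5), rep(0.4, 15)) * decay
  tr <- frap_trace(t, roi, rep(0, 20), control_cell = decay,
                   whole_cell = decay, bleach_index = 6L)
  nt <- single_normalize(tr)
  expect_equal(nt$values, c(rep(1, 5), rep(0.4, 15)), tolerance = 1e-12)
})

test_that("single normalization recovers the generator's plateau under acquisition bleaching", {
  tr <- simulate_frap_trace(0.85, 0.5, acquisition_bleach_rate = 0.01,
                            noise_sd = 0, n_pre = 10, n_post = 400,
                            config = cfg41(3))
  nt <- single_normalize(tr)
  expect_equal(tail(nt$values, 1), 0.85, tolerance = 1e-3)
})

test_that("degenerate control channels are rejected", {
  tr <- frap_trace(0:9 / 10, c(1, 1, rep(0.5, 8)), rep(0.6, 10),
                   control_cell = rep(0.5, 10), whole_cell = rep(2, 10),
                   bleach_index = 3L)
  expect_error(single_normalize(tr), "degenerate single")
})

test_that("double normalization of an unbleached trace is flat at 1", {
  t <- 0:9 / 10
  tr <- frap_trace(t, rep(3, 10), rep(1, 10), rep(4, 10), rep(5, 10),
                   bleach_index = 5L)
  nt <- double_normalize(tr)
  expect_equal(nt$values, rep(1, 10))
  expect_equal(nt$normalization_mode, "double")
})

test_that("double normalization exposes the immobile fraction", {
  for (q in c(0, 0.1, 0.2)) {
    tr <- simulate_frap_trace(1 - q, 0.4, noise_sd = 0, n_pre = 10,
                              n_post = 300, config = cfg41(4))
    fit <- fit_recovery(double_normalize(tr))
    expect_equal(fit$immobile_fraction, q, tolerance = 0.02)
  }
})

test_that("clustering averages identical traces to themselves", {
  tr <- simulate_frap_trace(0.9, 0.3, noise_sd = 0, n_pre = 5,
                            n_post = 50, config = cfg41(1))
  nts <- lapply(1:3, function(i) single_normalize(tr))
  cl <- cluster_traces(nts, 3)
  expect_length(cl, 1L)
  # identical traces: the average equals any single full-scale-normalized one
  one <- nts[[1]]
  post <- one$times >= 0
  mn <- min(one$values[post]); pm <- mean(one$values[!post])
  expect_equal(cl[[1]]$values, (one$values - mn) / (pm - mn))
  expect_equal(cl[[1]]$n_traces, 3L)
})

test_that("full-scale normalization aligns different bleach depths at zero", {
  nts <- lapply(c(0.3, 0.5, 0.7), function(b) {
    tr <- simulate_frap_trace(1, 0.5, bleach_depth = b, noise_sd = 0,
                              n_pre = 5, n_post = 100, config = cfg41(1))
    single_normalize(tr)
  })
  cl <- cluster_traces(nts, 3)
  first_post <- which(cl[[1]]$times >= 0)[1]
  expect_equal(cl[[1]]$values[first_post], 0, tolerance = 1e-9)
})

test_that("cluster partition keeps remainder pairs and drops singletons", {
  mk <- function(i) single_normalize(
    simulate_frap_trace(0.9, 0.3, noise_sd = 0.01, n_pre = 5, n_post = 50,
                        config = cfg41(i)))
  cl8 <- cluster_traces(lapply(1:8, mk), 3)
  expect_equal(vapply(cl8, `[[`, integer(1), "n_traces"), c(3L, 3L, 2L),
               ignore_attr = TRUE)
  expect_message(cl7 <- cluster_traces(lapply(1:7, mk), 3), "dropping")
  expect_equal(vapply(cl7, `[[`, integer(1), "n_traces"), c(3L, 3L),
               ignore_attr = TRUE)
})

test_that("traces of unequal length cannot be clustered", {
  a <- single_normalize(simulate_frap_trace(0.9, 0.3, n_pre = 5,
                                            n_post = 50, config = cfg41(1)))
  b <- single_normalize(simulate_frap_trace(0.9, 0.3, n_pre = 5,
                                            n_post = 60, config = cfg41(1)))
  expect_error(cluster_traces(list(a, b, a), 3), "alignment")
})

test_that("noiseless recovery fits are exact and t_half * k_r = ln 2", {
  cases <- list(c(A = 1, k = log(2)), c(A = 0.9, k = 0.2773),
                c(A = 0.7, k = 1.5))
  for (cs in cases) {
    t <- seq(0, 25, by = 0.041)
    nt <- structure(list(times = t, values = cs[["A"]] * (1 - exp(-cs[["k"]] * t)),
                         normalization_mode = "single",
                         prebleach_level = 1, n_pre = 0, n_traces = 1L),
                    class = "normalized_trace")
    fit <- fit_recovery(nt)
    expect_equal(fit$A, cs[["A"]], tolerance = 1e-6)
    expect_equal(fit$k_r, cs[["k"]], tolerance = 1e-6)
    expect_identical(fit$t_half, log(2) / fit$k_r)  # exact by construction
  }
  # the headline conversion: k_r = 0.2773 1/s corresponds to 2.50 s
  expect_equal(log(2) / 0.2773, 2.4996, tolerance = 1e-4)
})

test_that("half-time estimates are accurate on noisy single traces", {
  errs <- vapply(1:100, function(i) {
    tr <- simulate_frap_trace(0.9, 0.277, noise_sd = 0.03, n_pre = 10,
                              n_post = 488, config = cfg41(i))
    fit <- fit_recovery(single_normalize(tr))
    abs(fit$t_half - log(2) / 0.277) / (log(2) / 0.277)
  }, numeric(1))
  expect_lte(median(errs), 0.05)
})

test_that("summarize_halftimes does plain mean/SEM arithmetic", {
  mk <- function(th) structure(list(t_half = th), class = "frap_fit")
  same <- summarize_halftimes(list(mk(2), mk(2), mk(2)))
  expect_equal(same$sem, 0)
  s <- summarize_halftimes(list(mk(2), mk(3), mk(4)))
  expect_equal(s$mean, 3)
  expect_equal(s$sem, 0.5774, tolerance = 1e-4)
})

test_that("identical groups compare with p = 1", {
  cmp <- compare_halftimes(c(2.5, 2.5, 2.5), c(2.5, 2.5, 2.5))
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$t_statistic, 0)
})

test_that("the pooled t-test is calibrated and has power at Table-like effect sizes", {
  # type-I calibration: same-distribution groups reject at about 5%
  set.seed(1)
  rej <- mean(replicate(400, {
    compare_halftimes(rnorm(12, 2.5, 0.8), rnorm(12, 2.5, 0.8))$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)

  # power: half-times 2.5 s (n=32) vs 4.3 s (n=42) with SEM-consistent
  # spreads (sd = SEM * sqrt(n)); analytic power at alpha = 0.01 is 0.79,
  # so the empirical rate over 200 replicates stays well above 0.65
  set.seed(2)
  power <- mean(replicate(200, {
    a <- rnorm(32, 2.5, 0.3 * sqrt(32))
    b <- rnorm(42, 4.3, 0.4 * sqrt(42))
    compare_halftimes(a, b)$p_value < 0.01
  }))
  expect_gte(power, 0.65)
})
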