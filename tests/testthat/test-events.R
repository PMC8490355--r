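test_that("closed forms: fwhm and excluded_current", {
  expect_equal(fwhm(1, 1), 2 * sqrt(2 * log(2)), tolerance = 1e-12)
  expect_equal(fwhm(1, 1), 2.35482, tolerance = 1e-5)
  expect_equal(fwhm(1, 1e9), 2 * sqrt(2), tolerance = 1e-6)
  expect_equal(fwhm(4, 1), 2 * fwhm(1, 1), tolerance = 1e-12)
  expect_error(fwhm(-1, 1), "positive")
  expect_error(fwhm(1, 0), "positive")

  expect_equal(excluded_current(70, 100), 30)
  expect_equal(excluded_current(100, 100), 0)
  expect_equal(excluded_current(0, 100), 100)
  expect_error(excluded_current(50, 0), "positive")
})

test_that("fwhm is strictly increasing in sigma2 and beta", {
  s2 <- seq(0.5, 5, by = 0.5)
  expect_true(all(diff(fwhm(s2, 1.5)) > 0))
  b <- seq(0.5, 5, by = 0.25)
  expect_true(all(diff(vapply(b, function(x) fwhm(2, x), 1)) > 0))
})

test_that("estimate_baseline recovers level and spread", {
  # constant trace: spread floored at machine epsilon
  bl <- estimate_baseline(new_trace(rep(50, 1000), 50000), window_length = 500)
  expect_true(all(bl$level == 50))
  expect_true(all(bl$spread <= 1e-12))

  set.seed(5)
  tr <- new_trace(rnorm(50000, 100, 2), 50000)
  bl <- estimate_baseline(tr)
  expect_lt(max(abs(bl$level - 100)), 0.2)
  expect_lt(max(abs(bl$spread - 2)), 0.2)
})

test_that("median baseline resists 10% of samples at deep blockade", {
  set.seed(6)
  x <- rnorm(50000, 100, 2)
  block <- sample.int(50000, 5000)
  x[block] <- rnorm(5000, 30, 2)
  bl <- estimate_baseline(new_trace(x, 50000))
  expect_lt(max(abs(bl$level - 100)) / 100, 0.01)
})

test_that("threshold_search finds rectangular dips and nothing else", {
  x <- rep(100, 5000)
  x[2000:2100] <- 70  # 10x deeper than the 3 pA threshold below
  tr <- new_trace(x, 50000)
  bl <- tibble::tibble(level = rep(100, 5000), spread = rep(1, 5000))
  segs <- threshold_search(tr, bl, k = 3)
  expect_equal(nrow(segs), 1)
  expect_true(segs$core_start <= 2000 && segs$core_end >= 2100)
  expect_true(segs$start <= segs$core_start && segs$end >= segs$core_end)

  quiet <- threshold_search(new_trace(rep(100, 5000) + 0.1 * sin(1:5000), 50000),
                            bl, k = 3)
  expect_equal(nrow(quiet), 0)

  expect_error(
    threshold_search(new_trace(rep(100, 5000), 50000),
                     tibble::tibble(level = rep(100, 5000),
                                    spread = rep(0, 5000))),
    "flat"
  )
})

test_that("50 well-separated events yield exactly 50 segments", {
  set.seed(7)
  n <- 50
  rt <- render_trace(
    mus = (1:n) * 0.02, iex = rep(40, n), beta = runif(n, 1, 2.5),
    dwell = rep(0.002, n), duration = (n + 1) * 0.02
  )
  bl <- estimate_baseline(rt$trace)
  segs <- threshold_search(rt$trace, bl, k = 3, min_run = 5)
  expect_equal(nrow(segs), 50)
})

test_that("fit_gndf recovers its own noiseless output to high precision", {
  rate <- 50000
  t <- (0:400) / rate
  true <- list(mu = 0.004, sigma2 = (4e-4)^2, beta = 1, delta_ib = 30, i_o = 100)
  y <- true$i_o - true$delta_ib * gndf(t, true$mu, true$sigma2, true$beta)
  fit <- fit_gndf(y, t, level = 100, spread = 1)
  expect_true(fit$accepted)
  for (p in names(true)) {
    expect_equal(fit[[p]], true[[p]], tolerance = 1e-6)
  }
  expect_equal(fit$iex_pct, 30, tolerance = 1e-6)
})

test_that("fit_gndf recovers noisy flat-top parameters and flags spikes", {
  set.seed(8)
  rate <- 50000
  t <- (0:600) / rate
  y <- 100 - 30 * gndf(t, 0.006, (5e-4)^2, 1.5) + rnorm(length(t), 0, 1)
  fit <- fit_gndf(y, t, level = 100, spread = 1)
  expect_true(fit$accepted)
  expect_equal(fit$delta_ib, 30, tolerance = 0.02)
  expect_equal(fit$beta, 1.5, tolerance = 0.1)

  spike <- 100 - 30 * gndf(t, 0.006, (5e-4)^2, 0.5) + rnorm(length(t), 0, 1)
  sfit <- fit_gndf(spike, t, level = 100, spread = 1)
  expect_false(sfit$accepted)
  expect_equal(sfit$reject_reason, "beta_below_min")

  short <- fit_gndf(c(100, 70, 100), (0:2) / rate, level = 100, spread = 1)
  expect_false(short$accepted)
})

test_that("detection on simulated traces is near-complete and unbiased", {
  peps <- tibble::tibble(mass = c(700, 1100, 1500))
  cfg <- sim_config(
    duration = 15, event_rate = 8, beta_range = c(1, 3),
    dwell_median = 0.002, replicate_offset_sigma = 0, seed = 99,
    spacing = "even"
  )
  sim <- simulate_trace(peps, default_calibration(), cfg)
  ev <- detect_events(sim$trace)
  acc <- ev[ev$accepted, ]
  idx <- match_events(acc$mu, sim$truth$mu, tol = 0.005)
  expect_true(all(!is.na(idx)))
  # >= 95% of injected flat-top events detected and accepted
  expect_gte(length(unique(idx)) / nrow(sim$truth), 0.95)
  # recovered I_ex% unbiased to < 0.5 I_ex%
  err <- acc$iex_pct - sim$truth$iex_applied[idx]
  expect_lt(abs(mean(err)), 0.5)
})

test_that("an event-free trace produces no detections", {
  set.seed(12)
  tr <- new_trace(rnorm(2e5, 100, 2), 50000)
  expect_equal(nrow(detect_events(tr)), 0)
})
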