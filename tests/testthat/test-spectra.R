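test_that("build_spectrum bins events on the unit grid", {
  sp <- build_spectrum(event_table(c(10.5, 10.7, 20.2)), normalize = FALSE)
  expect_equal(sp$value[sp$bin_center == 10.5], 2)
  expect_equal(sp$value[sp$bin_center == 20.5], 1)
  expect_equal(sum(sp$value), 3)

  # values exactly 100 land in the last bin; normalization sums to 1
  spn <- build_spectrum(event_table(c(100, 98.2, 50)))
  expect_equal(spn$value[100], 1 / 3)
  expect_equal(spn$value[99], 1 / 3)
  expect_equal(sum(spn$value), 1, tolerance = 1e-9)
  expect_equal(attr(spn, "n_events"), 3)

  expect_error(build_spectrum(event_table(numeric())), "empty spectrum")
  ev <- tibble::tibble(iex_pct = c(10, 20), accepted = c(FALSE, FALSE))
  expect_error(build_spectrum(ev), "empty spectrum")
})

test_that("spectrum counts follow the sampled mixture", {
  set.seed(21)
  iex <- c(rnorm(600, 40, 2), rnorm(400, 70, 3))
  sp <- build_spectrum(event_table(iex), normalize = FALSE)
  expect_equal(sum(sp$value), 1000)
  # per-bin counts within 3 sqrt(expected) + 1 of the mixture expectation
  edges <- 0:100
  p <- 0.6 * (pnorm(edges[-1], 40, 2) - pnorm(edges[-101], 40, 2)) +
    0.4 * (pnorm(edges[-1], 70, 3) - pnorm(edges[-101], 70, 3))
  expected <- 1000 * p
  expect_true(all(abs(sp$value - expected) <= 3 * sqrt(expected) + 1))
})

test_that("realign recovers imposed offsets to one grid step", {
  ref <- smooth_spectrum(c(45, 60, 75), c(1, 2, 1.5), sigma = 2)
  expect_equal(realign(ref, ref)$offset, 0)
  for (shift in c(-2.4, -0.85, 1.3, 3.15)) {
    sample <- smooth_spectrum(c(45, 60, 75) + shift, c(1, 2, 1.5), sigma = 2)
    al <- realign(sample, ref)
    expect_equal(al$offset, -shift, tolerance = 0.051)
    # the aligned spectrum is closer to the reference than the input
    expect_lt(sum((al$aligned$value - ref$value)^2),
              sum((sample$value - ref$value)^2))
  }
})

test_that("offsets beyond the grid saturate at the edge with a warning", {
  ref <- smooth_spectrum(c(60), sigma = 2)
  sample <- smooth_spectrum(c(67), sigma = 2)
  expect_warning(al <- realign(sample, ref), "edge")
  expect_equal(al$offset, -5)
})

test_that("realign error curve is symmetric under sample/reference exchange", {
  a <- smooth_spectrum(c(55, 70), c(1, 1.3), sigma = 2.5)
  b <- smooth_spectrum(c(57, 72), c(1, 1.3), sigma = 2.5)
  # at whole-bin offsets the shift is exact, so the curves must agree
  ab <- realign(a, b, step = 1, max_shift = 4)$error_curve
  ba <- realign(b, a, step = 1, max_shift = 4)$error_curve
  expect_equal(ab$error, rev(ba$error), tolerance = 1e-9)
})

test_that("realign validates its inputs", {
  a <- smooth_spectrum(60)
  raw <- build_spectrum(event_table(c(60.2, 61)), normalize = FALSE)
  expect_error(realign(raw, a), "normalized")
  expect_error(realign(a, 1:10), "iex_spectrum")
})

test_that("realign_replicates aligns groups to their first replicate", {
  base <- c(55, 70)
  tbl <- tibble::tibble(
    label = "p1", replicate = 1:3,
    spectrum = list(
      smooth_spectrum(base), smooth_spectrum(base + 1.5),
      smooth_spectrum(base - 2)
    )
  )
  out <- realign_replicates(tbl)
  expect_equal(out$offset, c(0, -1.5, 2), tolerance = 0.051)
})

test_that("baseline_correct removes flat background and keeps peaks", {
  flat <- new_spectrum(rep(0.01, 100), normalized = FALSE)
  expect_true(all(baseline_correct(flat)$value == 0))

  peak <- new_spectrum(exp(-(seq(0.5, 99.5) - 60)^2 / 2), normalized = FALSE)
  out <- baseline_correct(peak, window = 8)
  expect_equal(max(out$value), max(peak$value), tolerance = 0.05)
  expect_true(all(out$value <= peak$value + 1e-12))

  expect_error(baseline_correct(peak, window = 2), ">= 3")
  expect_error(baseline_correct(peak, window = 101), "larger")
})

test_that("spectra round-trip through the delimited-text format", {
  sp <- smooth_spectrum(c(50, 80), label = "lysozyme")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$value, sp$value, tolerance = 1e-9)
  expect_equal(attr(back, "label"), "lysozyme")
  expect_true(attr(back, "normalized"))
})
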