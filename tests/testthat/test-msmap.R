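test_that("single-peak density at its own center equals sqrt(area)", {
  m <- default_calibration()
  peaks <- tibble::tibble(mass = 1000, area = 4)
  center <- predict_iex(m, 1000)
  expect_equal(ms_density(center, peaks, m), 2, tolerance = 1e-12)
  # per-peak mode gives the same value for a single peak
  expect_equal(ms_density(center, peaks, m, mode = "sqrt_per_peak"), 2,
               tolerance = 1e-12)
})

test_that("well-separated equal peaks give equal-height modes", {
  m <- default_calibration()
  peaks <- tibble::tibble(mass = c(700, 1400), area = c(5, 5))
  centers <- predict_iex(m, peaks$mass)
  h <- ms_density(centers, peaks, m, peak_sigma = 0.5)
  expect_gt(min(centers[2] - centers[1]) / 0.5, 6) # >= 6 sigma apart
  expect_equal(h[1], h[2], tolerance = 1e-6)
  # and both are local maxima of the density
  eps <- 0.05
  for (cc in centers) {
    expect_gt(ms_density(cc, peaks, m), ms_density(cc - eps, peaks, m))
    expect_gt(ms_density(cc, peaks, m), ms_density(cc + eps, peaks, m))
  }
})

test_that("projected spectra are normalized and scale-invariant", {
  m <- default_calibration()
  peaks <- tibble::tibble(mass = c(600, 1000, 1500), area = c(1, 4, 2))
  sp <- project_ms(peaks, m)
  expect_s3_class(sp, "iex_spectrum")
  expect_equal(sum(sp$value), 1, tolerance = 1e-9)
  doubled <- project_ms(dplyr::mutate(peaks, area = 2 * area), m)
  expect_equal(sp$value, doubled$value, tolerance = 1e-12)
})

test_that("peak centers do not depend on the sqrt placement", {
  m <- default_calibration()
  peaks <- tibble::tibble(mass = c(600, 1500), area = c(1, 9))
  a <- project_ms(peaks, m, mode = "sum_then_sqrt")
  b <- project_ms(peaks, m, mode = "sqrt_per_peak")
  top <- function(sp, lo, hi) {
    sel <- sp$bin_center >= lo & sp$bin_center <= hi
    sp$bin_center[sel][which.max(sp$value[sel])]
  }
  centers <- predict_iex(m, peaks$mass)
  for (cc in centers) {
    expect_equal(top(a, cc - 3, cc + 3), top(b, cc - 3, cc + 3))
  }
})

test_that("removing a peak never increases the summed density", {
  m <- default_calibration()
  peaks <- tibble::tibble(mass = c(700, 1000, 1300), area = c(2, 3, 1))
  x <- seq(0, 100, by = 0.25)
  full <- ms_density(x, peaks, m)
  fewer <- ms_density(x, peaks[-2, ], m)
  expect_true(all(fewer <= full + 1e-12))
})

test_that("the in-silico digest projects one mode per retained peptide", {
  m <- default_calibration()
  d <- digest_protein("HGLDNYRTPGSRLLLLLKAAEEWWK", digest_params())
  expect_gte(nrow(d), 3)
  centers <- sort(predict_iex(m, d$mass))
  expect_true(all(diff(centers) >= 3 * 0.5)) # >= 3 sigma apart
  peaks <- tibble::tibble(mass = d$mass, area = rep(1, nrow(d)))
  x <- seq(0.025, 99.975, by = 0.05)
  g <- ms_density(x, peaks, m, peak_sigma = 0.5)
  is_max <- which(diff(sign(diff(g))) == -2) + 1
  modes <- x[is_max][g[is_max] > 0.05 * max(g)]
  expect_equal(length(modes), nrow(d))
  expect_equal(sort(modes), centers, tolerance = 0.5)
})

test_that("out-of-range peaks are dropped with a warning", {
  m <- default_calibration()
  peaks <- tibble::tibble(mass = c(1000, 2500), area = c(1, 1))
  expect_warning(sp <- project_ms(peaks, m), "dropped")
  expect_equal(sum(sp$value), 1, tolerance = 1e-9)
  expect_error(
    suppressWarnings(project_ms(tibble::tibble(mass = 2500, area = 1), m)),
    "no peaks"
  )
  expect_error(project_ms(tibble::tibble(mass = numeric(), area = numeric()), m),
               "empty")
})

test_that("peak tables read from text with mass or sequence columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mass_da\tarea", "1000\t4", "1500\t1"), path)
  tbl <- read_peaks(path)
  expect_equal(tbl$mass, c(1000, 1500))
  writeLines(c("sequence\tarea", "HGLDNYR\t2"), path)
  tbl2 <- read_peaks(path)
  sp <- project_ms(tbl2, default_calibration())
  expect_equal(sum(sp$value), 1, tolerance = 1e-9)
})
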