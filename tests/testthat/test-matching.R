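test_that("deuc self-match is 1 and the score is symmetric", {
  a <- smooth_spectrum(c(60, 75), c(1, 2))
  b <- smooth_spectrum(c(58, 80), c(2, 1))
  expect_equal(deuc(a, a), 1, tolerance = 1e-12)
  expect_equal(deuc(a, b), deuc(b, a), tolerance = 1e-12)
  expect_gte(deuc(a, b), 0)
  expect_lte(deuc(a, b), 1)
})

test_that("deuc ignores constant offsets and positive scaling", {
  a <- smooth_spectrum(c(60, 75), c(1, 2))
  b <- smooth_spectrum(c(65, 82), c(1.5, 1))
  base <- deuc(a, b)
  shifted <- new_spectrum(b$value + 0.02, normalized = TRUE)
  expect_equal(deuc(a, shifted), base, tolerance = 1e-9)
  scaled <- new_spectrum(7 * b$value, normalized = TRUE)
  expect_equal(deuc(a, scaled), base, tolerance = 1e-12)
  # a constant-offset copy of a matches a perfectly: the derivative
  # annihilates baseline sloping
  expect_equal(deuc(a, new_spectrum(a$value + 0.01, normalized = TRUE)), 1,
               tolerance = 1e-9)
})

test_that("orthogonal derivative vectors score zero", {
  # window [50, 98) covers bins 51..98 -> 48 values, 47 first differences
  ramp <- seq(0, 1, length.out = 48)             # constant derivative
  tri <- c(seq(0, 1, length.out = 25), seq(1, 0, length.out = 24)[-1])
  va <- rep(0, 100); va[51:98] <- ramp
  vb <- rep(0, 100); vb[51:98] <- tri            # sums of diffs cancel
  a <- new_spectrum(va, normalized = TRUE)
  b <- new_spectrum(vb, normalized = TRUE)
  expect_equal(deuc(a, b), 0, tolerance = 1e-12)
})

test_that("degenerate windows are rejected", {
  a <- smooth_spectrum(c(60, 75))
  flat <- new_spectrum(rep(0.01, 100), normalized = TRUE)
  expect_error(deuc(a, flat), "degenerate")
  expect_error(deuc(a, a, window = c(98, 50)), "window")
  # spectra concentrated outside the window are degenerate inside it
  low <- smooth_spectrum(20, sigma = 1)
  expect_error(deuc(low, a), "degenerate")
})

test_that("build_database averages replicates and honours exclusion", {
  s1 <- smooth_spectrum(c(60, 70), c(1, 1))
  s2 <- smooth_spectrum(c(60, 70), c(1, 1))
  tbl <- tibble::tibble(
    label = c("A", "A", "B"), replicate = c(1, 2, 1),
    spectrum = list(s1, s2, smooth_spectrum(80))
  )
  db <- build_database(tbl)
  expect_equal(db$label, c("A", "B"))
  expect_equal(db$spectrum[[1]]$value, s1$value) # identical replicates
  expect_equal(db$spectrum[[2]]$value, tbl$spectrum[[3]]$value) # single rep
  expect_error(build_database(tbl, exclude = list("B", 1)), "no remaining")
})

test_that("re-alignment before averaging sharpens the database mean", {
  reps <- list(
    smooth_spectrum(70, sigma = 1.5), smooth_spectrum(72, sigma = 1.5),
    smooth_spectrum(68.5, sigma = 1.5)
  )
  tbl <- tibble::tibble(label = "A", replicate = 1:3, spectrum = reps)
  width <- function(sp) {
    mu <- sum(sp$bin_center * sp$value) / sum(sp$value)
    sqrt(sum((sp$bin_center - mu)^2 * sp$value) / sum(sp$value))
  }
  raw_mean <- build_database(tbl)$spectrum[[1]]
  aligned_mean <- build_database(realign_replicates(tbl))$spectrum[[1]]
  expect_lt(width(aligned_mean), width(raw_mean))
})

test_that("leave-one-out assigns exact-copy replicates to their protein", {
  mk <- function(centers) smooth_spectrum(centers, sigma = 2)
  tbl <- tibble::tibble(
    label = rep(c("A", "B", "C"), each = 2),
    replicate = rep(1:2, 3),
    spectrum = list(
      mk(c(55, 70)), mk(c(55, 70)),
      mk(c(60, 85)), mk(c(60, 85)),
      mk(c(52, 90)), mk(c(52, 90))
    )
  )
  res <- leave_one_out(tbl)
  expect_true(all(res$assignments$correct))
  expect_false(any(res$assignments$tie))
  m <- res$score_matrix
  expect_true(all(diag(m) == 100)) # row max normalization
  off <- m - diag(diag(m))
  expect_true(all(diag(m) > apply(off, 1, max)))
  gl <- glance(res)
  expect_equal(gl$accuracy, 1)
  expect_equal(gl$n_samples, 6)
})

test_that("indistinguishable proteins are reported as ties", {
  same <- smooth_spectrum(c(60, 75))
  tbl <- tibble::tibble(
    label = rep(c("A", "B"), each = 2), replicate = rep(1:2, 2),
    spectrum = list(same, same, same, same)
  )
  res <- leave_one_out(tbl)
  expect_true(all(res$assignments$tie))
  expect_true(all(is.na(res$assignments$predicted)))
})

test_that("leave_one_out validates replicate structure", {
  a <- smooth_spectrum(c(60, 75))
  one_prot <- tibble::tibble(label = "A", replicate = 1:2,
                             spectrum = list(a, a))
  expect_error(leave_one_out(one_prot), "2 proteins")
  single_rep <- tibble::tibble(label = c("A", "B"), replicate = c(1, 1),
                               spectrum = list(a, a))
  expect_error(leave_one_out(single_rep), "2 replicates")
})
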