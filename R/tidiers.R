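#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a calibration model
#'
#' @param x A `porefp_calibration`.
#' @param ... Unused.
#' @return A tibble with one row per polynomial term (`b0`, `b1`, `b2`),
#'   with standard errors when the model carries a fitted `lm`.
#' @export
tidy.porefp_calibration <- function(x, ...) {
  if (!is.null(x$fit)) {
    s <- summary(x$fit)$coefficients
    tibble::tibble(
      term = c("b0", "b1", "b2"),
      estimate = unname(s[, 1]),
      std.error = unname(s[, 2])
    )
  } else {
    tibble::tibble(
      term = c("b0", "b1", "b2"),
      estimate = c(x$b0, x$b1, x$b2),
      std.error = NA_real_
    )
  }
}

#' @rdname tidy.porefp_calibration
#' @export
glance.porefp_calibration <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    domain_min = x$domain[1], domain_max = x$domain[2],
    r.squared = if (!is.null(x$fit)) summary(x$fit)$r.squared else NA_real_,
    n = if (!is.null(x$fit)) stats::nobs(x$fit) else NA_integer_
  )
}

#' Tidy a leave-one-out matching result
#'
#' @param x A `porefp_match`.
#' @param ... Unused.
#' @return `tidy()`: the per-sample assignment tibble; `glance()`: one row
#'   with accuracy, sample and protein counts, and ties.
#' @export
tidy.porefp_match <- function(x, ...) x$assignments

#' @rdname tidy.porefp_match
#' @export
glance.porefp_match <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$assignments),
    n_proteins = nrow(x$score_matrix),
    n_correct = sum(x$assignments$correct),
    n_ties = sum(x$assignments$tie),
    accuracy = mean(x$assignments$correct)
  )
}

#' Tidy a re-alignment result
#'
#' @param x A `porefp_alignment`.
#' @param ... Unused.
#' @return `tidy()`: the offset-vs-error curve; `glance()`: one row with the
#'   chosen offset and its error.
#' @export
tidy.porefp_alignment <- function(x, ...) x$error_curve

#' @rdname tidy.porefp_alignment
#' @export
glance.porefp_alignment <- function(x, ...) {
  tibble::tibble(
    offset = x$offset,
    error = min(x$error_curve$error)
  )
}
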