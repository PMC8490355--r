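#' Fit the mass-to-excluded-current calibration polynomial
#'
#' The mean excluded current of a peptide relates to its mass through a
#' second-order polynomial
#' \deqn{I_{ex}(m) = b_0 + b_1 m + b_2 m^2}
#' fitted here by ordinary least squares. Including the origin adds (0, 0)
#' as one ordinary (unweighted) data point, reflecting that a massless
#' analyte excludes no current, without constraining the intercept to zero.
#'
#' @param points A data frame with columns `mass` (Da) and `iex` (mean
#'   I_ex%), one row per calibrant peptide.
#' @param include_origin Append (0, 0) as an ordinary point (default
#'   `TRUE`).
#' @return An object of class `porefp_calibration` with elements `b0`, `b1`,
#'   `b2`, `domain` (mass range of the input points, Da), and `fit` (the
#'   underlying `lm`).
#' @seealso [default_calibration()], [predict_iex()], [invert_iex()]
#' @export
fit_calibration <- function(points, include_origin = TRUE) {
  stopifnot(all(c("mass", "iex") %in% names(points)))
  pts <- tibble::tibble(mass = points$mass, iex = points$iex)
  domain <- range(pts$mass)
  if (include_origin) pts <- dplyr::bind_rows(pts, tibble::tibble(mass = 0, iex = 0))
  if (nrow(pts) < 3L || length(unique(pts$mass)) < 3L) {
    rlang::abort("need at least 3 distinct masses to fit a quadratic")
  }
  fit <- stats::lm(iex ~ mass + I(mass^2), data = pts)
  cf <- stats::coef(fit)
  new_calibration(
    b0 = unname(cf[1]), b1 = unname(cf[2]), b2 = unname(cf[3]),
    domain = domain, fit = fit, name = "user"
  )
}

new_calibration <- function(b0, b1, b2, domain, fit = NULL, name = "user") {
  structure(
    list(b0 = b0, b1 = b1, b2 = b2, domain = domain, fit = fit, name = name),
    class = "porefp_calibration"
  )
}

#' The shipped FraC-G13F-T1 calibration
#'
#' The default mass-to-I_ex% model, fitted on synthetic peptides spanning
#' the 500-1700 Da working window of the G13F FraC (type 1 oligomer)
#' nanopore in 1 M KCl at pH 3.8: `b2 = -1.33e-5`, `b1 = 7.23e-2`,
#' `b0 = 3.28`. Used whenever no user calibration is supplied.
#'
#' @return A `porefp_calibration` with domain `[0, 1700]` Da.
#' @export
default_calibration <- function() {
  new_calibration(
    b0 = 3.28, b1 = 7.23e-2, b2 = -1.33e-5,
    domain = c(0, 1700), name = "fraC-G13F-T1-2021"
  )
}

#' @export
print.porefp_calibration <- function(x, ...) {
  cat(sprintf(
    "<porefp_calibration '%s'>\n  I_ex%%(m) = %.4g + %.4g m + %.4g m^2,  m in [%g, %g] Da\n",
    x$name, x$b0, x$b1, x$b2, x$domain[1], x$domain[2]
  ))
  invisible(x)
}

#' Predict excluded current from peptide mass
#'
#' Evaluates the calibration polynomial. Masses outside the model's fit
#' domain are extrapolations and raise a warning.
#'
#' @param model A `porefp_calibration`.
#' @param mass Peptide mass(es) in Da, >= 0.
#' @return Predicted I_ex% (not clamped).
#' @examples
#' predict_iex(default_calibration(), 1000) # 62.28
#' @export
predict_iex <- function(model, mass) {
  stopifnot(inherits(model, "porefp_calibration"))
  if (any(mass < 0)) rlang::abort("`mass` must be non-negative")
  out_dom <- mass < model$domain[1] | mass > model$domain[2]
  if (any(out_dom)) {
    rlang::warn(sprintf(
      "%d mass value(s) outside the calibration domain [%g, %g] Da; extrapolating",
      sum(out_dom), model$domain[1], model$domain[2]
    ))
  }
  model$b0 + model$b1 * mass + model$b2 * mass^2
}

#' Invert the calibration: excluded current to mass
#'
#' Solves the quadratic for the root inside the model's fit domain. Only
#' excluded currents attainable on the domain (between the predictions at
#' the domain ends, for a monotone model) can be inverted.
#'
#' @param model A `porefp_calibration`.
#' @param iex Excluded current(s) in percent.
#' @return Mass in Da satisfying `predict_iex(model, mass) == iex`.
#' @export
invert_iex <- function(model, iex) {
  stopifnot(inherits(model, "porefp_calibration"))
  lo <- predict_iex(model, model$domain[1])
  hi <- predict_iex(model, model$domain[2])
  rng <- sort(c(lo, hi))
  tol <- 1e-9 * max(1, abs(rng))
  vapply(iex, function(y) {
    if (y < rng[1] - tol[1] || y > rng[2] + tol[length(tol)]) {
      rlang::abort(sprintf(
        "I_ex%% = %.4g is outside the attainable range [%.4g, %.4g] of calibration '%s'",
        y, rng[1], rng[2], model$name
      ))
    }
    if (abs(model$b2) < 1e-300) {
      return((y - model$b0) / model$b1)
    }
    disc <- model$b1^2 - 4 * model$b2 * (model$b0 - y)
    if (disc < 0) {
      rlang::abort(sprintf("I_ex%% = %.4g lies beyond the quadratic vertex", y))
    }
    roots <- (-model$b1 + c(1, -1) * sqrt(disc)) / (2 * model$b2)
    dtol <- 1e-6 * max(1, diff(model$domain))
    inside <- roots >= model$domain[1] - dtol & roots <= model$domain[2] + dtol
    if (!any(inside)) {
      rlang::abort(sprintf("no root in the fit domain for I_ex%% = %.4g", y))
    }
    roots[inside][1]
  }, numeric(1))
}

#' Mean excluded current of a unimodal spectrum region
#'
#' Helper for building calibration points from measured spectra: returns the
#' bin-center of the maximum value inside `[lo, hi]`, refined by a
#' value-weighted centroid over the neighbouring bins.
#'
#' @param spectrum An `iex_spectrum`.
#' @param lo,hi Region of interest in I_ex%.
#' @param centroid_halfwidth Bins on either side of the argmax included in
#'   the centroid; 0 returns the raw argmax bin center.
#' @return Peak position in I_ex%.
#' @export
spectrum_peak <- function(spectrum, lo = 0, hi = 100, centroid_halfwidth = 2L) {
  assert_spectrum(spectrum)
  sel <- which(spectrum$bin_center >= lo & spectrum$bin_center <= hi)
  if (length(sel) == 0L) rlang::abort("empty region of interest")
  i <- sel[which.max(spectrum$value[sel])]
  idx <- max(1L, i - centroid_halfwidth):min(nrow(spectrum), i + centroid_halfwidth)
  w <- spectrum$value[idx]
  if (sum(w) == 0) return(spectrum$bin_center[i])
  sum(spectrum$bin_center[idx] * w) / sum(w)
}
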