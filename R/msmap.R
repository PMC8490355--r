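#' Predicted I_ex% density from an ESI-MS peak table
#'
#' Evaluates the Gaussian-mixture density underlying the projected spectrum
#' at arbitrary points:
#' \deqn{g(x) = \left(\sum_i a_i \exp\!\big(-(x - \hat I_{ex}(m_i))^2 /
#'   2\sigma^2\big)\right)^{p}}
#' in `sum_then_sqrt` mode (with power `p`, default 0.5 — Orbitrap detectors
#' report intensity as the squared ion count, hence the square root), or
#' \eqn{\sum_i a_i^{p}\exp(\cdot)} in `sqrt_per_peak` mode. Peak centers are
#' the calibrated excluded currents of the peptide masses.
#'
#' @param x Evaluation points (I_ex%).
#' @param peaks Data frame with columns `mass` (Da) and `area` (>= 0), or
#'   `sequence` and `area` (masses computed via [peptide_mass()]).
#' @param model A `porefp_calibration`.
#' @param peak_sigma Peak standard deviation in I_ex% (default 0.5).
#' @param mode `"sum_then_sqrt"` (default) or `"sqrt_per_peak"`.
#' @param intensity_power Power applied to intensities (default 0.5; use 1
#'   for detectors whose response is linear in ion count).
#' @return Numeric vector, `g(x)`.
#' @export
ms_density <- function(x, peaks, model = default_calibration(),
                       peak_sigma = 0.5,
                       mode = c("sum_then_sqrt", "sqrt_per_peak"),
                       intensity_power = 0.5) {
  mode <- match.arg(mode)
  peaks <- prepare_peaks(peaks, model)
  if (peak_sigma <= 0) rlang::abort("`peak_sigma` must be positive")
  centers <- predict_iex(model, peaks$mass)
  g <- rep(0, length(x))
  for (i in seq_len(nrow(peaks))) {
    kern <- exp(-(x - centers[i])^2 / (2 * peak_sigma^2))
    g <- g + if (mode == "sum_then_sqrt") {
      peaks$area[i] * kern
    } else {
      peaks$area[i]^intensity_power * kern
    }
  }
  if (mode == "sum_then_sqrt") g <- g^intensity_power
  g
}

prepare_peaks <- function(peaks, model) {
  if (!"mass" %in% names(peaks)) {
    if (!"sequence" %in% names(peaks)) {
      rlang::abort("`peaks` needs a `mass` or `sequence` column")
    }
    peaks <- dplyr::mutate(peaks, mass = peptide_mass(.data$sequence))
  }
  stopifnot("area" %in% names(peaks))
  if (nrow(peaks) == 0L) rlang::abort("empty peak list")
  if (any(peaks$area < 0)) rlang::abort("peak areas must be non-negative")
  rng <- sort(predict_iex(model, model$domain))
  centers <- suppressWarnings(predict_iex(model, peaks$mass))
  drop <- peaks$mass < model$domain[1] | peaks$mass > model$domain[2] |
    centers < 0 | centers > 100
  if (any(drop)) {
    rlang::warn(sprintf(
      "%d peak(s) outside the calibration's attainable range dropped", sum(drop)
    ))
    peaks <- peaks[!drop, , drop = FALSE]
  }
  if (nrow(peaks) == 0L) rlang::abort("no peaks inside the calibration range")
  peaks
}

#' Project an ESI-MS peak table into a predicted I_ex% spectrum
#'
#' Each mass-spectrometry peak becomes a Gaussian of standard deviation
#' `peak_sigma` I_ex% centered at its calibrated excluded current, with
#' height derived from its (square-rooted) peak area. The density is
#' evaluated on a fine internal grid (0.05 I_ex%), averaged into the
#' standard 1 I_ex% bins so that projected and measured spectra share a
#' grid, and normalized to unit sum.
#'
#' @inheritParams ms_density
#' @param label Identifier stored with the spectrum.
#' @return An `iex_spectrum` (normalized).
#' @export
project_ms <- function(peaks, model = default_calibration(), peak_sigma = 0.5,
                       mode = c("sum_then_sqrt", "sqrt_per_peak"),
                       intensity_power = 0.5, label = NA_character_) {
  mode <- match.arg(mode)
  fine <- seq(0.025, 99.975, by = 0.05)
  g <- ms_density(fine, peaks, model, peak_sigma, mode, intensity_power)
  binned <- colMeans(matrix(g, nrow = 20))
  if (sum(binned) == 0) rlang::abort("projected spectrum is identically zero")
  new_spectrum(binned / sum(binned), n_events = NA_integer_,
               normalized = TRUE, label = label)
}

#' Read an ESI-MS peak table from delimited text
#'
#' Expects columns (`mass_da`, `area`) or (`sequence`, `area`), header row
#' optional `#` comments allowed.
#'
#' @param path File path.
#' @return A tibble with columns `mass` (or `sequence`) and `area`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("peak table not found: %s", path))
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  names(tbl) <- tolower(names(tbl))
  if ("mass_da" %in% names(tbl)) tbl <- dplyr::rename(tbl, mass = "mass_da")
  if (!any(c("mass", "sequence") %in% names(tbl)) || !"area" %in% names(tbl)) {
    rlang::abort("peak table needs (mass_da|sequence) and area columns")
  }
  tbl
}
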