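#' Construct an excluded-current (I_ex%) spectrum
#'
#' Histograms the `iex_pct` column of an event table into 100 unit-width
#' bins spanning 0-100 I_ex%. Bins are half-open `[a, a+1)` except the last,
#' which also includes values exactly at 100. The normalized spectrum (bin
#' values divided by the event count) is the protein's nanopore fingerprint.
#'
#' @param events An event tibble with an `iex_pct` column (and optionally
#'   `accepted`), e.g. from [detect_events()].
#' @param accepted_only Keep only rows with `accepted == TRUE` (default).
#' @param normalize Divide counts by the number of events (default `TRUE`).
#' @param label Sample / protein identifier stored with the spectrum.
#' @return A tibble of class `iex_spectrum` with columns `bin_center`
#'   (0.5, 1.5, ..., 99.5) and `value`; attributes `n_events`, `normalized`,
#'   `label`, `offset_applied`.
#' @export
build_spectrum <- function(events, accepted_only = TRUE, normalize = TRUE,
                           label = NA_character_) {
  stopifnot("iex_pct" %in% names(events))
  if (accepted_only && "accepted" %in% names(events)) {
    events <- dplyr::filter(events, .data$accepted)
  }
  iex <- events$iex_pct[is.finite(events$iex_pct)]
  if (length(iex) == 0L) rlang::abort("empty spectrum: no accepted events")
  if (any(iex < 0 | iex > 100)) {
    rlang::abort("iex_pct values outside [0, 100]")
  }
  idx <- pmin(floor(iex), 99) + 1L  # values exactly 100 -> last bin
  counts <- tabulate(idx, nbins = 100L)
  new_spectrum(
    if (normalize) counts / length(iex) else as.numeric(counts),
    n_events = length(iex), normalized = normalize, label = label
  )
}

#' Construct an I_ex% spectrum from bin values
#'
#' Low-level constructor for the standard 100-bin grid; [build_spectrum()]
#' is the usual entry point from event tables.
#'
#' @param value 100 non-negative bin values (bins `[0,1), ..., [99,100]`).
#' @param n_events Number of events behind the spectrum (`NA` for derived
#'   spectra such as MS projections).
#' @param normalized Whether `value` sums to one.
#' @param label Sample / protein identifier.
#' @param offset_applied Re-alignment shift already applied, I_ex%.
#' @return A tibble of class `iex_spectrum`.
#' @export
new_spectrum <- function(value, n_events = NA_integer_, normalized = TRUE,
                         label = NA_character_, offset_applied = 0) {
  stopifnot(length(value) == 100L)
  out <- tibble::tibble(bin_center = seq(0.5, 99.5, by = 1), value = value)
  attr(out, "n_events") <- n_events
  attr(out, "normalized") <- normalized
  attr(out, "label") <- label
  attr(out, "offset_applied") <- offset_applied
  class(out) <- c("iex_spectrum", class(out))
  out
}

is_spectrum <- function(x) inherits(x, "iex_spectrum")

assert_spectrum <- function(x, arg = "spectrum") {
  if (!is_spectrum(x)) {
    rlang::abort(sprintf("`%s` must be an iex_spectrum", arg))
  }
  invisible(x)
}

spectrum_label <- function(x) attr(x, "label")

# Shift a spectrum along the I_ex% axis by `offset` (linear interpolation of
# bin values treated as samples at bin centers; mass moved outside [0, 100]
# is dropped, i.e. values outside the grid are 0).
shift_spectrum <- function(spectrum, offset) {
  y <- stats::approx(
    spectrum$bin_center, spectrum$value,
    xout = spectrum$bin_center - offset, rule = 1
  )$y
  y[is.na(y)] <- 0
  new_spectrum(
    y,
    n_events = attr(spectrum, "n_events"),
    normalized = attr(spectrum, "normalized"),
    label = attr(spectrum, "label"),
    offset_applied = attr(spectrum, "offset_applied") + offset
  )
}

#' Re-align a spectrum to a reference by grid-search offset
#'
#' Replicate spectra drift along the I_ex% axis with salt concentration,
#' temperature, and instrument offset. The sample spectrum is shifted over a
#' grid of candidate offsets (default -5 to +5 I_ex% in 0.05 steps, i.e.
#' 100 step-wise subtractions and additions), the bin-by-bin residual sum of
#' squares against the reference recorded at each step, and the
#' error-minimizing offset applied. Shifted bin values are obtained by
#' linear interpolation at bin centers.
#'
#' @param sample,reference Normalized [build_spectrum()] spectra on the same
#'   grid.
#' @param step Offset grid step in I_ex%, default 0.05.
#' @param max_shift Half-range of the search grid in I_ex%, default 5.
#' @return A list of class `porefp_alignment`: `offset` (the applied shift,
#'   I_ex%), `aligned` (the shifted sample spectrum), `error_curve` (tibble
#'   `offset`, `error`). A warning is raised when the optimum sits on the
#'   grid edge.
#' @export
realign <- function(sample, reference, step = 0.05, max_shift = 5) {
  assert_spectrum(sample, "sample")
  assert_spectrum(reference, "reference")
  if (!isTRUE(attr(sample, "normalized")) ||
      !isTRUE(attr(reference, "normalized"))) {
    rlang::abort("both spectra must be normalized before re-alignment")
  }
  if (!isTRUE(all.equal(sample$bin_center, reference$bin_center))) {
    rlang::abort("spectra are on different grids")
  }
  offsets <- seq(-max_shift, max_shift, by = step)
  err <- vapply(offsets, function(d) {
    sum((shift_spectrum(sample, d)$value - reference$value)^2)
  }, numeric(1))
  best <- which(err == min(err))
  if (length(best) > 1L) best <- best[which.min(abs(offsets[best]))]
  offset <- offsets[best]
  if (abs(abs(offset) - max_shift) < step / 2 && offset != 0) {
    rlang::warn(sprintf(
      "re-alignment optimum at grid edge (%+.2f I_ex%%); true offset may lie beyond max_shift",
      offset
    ))
  }
  structure(
    list(
      offset = offset,
      aligned = shift_spectrum(sample, offset),
      error_curve = tibble::tibble(offset = offsets, error = err)
    ),
    class = "porefp_alignment"
  )
}

#' Re-align replicate spectra within each protein group
#'
#' Convenience wrapper applying [realign()] to every replicate against a
#' per-protein reference (the first replicate by input order, by default).
#'
#' @param spectra A tibble with columns `label`, `replicate`, and `spectrum`
#'   (a list-column of `iex_spectrum`), e.g. from [simulate_replicates()]
#'   piped through detection.
#' @param reference `"first"` (default) or a function
#'   `f(group_tibble) -> row index` choosing the reference replicate.
#' @param step,max_shift Passed to [realign()].
#' @return The input tibble with spectra replaced by aligned spectra and an
#'   added `offset` column.
#' @export
realign_replicates <- function(spectra, reference = "first", step = 0.05,
                               max_shift = 5) {
  stopifnot(all(c("label", "spectrum") %in% names(spectra)))
  spectra |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(g, key) {
      ref_i <- if (is.function(reference)) reference(g) else 1L
      ref <- g$spectrum[[ref_i]]
      res <- purrr::map(g$spectrum, function(sp) {
        if (identical(sp, ref)) {
          list(offset = 0, aligned = sp)
        } else {
          realign(sp, ref, step = step, max_shift = max_shift)
        }
      })
      g$spectrum <- purrr::map(res, "aligned")
      g$offset <- purrr::map_dbl(res, "offset")
      g
    }) |>
    dplyr::ungroup()
}

#' Rolling-minimum baseline correction of a spectrum
#'
#' Subtracts a slowly varying background envelope: the rolling minimum over
#' `window` bins, smoothed by a moving average of the same window. Negative
#' residuals are clamped to zero and normalized spectra are renormalized.
#' Matching via the derivative score is already insensitive to baseline
#' sloping, so correction is optional there; it is mainly a display aid.
#'
#' @param spectrum An `iex_spectrum`.
#' @param window Envelope window in bins (>= 3, <= 100); default 8.
#' @return A corrected `iex_spectrum`.
#' @export
baseline_correct <- function(spectrum, window = 8L) {
  assert_spectrum(spectrum)
  n <- nrow(spectrum)
  if (window < 3L) rlang::abort("`window` must be >= 3 bins")
  if (window > n) rlang::abort("`window` larger than the spectrum")
  half <- window %/% 2L
  v <- spectrum$value
  rollmin <- vapply(seq_len(n), function(i) {
    min(v[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  envelope <- vapply(seq_len(n), function(i) {
    mean(rollmin[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  corrected <- pmax(v - envelope, 0)
  if (isTRUE(attr(spectrum, "normalized")) && sum(corrected) > 0) {
    corrected <- corrected / sum(corrected)
  }
  new_spectrum(
    corrected,
    n_events = attr(spectrum, "n_events"),
    normalized = attr(spectrum, "normalized"),
    label = attr(spectrum, "label"),
    offset_applied = attr(spectrum, "offset_applied")
  )
}

#' Read / write spectrum files
#'
#' Spectrum files are two-column delimited text (`bin_center`, `value`) with
#' `#` header lines carrying `label`, `n_events`, `normalized`, and
#' `offset_applied`.
#'
#' @param spectrum An `iex_spectrum`.
#' @param path File path.
#' @return `write_spectrum()`: `path` invisibly; `read_spectrum()`: an
#'   `iex_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  assert_spectrum(spectrum)
  hdr <- c(
    sprintf("# label = %s", attr(spectrum, "label")),
    sprintf("# n_events = %s", attr(spectrum, "n_events")),
    sprintf("# normalized = %s", attr(spectrum, "normalized")),
    sprintf("# offset_applied = %.10g", attr(spectrum, "offset_applied"))
  )
  body <- sprintf("%.1f\t%.10g", spectrum$bin_center, spectrum$value)
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("spectrum file not found: %s", path))
  lines <- readr::read_lines(path)
  hdr <- parse_hash_header(lines)
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  fields <- strsplit(trimws(body), "[\t ,]+")
  val <- as.numeric(vapply(fields, `[[`, "", 2L))
  if (length(val) != 100L) {
    rlang::abort(sprintf("expected 100 bins, found %d in %s", length(val), path))
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  new_spectrum(
    val,
    n_events = as.integer(num_or_na(hdr[["n_events"]] %||% NA)),
    normalized = isTRUE(as.logical(hdr[["normalized"]] %||% TRUE)),
    label = {
      l <- as.character(hdr[["label"]] %||% NA_character_)
      if (identical(l, "NA")) NA_character_ else l
    },
    offset_applied = num_or_na(hdr[["offset_applied"]] %||% 0)
  )
}
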