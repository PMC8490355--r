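#' Squared first-derivative Euclidean cosine similarity (DEuc)
#'
#' Restricts both spectra to bins whose centers fall in the matching window
#' (default 50-98 I_ex%, excluding sub-detection-limit noise and fully
#' blocked events), takes forward first differences, and returns
#' \deqn{DEuc = \frac{(\sum_i \Delta a_i \Delta b_i)^2}
#'   {\sum_i \Delta a_i^2 \; \sum_i \Delta b_i^2}}
#' i.e. the squared cosine of the angle between the derivative vectors,
#' in `[0, 1]`. Differentiation makes the score invariant to per-bin
#' constant offsets (baseline sloping) and the ratio form to positive
#' scaling of either spectrum.
#'
#' @param a,b Normalized `iex_spectrum` objects on the same grid.
#' @param window Matching window `c(lo, hi)` in I_ex%; bins with centers in
#'   `[lo, hi)` are used. Default `c(50, 98)`.
#' @return The DEuc score, a scalar in `[0, 1]`.
#' @export
deuc <- function(a, b, window = c(50, 98)) {
  assert_spectrum(a, "a")
  assert_spectrum(b, "b")
  if (!isTRUE(all.equal(a$bin_center, b$bin_center))) {
    rlang::abort("spectra are on different grids")
  }
  if (!(window[1] >= 0 && window[1] < window[2] && window[2] <= 100)) {
    rlang::abort("`window` must satisfy 0 <= lo < hi <= 100")
  }
  sel <- a$bin_center >= window[1] & a$bin_center < window[2]
  da <- diff(a$value[sel])
  db <- diff(b$value[sel])
  ssa <- sum(da^2)
  ssb <- sum(db^2)
  if (ssa == 0 || ssb == 0) {
    rlang::abort("degenerate spectrum in window: derivative identically zero")
  }
  sum(da * db)^2 / (ssa * ssb)
}

#' Per-protein mean spectra (the matching database)
#'
#' Averages the normalized, re-aligned replicate spectra of each protein
#' bin-wise, optionally excluding one sample (for leave-one-out matching).
#'
#' @param spectra A tibble with columns `label`, `replicate`, `spectrum`
#'   (list-column of `iex_spectrum`).
#' @param exclude `NULL`, or a `c(label, replicate)` pair identifying the
#'   sample to leave out.
#' @return A tibble `label`, `n`, `spectrum` (list-column of mean spectra).
#' @export
build_database <- function(spectra, exclude = NULL) {
  stopifnot(all(c("label", "replicate", "spectrum") %in% names(spectra)))
  labs <- unique(spectra$label)
  if (!is.null(exclude)) {
    keep <- !(spectra$label == exclude[[1]] & spectra$replicate == exclude[[2]])
    spectra <- spectra[keep, , drop = FALSE]
  }
  if (!all(labs %in% spectra$label)) {
    rlang::abort("a protein has no remaining spectra after exclusion")
  }
  spectra |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      spectrum = {
        m <- rowMeans(sapply(.data$spectrum, function(s) s$value))
        list(new_spectrum(m, normalized = TRUE,
                          label = .data$label[1]))
      },
      .groups = "drop"
    )
}

#' Leave-one-out protein identification by spectral matching
#'
#' For every replicate spectrum (the sample), builds the database of
#' per-protein mean spectra from all other measurements, scores the sample
#' against each protein with [deuc()], and assigns the argmax. Ties are
#' reported as ties (predicted label `NA`), never silently broken. The
#' protein x protein matrix of sample-averaged scores is also returned,
#' normalized per row for display.
#'
#' @param spectra A tibble with columns `label`, `replicate`, `spectrum`
#'   (list-column of normalized, re-aligned `iex_spectrum`); at least 2
#'   proteins with at least 2 replicates each.
#' @param window Matching window, see [deuc()].
#' @param normalization Display scaling of the score matrix: `"row_max_100"`
#'   (row maximum becomes 100, default) or `"row_sum_100"`. Assignments use
#'   raw scores and are identical under both.
#' @return An object of class `porefp_match`: `assignments` (tibble
#'   `label`, `replicate`, `predicted`, `score`, `tie`, `correct`),
#'   `scores` (long tibble `label`, `database`, `score` of sample-averaged
#'   raw DEuc), `score_matrix` (normalized wide matrix, proteins x
#'   proteins), `window`, `normalization`.
#' @export
leave_one_out <- function(spectra, window = c(50, 98),
                          normalization = c("row_max_100", "row_sum_100")) {
  normalization <- match.arg(normalization)
  stopifnot(all(c("label", "replicate", "spectrum") %in% names(spectra)))
  labs <- unique(spectra$label)
  if (length(labs) < 2L) rlang::abort("need at least 2 proteins")
  if (any(table(spectra$label) < 2L)) {
    rlang::abort("need at least 2 replicates per protein for leave-one-out")
  }
  per_sample <- purrr::map_dfr(seq_len(nrow(spectra)), function(i) {
    db <- build_database(
      spectra,
      exclude = list(spectra$label[i], spectra$replicate[i])
    )
    sc <- vapply(db$spectrum, function(ref) {
      deuc(spectra$spectrum[[i]], ref, window)
    }, numeric(1))
    tibble::tibble(
      label = spectra$label[i], replicate = spectra$replicate[i],
      database = db$label, score = sc
    )
  })
  assignments <- per_sample |>
    dplyr::group_by(.data$label, .data$replicate) |>
    dplyr::summarise(
      tie = sum(.data$score == max(.data$score)) > 1L,
      predicted = {
        best <- .data$database[.data$score == max(.data$score)]
        if (length(best) > 1L) NA_character_ else best
      },
      score = max(.data$score),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      correct = !.data$tie & !is.na(.data$predicted) &
        .data$predicted == .data$label
    ) |>
    dplyr::select("label", "replicate", "predicted", "score", "tie", "correct")
  scores <- per_sample |>
    dplyr::group_by(.data$label, .data$database) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop")
  wide <- tidyr::pivot_wider(
    scores, names_from = "database", values_from = "score"
  )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$label
  mat <- mat[, rownames(mat), drop = FALSE]
  norm_mat <- t(apply(mat, 1, function(r) {
    if (normalization == "row_max_100") 100 * r / max(r) else 100 * r / sum(r)
  }))
  structure(
    list(
      assignments = assignments, scores = scores, score_matrix = norm_mat,
      window = window, normalization = normalization
    ),
    class = "porefp_match"
  )
}

#' @export
print.porefp_match <- function(x, ...) {
  acc <- mean(x$assignments$correct)
  cat(sprintf(
    "<porefp_match> %d samples, %d proteins, window [%g, %g) I_ex%%\n  correct assignments: %d/%d (%.0f%%)\n",
    nrow(x$assignments), nrow(x$score_matrix), x$window[1], x$window[2],
    sum(x$assignments$correct), nrow(x$assignments), 100 * acc
  ))
  invisible(x)
}
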