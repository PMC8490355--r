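#' Plot an ionic-current trace
#'
#' Long traces are downsampled for display by plotting per-chunk minima and
#' maxima, preserving the visual envelope of blockade events.
#'
#' @param object A `porefp_trace`.
#' @param max_points Display budget; default 20000.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.porefp_trace <- function(object, max_points = 20000, ...) {
  df <- object
  n <- nrow(df)
  if (n > max_points) {
    chunk <- ceiling(n / (max_points / 2))
    grp <- (seq_len(n) - 1) %/% chunk
    df <- df |>
      dplyr::mutate(.grp = grp) |>
      dplyr::group_by(.data$.grp) |>
      dplyr::summarise(
        time = c(.data$time[which.min(.data$current)],
                 .data$time[which.max(.data$current)]),
        current = range(.data$current),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$time)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$current)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "current (pA)") +
    ggplot2::theme_minimal()
}

#' Plot an excluded-current spectrum
#'
#' @param object An `iex_spectrum`.
#' @param ... Unused.
#' @return A ggplot column chart over the 1 I_ex% bins.
#' @export
autoplot.iex_spectrum <- function(object, ...) {
  lab <- attr(object, "label")
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_center, .data$value)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::labs(
      x = expression(I[ex] * " (%)"),
      y = if (isTRUE(attr(object, "normalized"))) "fraction of events" else "count",
      title = if (!is.na(lab)) lab else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a calibration model with its points
#'
#' @param object A `porefp_calibration`.
#' @param ... Unused.
#' @return A ggplot of the fitted polynomial (and calibration points when
#'   the model carries them).
#' @export
autoplot.porefp_calibration <- function(object, ...) {
  grid <- tibble::tibble(mass = seq(object$domain[1], object$domain[2],
                                    length.out = 200))
  grid$iex <- suppressWarnings(predict_iex(object, grid$mass))
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$mass, .data$iex)) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::labs(x = "peptide mass (Da)", y = expression(I[ex] * " (%)")) +
    ggplot2::theme_minimal()
  if (!is.null(object$fit)) {
    pts <- object$fit$model
    names(pts)[1:2] <- c("iex", "mass")
    p <- p + ggplot2::geom_point(data = pts, size = 2, colour = "grey40")
  }
  p
}

#' Plot a leave-one-out score matrix
#'
#' @param object A `porefp_match`.
#' @param ... Unused.
#' @return A ggplot tile heatmap of normalized sample-averaged scores, the
#'   matched protein on the y axis and the database protein on the x axis.
#' @export
autoplot.porefp_match <- function(object, ...) {
  m <- object$score_matrix
  df <- tibble::as_tibble(m, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "database", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(.data$database, .data$sample,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "score (%)") +
    ggplot2::labs(x = "database protein", y = "matched protein") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a re-alignment error curve
#'
#' @param object A `porefp_alignment`.
#' @param ... Unused.
#' @return A ggplot of residual sum of squares versus candidate offset, the
#'   chosen offset marked.
#' @export
autoplot.porefp_alignment <- function(object, ...) {
  ggplot2::ggplot(object$error_curve,
                  ggplot2::aes(.data$offset, .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$offset, linetype = "dotted") +
    ggplot2::labs(
      x = expression(Delta * I[ex] * " (%)"),
      y = "residual sum of squares"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
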