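#' Tidy and glance methods for fitted atlases and shape scores
#'
#' `tidy.daa_atlas()` returns one row per specimen and control point with
#' the momentum components; `glance.daa_atlas()` a one-row model summary.
#' `tidy.shape_scores()` returns one row per specimen with the score
#' columns; `glance.shape_scores()` summarises the spectrum.
#'
#' @param x A `daa_atlas` or `shape_scores` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.daa_atlas <- function(x, ...) {
  ids <- names(x$momenta) %||% paste0("spec_", seq_along(x$momenta))
  purrr::map2_dfr(x$momenta, ids, function(m, id) {
    tibble::tibble(specimen_id = id, cp_index = seq_len(nrow(m)),
                   mx = m[, 1], my = m[, 2], mz = m[, 3])
  })
}

#' @rdname tidiers
#' @export
glance.daa_atlas <- function(x, ...) {
  tibble::tibble(n_specimens = length(x$momenta),
                 n_control_points = nrow(x$control_points),
                 sigma = x$kernel$sigma, sigma_w = x$kernel$sigma_w,
                 noise_sigma = x$noise_sigma, attachment = x$attachment,
                 initial_loss = x$loss_trace[1],
                 final_loss = x$loss_trace[length(x$loss_trace)],
                 n_accepted = length(x$loss_trace) - 1L)
}

#' @rdname tidiers
#' @export
tidy.shape_scores <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "specimen_id")
}

#' @rdname tidiers
#' @export
glance.shape_scores <- function(x, ...) {
  tibble::tibble(n_specimens = nrow(x$scores), n_axes = ncol(x$scores),
                 axis_kind = x$axis_kind,
                 pc1_percent = x$percent_variance[1],
                 pc2_percent = if (ncol(x$scores) > 1)
                   x$percent_variance[2] else NA_real_)
}

#' Plot methods
#'
#' `autoplot.shape_scores()` draws the ordination scatter of two axes with
#' optional group colouring; `autoplot.daa_atlas()` the loss trace over
#' accepted iterations.
#'
#' @param object A `shape_scores` or `daa_atlas`.
#' @param axes Which two axes to plot (default 1:2).
#' @param groups Optional named specimen -> label vector for colouring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shape_scores <- function(object, axes = c(1, 2), groups = NULL,
                                  ...) {
  df <- tidy(object)
  nm <- paste0("pc", axes)
  if (!is.null(groups)) df$group <- groups[df$specimen_id]
  pv <- object$percent_variance[axes]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[nm[1]]], .data[[nm[2]]])) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", toupper(nm[1]), pv[1]),
      y = sprintf("%s (%.1f%%)", toupper(nm[2]), pv[2]),
      title = sprintf("%s shape space", toupper(object$axis_kind))) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' @rdname autoplot.shape_scores
#' @export
autoplot.daa_atlas <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loss_trace) - 1L,
                       loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "accepted iteration", y = "total loss",
                  title = "Atlas estimation loss trace") +
    ggplot2::theme_minimal()
}
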