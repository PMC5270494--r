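# ggplot2 views of sweeps, ensembles, models and reports.

#' Plot a handful of raw sweeps and their ensemble mean
#'
#' @param object A `sweep_matrix`.
#' @param n_sweeps Number of individual sweeps to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_matrix
#' @export
autoplot.sweep_matrix <- function(object, n_sweeps = 5, ...) {
  n_show <- min(n_sweeps, nrow(object$data))
  df <- tibble::tibble(
    sweep = rep(seq_len(n_show), each = ncol(object$data)),
    sample = rep(seq_len(ncol(object$data)) - 1L, n_show),
    value = as.numeric(t(object$data[seq_len(n_show), , drop = FALSE]))
  )
  mean_df <- tibble::tibble(sample = seq_len(ncol(object$data)) - 1L,
                            value = colMeans(object$data))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$value,
                                   group = .data$sweep)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = mean_df, ggplot2::aes(group = NULL),
                       colour = "firebrick", linewidth = 0.7) +
    ggplot2::labs(
      title = sprintf("Subject %s, channel %s, state %s",
                      object$subject_id, object$channel, object$state),
      subtitle = sprintf("%d of %d sweeps (grey), ensemble mean (red)",
                         n_show, nrow(object$data)),
      x = "sample (0-based)", y = "amplitude (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot ensemble-averaged sweeps by state
#'
#' Overlays ensemble-averaged waveforms, coloured by sleep state and
#' faceted by subject, making the wake/deep-sleep amplitude difference
#' visible.
#'
#' @param data Ensemble tibble (see [windowed_averages()]).
#' @param max_windows Windows drawn per (subject, state).
#' @return A ggplot object.
#' @export
plot_ensemble <- function(data, max_windows = 5) {
  stopifnot(is.data.frame(data), "values" %in% names(data))
  d <- dplyr::slice_head(dplyr::group_by(data, .data$subject_id,
                                         .data$channel, .data$state),
                         n = max_windows)
  d <- dplyr::ungroup(d)
  long <- tidyr::unnest(
    dplyr::mutate(d, sample = purrr::map(.data$values,
                                         ~ seq_along(.x) - 1L)),
    c("values", "sample"))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$values,
                                     colour = .data$state,
                                     group = interaction(.data$state,
                                                         .data$window_index))) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::labs(x = "sample (0-based)", y = "amplitude (a.u.)",
                  colour = "state",
                  title = "Ensemble-averaged 40-Hz ASSR sweeps") +
    ggplot2::theme_minimal()
}

#' Plot LVQ prototypes (and training history when available)
#'
#' @param object An `lvq_model`.
#' @param ... Unused.
#' @return A ggplot object of the prototype waveforms coloured by class.
#' @method autoplot lvq_model
#' @export
autoplot.lvq_model <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::unnest(
    dplyr::mutate(td, sample = purrr::map(.data$weights,
                                          ~ seq_along(.x) - 1L)),
    c("weights", "sample"))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$weights,
                                     colour = .data$class,
                                     group = .data$prototype)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sample (0-based)", y = "prototype weight",
                  title = sprintf("LVQ prototypes (%d hidden neurons)",
                                  nrow(object$prototypes))) +
    ggplot2::theme_minimal()
}

#' Plot per-subject error rates of an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-subject error percentages with the
#'   mean as a dashed line.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$rows,
                  ggplot2::aes(.data$test_subject, .data$error_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_error_pct,
                        linetype = "dashed") +
    ggplot2::labs(x = "test subject", y = "error (%)",
                  title = sprintf("%s design, %s classifier (mean %.2f%%)",
                                  object$design, object$classifier,
                                  object$mean_error_pct)) +
    ggplot2::theme_minimal()
}
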