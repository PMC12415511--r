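#' Plot condition-average waveforms of an epoch set
#'
#' Cluster-pooled average voltage over time, one line per condition.
#'
#' @param object An [epoch_set].
#' @param condition_col Condition column in the trial keys.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epoch_set <- function(object, condition_col = "condition", ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$time,
                    condition = .data[[condition_col]]) |>
    dplyr::summarise(voltage = mean(.data$voltage), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$voltage,
                                   color = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = sprintf("Time relative to %s onset (ms)", object$lock),
                  y = "Amplitude (µV, negative up)")
}

#' Plot a composite waveform with its scoring window
#'
#' @param object A [composite_waveform()].
#' @param window Optional [find_peak_window()] result to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.composite_waveform <- function(object, window = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                            y = .data$amplitude)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Time (ms)", y = "Amplitude (µV, negative up)")
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = window$window[1],
                               xmax = window$window[2], ymin = -Inf,
                               ymax = Inf, alpha = 0.15)
  }
  p
}

#' Learning curves: test-phase accuracy by block and group
#'
#' @param trials A cohort trial table ([simulate_cohort()]).
#' @param design The [task_design()] for accuracy coding.
#' @return A ggplot object (mean accuracy per block, by group and agency).
#' @export
plot_learning_curve <- function(trials, design = task_design()) {
  df <- trials |>
    dplyr::filter(.data$phase == "test") |>
    filter_valid() |>
    code_accuracy(design) |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$group, .data$agency, .data$block) |>
    dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block, y = .data$accuracy,
                                   color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$agency) +
    ggplot2::labs(x = "Test block", y = "Choice accuracy")
}

#' Multistart diagnostics for an RL fit
#'
#' Dot plot of per-start NLLs, highlighting the best start; flat profiles
#' indicate a well-identified optimum.
#'
#' @param object An [fit_rl()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rl_fit <- function(object, ...) {
  df <- object$starts
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$nll,
                                   shape = .data$converged)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$nll, linetype = 2) +
    ggplot2::labs(x = "Start", y = "NLL",
                  title = sprintf("%s: best NLL %.2f", object$model$id,
                                  object$nll))
}
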