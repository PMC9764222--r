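# ggplot2 visualisations for the main result types.

#' Plot the h1/h2 amplitude profiles
#'
#' One panel per deviant position, amplitude against sound position — the
#' shape of the habituation (decaying) vs prediction-error (hazard-scaled)
#' hypotheses.
#'
#' @param object An `amplitude_model` tibble from [amplitude_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amplitude_model <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data$amplitude)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$position ==
                                       .data$deviant_position), size = 2) +
    ggplot2::facet_wrap(~deviant_position,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_x_continuous(breaks = 1:8) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey30",
                                            "TRUE" = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(title = paste("Amplitude model", object$model[[1]]),
                  x = "sound position", y = "amplitude") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of SSA magnitude per ROI
#'
#' @param object An `ssa_map` from [ssai_map()].
#' @param ... Unused.
#' @return A ggplot object (histograms of SSAi, one facet per ROI when ROI
#'   labels are present).
#' @export
autoplot.ssa_map <- function(object, ...) {
  p <- ggplot2::ggplot(dplyr::filter(object, .data$defined),
                       ggplot2::aes(x = .data$ssai)) +
    ggplot2::geom_histogram(bins = 30, fill = "mediumpurple",
                            colour = "white") +
    ggplot2::labs(x = "SSA index", y = "voxels") +
    ggplot2::theme_minimal()
  if ("roi" %in% names(object)) p <- p + ggplot2::facet_wrap(~roi)
  p
}

#' Plot the Bayes-factor distribution of the model comparison
#'
#' Histogram of per-voxel log K (h2 over h1), faceted by ROI; positive
#' values favor the prediction-error model.
#'
#' @param object A `posterior_maps` tibble from [group_maps()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.posterior_maps <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$log_K)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(log ~ K[h2 / h1]), y = "voxels") +
    ggplot2::theme_minimal()
  if ("roi" %in% names(object)) p <- p + ggplot2::facet_wrap(~roi)
  p
}

#' Plot a run schedule's deviant timing
#'
#' Sound onsets of each trial against time, deviants highlighted; a quick
#' visual check of the pseudorandomisation and ITI structure.
#'
#' @param run A `run_schedule`.
#' @return A ggplot object.
#' @export
plot_run_schedule <- function(run) {
  ev <- event_table(run)
  ev$is_deviant <- grepl("^dev", ev$trial_type)
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$onset, y = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_deviant), size = 0.8) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey60",
                                            "TRUE" = "firebrick"),
                                 labels = c("standard", "deviant"),
                                 name = NULL) +
    ggplot2::labs(x = "time (s)", y = "trial") +
    ggplot2::theme_minimal()
}
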