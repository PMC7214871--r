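# autoplot() methods for the tabular result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an accuracy curve
#'
#' ANN curves (per output frame) are drawn as a step function over
#' simulation steps when `n_sf` is given; SNN curves are drawn per step.
#'
#' @param object An `accuracy_curve` tibble.
#' @param n_sf Steps per frame used to place an ANN curve on the step
#'   axis (ignored for SNN curves, which carry their own `step` column).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_curve <- function(object, n_sf = NULL, ...) {
  kind <- attr(object, "kind") %||% "accuracy"
  df <- tibble::as_tibble(object)
  if (!"step" %in% names(df)) {
    if (!is.null(n_sf)) {
      df$step <- df$frame * n_sf
    } else {
      return(ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$accuracy)) +
               ggplot2::geom_step(colour = "#b2182b") +
               ggplot2::labs(x = "rollout frame", y = "accuracy",
                             title = "ANN accuracy over rollout frames") +
               ggplot2::ylim(0, 1))
    }
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$accuracy)) +
    ggplot2::geom_step(colour = if (kind == "snn") "#2166ac" else "#b2182b") +
    ggplot2::labs(x = "simulation step", y = "accuracy",
                  title = sprintf("%s accuracy over simulation steps",
                                  toupper(kind))) +
    ggplot2::ylim(0, 1)
}

#' Plot combined ANN and SNN accuracy curves
#'
#' @param ann_curve An [ann_accuracy_curve()] result.
#' @param snn_curve An [snn_accuracy_curve()] result.
#' @param n_sf Simulation steps per frame (places the ANN curve on the
#'   step axis).
#' @return A ggplot object.
#' @export
plot_accuracy_comparison <- function(ann_curve, snn_curve, n_sf) {
  l_s <- min(ann_curve$frame) - 1L
  ann_df <- tibble::tibble(
    step = (l_s * n_sf + 1L):(max(ann_curve$frame) * n_sf),
    accuracy = rep(ann_curve$accuracy, each = n_sf),
    network = "ANN")
  snn_df <- tibble::tibble(step = snn_curve$step,
                           accuracy = snn_curve$accuracy, network = "SNN")
  df <- dplyr::bind_rows(ann_df, snn_df)
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$accuracy,
                                   colour = .data$network)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(ANN = "#b2182b", SNN = "#2166ac")) +
    ggplot2::labs(x = "simulation step", y = "accuracy") +
    ggplot2::ylim(0, 1)
}

#' Plot an n_sf sweep
#'
#' Accuracy ratio `rho` against SNN synaptic operations, each point
#' labelled with its `n_sf`.
#'
#' @param object An `nsf_sweep` tibble from [sweep_nsf()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nsf_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$snn_mops, .data$rho)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_sf), vjust = -0.8) +
    ggplot2::labs(x = "SNN synaptic operations [MOps]",
                  y = "accuracy ratio rho")
}

#' @importFrom rlang .data %||%
NULL
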