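#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dFVA envelope
#'
#' Objective-flux trajectories of the max and min directions (the dFVA
#' envelope), or the tracked concentration trajectories.
#'
#' @param object a [run_dfva()] result
#' @param what "flux" (default) or a tracked place id
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.dfva_result <- function(object, what = "flux", ...) {
  d <- object$trajectory
  if (what == "flux") {
    ggplot2::ggplot(dplyr::filter(d, !is.na(.data$flux)),
                    ggplot2::aes(.data$time, .data$flux,
                                 colour = .data$direction)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (h)",
                    y = paste0(object$objective, " flux (mmol/g DW/h)"),
                    colour = "direction") +
      ggplot2::theme_minimal()
  } else {
    if (!what %in% names(d)) stop("'", what, "' is not a tracked place")
    ggplot2::ggplot(d, ggplot2::aes(.data$time, .data[[what]],
                                    colour = .data$direction)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (h)", y = paste0(what, " (mM)"),
                    colour = "direction") +
      ggplot2::theme_minimal()
  }
}

#' Heatmap of a trajectory's flux capabilities
#'
#' Event-ordered flux matrix with the conventional colouring: positive
#' flux green, negative red, zero black; simulated (arbitrary-unit) time
#' progresses left to right.
#'
#' @param object a [run_trajectory()] result
#' @param reactions rows to show (default: all monitored)
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.trajectory <- function(object, reactions = object$monitored, ...) {
  M <- flux_heatmap_matrix(object, reactions)
  d <- tidyr::expand_grid(reaction = rownames(M),
                          step = seq_len(ncol(M))) |>
    dplyr::mutate(flux = M[cbind(match(.data$reaction, rownames(M)),
                                 .data$step)])
  lim <- max(abs(d$flux), 1e-9)
  ggplot2::ggplot(d, ggplot2::aes(.data$step, .data$reaction,
                                  fill = .data$flux)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "black", high = "green",
                                  limits = c(-lim, lim)) +
    ggplot2::labs(x = "simulated time (arbitrary units)", y = NULL,
                  fill = "flux") +
    ggplot2::theme_minimal()
}

#' Plot a fitted Michaelis-Menten depletion curve over the data
#'
#' @param object an [fit_mm()] result
#' @param data the data the model was fitted to (optional; defaults to the
#'   fit's stored data)
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.mm_fit <- function(object, data = NULL, ...) {
  if (!object$identifiable) stop("fit was non-identifiable; nothing to plot")
  if (is.null(data)) data <- eval(object$fit$data)
  est <- object$estimate
  grid <- tibble::tibble(time = seq(min(data$time), max(data$time),
                                    length.out = 200))
  grid$concentration <- mm_depletion(grid$time, est[["S0"]], est[["Vmax"]],
                                     est[["Km"]])
  ggplot2::ggplot(data, ggplot2::aes(.data$time, .data$concentration)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "time (h)", y = "concentration (mM)") +
    ggplot2::theme_minimal()
}
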