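#' Plot a hypnodensity track
#'
#' Stacked per-epoch state probabilities (the hypnodensity graph) with
#' the per-second arousal probability trace beneath.
#'
#' @param object an `nbs_prediction`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nbs_prediction <- function(object, ...) {
  hd <- tidyr::pivot_longer(object$hypnodensity, -"epoch",
                            names_to = "state", values_to = "prob")
  hd$state <- factor(hd$state, levels = c("WAKE", "REM", "NREM"))
  ggplot2::ggplot(hd, ggplot2::aes(x = .data$epoch * 0.5, y = .data$prob,
                                   fill = .data$state)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_fill_manual(values = c(WAKE = "#E69F00", REM = "#CC79A7",
                                          NREM = "#0072B2")) +
    ggplot2::labs(x = "time (min)", y = "state probability",
                  fill = NULL, title = "Hypnodensity") +
    ggplot2::theme_minimal()
}

#' Plot arousal probabilities with detected events
#'
#' @param pred an `nbs_prediction`.
#' @param threshold detection threshold drawn as a reference line.
#' @return a ggplot object.
#' @export
plot_arousal_track <- function(pred, threshold = 0.5) {
  df <- tibble(second = seq_along(pred$arousal_probs) - 1L,
               prob = pred$arousal_probs)
  ev <- detect_arousals(pred, threshold)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$second / 60, .data$prob)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "time (min)", y = "arousal probability") +
    ggplot2::theme_minimal()
  if (nrow(ev) > 0) {
    p <- p + ggplot2::annotate(
      "rect", xmin = ev$onset / 60, xmax = (ev$onset + ev$duration) / 60,
      ymin = 0, ymax = 1, alpha = 0.2, fill = "red")
  }
  p
}

#' Bland-Altman plot
#'
#' Differences against pair means with the bias (dot-dash) and 95%
#' limits of agreement (dashed).
#'
#' @param object a [bland_altman()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "dotdash") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "blue") +
    ggplot2::labs(x = "mean of pair", y = "difference (pred - ref)") +
    ggplot2::theme_minimal()
}

#' Plot a hypnogram
#'
#' Classic staircase hypnogram (Wake on top, REM, then NREM).
#'
#' @param hyp a hypnogram.
#' @return a ggplot object.
#' @export
plot_hypnogram <- function(hyp) {
  hyp <- as_hypnogram(hyp)
  lev <- c(WAKE = 3, REM = 2, NREM = 1, ARTIFACT = 0)
  df <- tibble(time_min = hyp$epoch * 0.5,
               level = lev[as.character(hyp$state)])
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$level)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = unname(lev[1:3]),
                                labels = names(lev)[1:3]) +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
}
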