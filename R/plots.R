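#' Plot an airspace mask or tissue mask
#'
#' @param mask An `airspace_mask`, `parenchyma_sim`, `epithelium_sim` or
#'   logical matrix.
#' @param pixel_size_um Pixel size when `mask` is a bare matrix.
#' @return A ggplot raster of the binary classification in micrometres.
#' @export
plot_mask <- function(mask, pixel_size_um = 1) {
  if (inherits(mask, c("parenchyma_sim", "epithelium_sim"))) {
    pixel_size_um <- mask$pixel_size_um; mask <- mask$mask
  } else if (inherits(mask, "airspace_mask")) {
    pixel_size_um <- mask$pixel_size_um; mask <- mask$mask
  }
  df <- tidyr::expand_grid(y = seq_len(nrow(mask)), x = seq_len(ncol(mask)))
  df$air <- mask[cbind(df$y, df$x)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * pixel_size_um,
                                   y = .data$y * pixel_size_um,
                                   fill = .data$air)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey25", `TRUE` = "white"),
                               name = "air") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sk_fit <- function(object, ...) {
  if (!object$converged) abort_bad_arg("cannot plot a failed fit.")
  d <- object$data
  A <- object$estimates[["A"]]; B <- object$estimates[["B"]]
  K <- object$estimates[["K"]]
  grid <- tibble(pressure_cmh2o = seq(min(d$pressure_cmh2o),
                                      max(d$pressure_cmh2o), length.out = 200))
  grid$volume_ml <- A - B * exp(-K * grid$pressure_cmh2o)
  ggplot2::ggplot(d, ggplot2::aes(.data$pressure_cmh2o, .data$volume_ml)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::labs(x = "pressure (cmH2O)", y = "volume (mL)",
                  title = sprintf("V(P) = %.3g - %.3g exp(-%.3g P)", A, B, K)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cohort_logit <- function(object, ...) {
  forest_plot(tidy(object))
}

#' @export
autoplot.cohort_report <- function(object, ...) {
  tab <- tidy(object)
  if (!nrow(tab)) abort_bad_arg("report contains no fitted model to plot.")
  forest_plot(tab) +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome))
}

forest_plot <- function(tab) {
  tab <- dplyr::filter(tab, is.finite(.data$odds_ratio))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$odds_ratio,
                                    y = stats::reorder(.data$term, seq_len(nrow(tab))))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci95_low,
                                         xmax = .data$ci95_high), height = 0.2,
                            na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a calcium trace with its epochs
#'
#' @param trace Tibble from [sim_calcium_trace()] or with the same columns.
#' @return A ggplot line plot coloured by epoch.
#' @export
plot_calcium_trace <- function(trace) {
  check_columns(trace, c("time_s", "fluorescence", "epoch"), "trace")
  ggplot2::ggplot(trace, ggplot2::aes(.data$time_s, .data$fluorescence,
                                      colour = .data$epoch)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a dose-response summary
#'
#' @param summary Tibble from [aggregate_dose_response()].
#' @return A ggplot of mean +/- SEM against dose (log x).
#' @export
plot_dose_response <- function(summary) {
  check_columns(summary, c("dose", "mean", "sem"), "summary")
  ggplot2::ggplot(summary, ggplot2::aes(.data$dose, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "response (mean ± SEM)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
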