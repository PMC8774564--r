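#' Plot a fitted voxel series
#'
#' Shows the measured magnitudes, the fitted total signal and the fitted
#' per-component curves against inversion time.
#'
#' @param object An [ir_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ir_fit
#' @export
autoplot.ir_fit <- function(object, ...) {
  ti <- seq(min(object$series$ti_ms), max(object$series$ti_ms),
            length.out = 300)
  total <- tibble(ti_ms = ti, magnitude = ir_signal(object$params, ti))
  comps <- purrr::map_dfr(seq_len(nrow(object$params)), function(j) {
    tibble(component = factor(object$params$component[j]),
           ti_ms = ti,
           magnitude = ir_component_signal(object$params$m0[j],
                                           object$params$t1_ms[j], ti))
  })
  ggplot2::ggplot(object$series, ggplot2::aes(x = .data$ti_ms, y = .data$magnitude)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_line(data = total, linewidth = 0.8) +
    ggplot2::geom_line(data = comps,
                       ggplot2::aes(colour = .data$component),
                       linetype = "dashed") +
    ggplot2::labs(x = "inversion time TI [ms]", y = "signal magnitude",
                  colour = "component",
                  title = sprintf("%d-component inversion-recovery fit",
                                  object$n_components)) +
    ggplot2::theme_minimal()
}

#' Plot an error-table experiment
#'
#' Mean relative error (with min-max ribbon) per coefficient family
#' against the experiment's sweep variable (number of starts or noise
#' variance).
#'
#' @param object An `ir_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ir_experiment
#' @export
autoplot.ir_experiment <- function(object, ...) {
  s <- object$summary
  xvar <- if ("variance" %in% names(s)) "variance" else "n_starts"
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data[[xvar]],
                                       y = .data$mean_error_pct,
                                       colour = .data$family,
                                       fill = .data$family)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min_error_pct,
                                      ymax = .data$max_error_pct),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "relative error [%]") +
    ggplot2::theme_minimal()
  if (xvar == "variance")
    p <- p + ggplot2::scale_x_continuous(trans = "log10") +
      ggplot2::labs(x = "noise variance")
  else p <- p + ggplot2::labs(x = "number of starting points")
  p
}

#' Histogram of pooled voxelwise T1 estimates
#'
#' The phantom analogue of a whole-object T1 spectrum: all matched T1
#' estimates across object voxels, where separated modes near the true
#' pool values indicate a successful decomposition.
#'
#' @param object An `ir_phantom_experiment` (or a numeric vector of T1
#'   estimates).
#' @param binwidth Histogram bin width in ms.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_t1_histogram <- function(object, binwidth = 5, ...) {
  t1 <- if (is.numeric(object)) object else object$t1_pooled
  df <- tibble(t1_ms = t1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t1_ms)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35") +
    ggplot2::labs(x = "estimated T1 [ms]", y = "voxel count",
                  title = "Voxelwise T1 estimates") +
    ggplot2::theme_minimal()
  if (!is.numeric(object))
    p <- p + ggplot2::geom_vline(
      xintercept = object$phantom$spec$pools$t1_ms,
      linetype = "dotted")
  p
}

#' @rdname plot_t1_histogram
#' @method autoplot ir_phantom_experiment
#' @export
autoplot.ir_phantom_experiment <- function(object, binwidth = 5, ...) {
  plot_t1_histogram(object, binwidth = binwidth, ...)
}
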