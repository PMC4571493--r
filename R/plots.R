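#' Plot an encoding sweep
#'
#' Mean cross-validated r-squared against the number of causal markers
#' `s`, one line per encoding: the oligogenic/polygenic comparison at a
#' glance. Points show the per-dataset values, lines the across-dataset
#' means.
#'
#' @param object A `gp_sweep` tibble from [encoding_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gp_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s, y = .data$mean_r2,
                                       colour = .data$encoding)) +
    ggplot2::geom_point(alpha = 0.4, position = ggplot2::position_jitter(
      width = 0, height = 0)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2.5) +
    ggplot2::scale_x_log10(breaks = unique(object$s)) +
    ggplot2::labs(x = "causal markers (s)",
                  y = expression("mean CV" ~ r^2),
                  colour = "encoding") +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation report
#'
#' Per-fold r-squared bars with the mean as a horizontal line.
#'
#' @param object A `cv_report` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$fold), y = .data$r2)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$mean_r2, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "fold", y = expression(r^2),
                  subtitle = paste0("encoding = ", object$config$encoding,
                                    ", mean r2 = ",
                                    signif(object$mean_r2, 3))) +
    ggplot2::theme_minimal()
}
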