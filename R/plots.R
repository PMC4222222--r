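# Diagnostic figures.  ggplot2 is suggested, not imported; both functions
# degrade to an informative error when it is unavailable.

#' Scatterplot of corrected volume against ICV with its regression line
#'
#' The visual check that a correction removed the head-size trend: after
#' an adequate correction the fitted line is parallel to the x-axis.
#'
#' @param corrected corrected values (one region).
#' @param icv matching ICV values (cc).
#' @param label plot title, e.g. region and method.
#' @return A ggplot object.
#' @export
plot_corrected_vs_icv <- function(corrected, icv, label = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- data.frame(icv = icv, corrected = as.numeric(corrected))
  ggplot2::ggplot(df, ggplot2::aes(x = icv, y = corrected)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.7) +
    ggplot2::labs(x = "ICV (cc)", y = "corrected volume", title = label) +
    ggplot2::theme_minimal()
}

#' Prediction-error scatter of two models with the 45-degree line
#'
#' One point per region: LOOCV prediction error of `model_x` against
#' `model_y`.  Points below the identity line favour the x-axis model.
#'
#' @param comparison a [compare_models()] result.
#' @param model_x,model_y model names present in the comparison.
#' @return A ggplot object.
#' @export
plot_prediction_errors <- function(comparison, model_x = "power_law",
                                   model_y = "linear") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  stopifnot(inherits(comparison, "model_comparison"))
  res <- comparison$results
  x <- res[res$model == model_x, c("region", "prediction_error")]
  y <- res[res$model == model_y, c("region", "prediction_error")]
  df <- merge(x, y, by = "region", suffixes = c("_x", "_y"))
  ggplot2::ggplot(df, ggplot2::aes(x = prediction_error_x,
                                   y = prediction_error_y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste("prediction error,", model_x),
                  y = paste("prediction error,", model_y)) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("prediction_error_x", "prediction_error_y",
                         "corrected"))
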