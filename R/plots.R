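#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Predicted vs chronological age scatter
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot: out-of-fold predicted age against chronological age
#'   with the identity line.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_result <- function(object, ...) {
  m <- object$metrics
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$age, y = .data$predicted_age)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "Chronological age (y)", y = "Brain-predicted age (y)",
      title = sprintf("%d-fold CV: r = %.2f, MAE = %.2f y",
                      object$folds, m$r, m$mae)
    ) +
    ggplot2::theme_minimal()
}

#' Null distribution of the permutation test
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot: histogram of permuted CV correlations with the
#'   observed correlation marked.
#' @exportS3Method ggplot2::autoplot
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(r = object$r_perm), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$r_obs, colour = "red") +
    ggplot2::labs(x = "Permuted CV correlation",
                  y = "Count",
                  title = sprintf("p = %.4g (%d permutations)",
                                  object$p, object$n_perm)) +
    ggplot2::theme_minimal()
}

#' Brain-PAD distribution by group
#'
#' @param predictions Tibble with `group` and `brain_pad` columns (e.g.
#'   `run$predictions` from [run_pipeline()]).
#' @return A ggplot boxplot with jittered points.
#' @export
plot_brainpad <- function(predictions) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$group, y = .data$brain_pad)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "Brain-PAD (y)") +
    ggplot2::theme_minimal()
}

#' Brain-PAD against a covariate, by group
#'
#' @param predictions Tibble with `group`, `brain_pad` and the covariate.
#' @param covariate Covariate column name (e.g. "bmi", "gm_ml").
#' @return A ggplot scatter with per-group linear fits.
#' @export
plot_brainpad_covariate <- function(predictions, covariate) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data[[covariate]], y = .data$brain_pad,
                               colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = covariate, y = "Brain-PAD (y)", colour = NULL) +
    ggplot2::theme_minimal()
}
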