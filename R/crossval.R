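#' Accuracy metrics for age predictions
#'
#' Pearson r between predicted and chronological age, R^2 = r^2 (variance
#' explained in the correlation sense), mean absolute error and root mean
#' squared error in years.
#'
#' @param predicted,age Numeric vectors, years.
#' @return Tibble: `r`, `r2`, `mae`, `rmse`.
#' @export
age_prediction_metrics <- function(predicted, age) {
  stopifnot(length(predicted) == length(age))
  err <- predicted - age
  r <- safe_cor(predicted, age)
  tibble::tibble(
    r = r, r2 = r^2,
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2))
  )
}

safe_cor <- function(x, y) {
  if (stats::sd(x) < 1e-300 || stats::sd(y) < 1e-300) return(0)
  stats::cor(x, y)
}

make_folds <- function(n, folds, seed) {
  if (n < folds) {
    warning("N = ", n, " < ", folds, " folds; reducing to ", n, " folds",
            call. = FALSE)
    folds <- n
  }
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  # chunk the permutation into near-equal folds (sizes differ by <= 1)
  sizes <- rep(n %/% folds, folds) + c(rep(1L, n %% folds),
                                       rep(0L, folds - n %% folds))
  assign <- integer(n)
  assign[perm] <- rep(seq_len(folds), times = sizes)
  assign
}

cv_on_kernel <- function(K, ages, fold_assign, hyper) {
  n <- length(ages)
  pred <- numeric(n)
  for (f in sort(unique(fold_assign))) {
    te <- which(fold_assign == f)
    tr <- which(fold_assign != f)
    fit <- gpr_fit(K[tr, tr, drop = FALSE], ages[tr], hyper = hyper)
    pred[te] <- fit$mu +
      fit$signal_scale * drop(K[te, tr, drop = FALSE] %*% fit$alpha)
  }
  pred
}

#' 10-fold cross-validated brain-age prediction
#'
#' Randomly chunks subjects into near-equal folds (seeded), fits the GPR
#' model on each training split — including hyperparameter optimization
#' inside the training fold only, so no information leaks from the held-out
#' fold — predicts the held-out subjects, and reports Pearson r, R^2, MAE
#' and RMSE over the out-of-fold predictions. Every subject is predicted
#' exactly once.
#'
#' @param features Feature matrix (rows = subjects) or a prebuilt
#'   `similarity_kernel`.
#' @param ages Chronological ages (years).
#' @param folds Number of folds (default 10; reduced with a warning when
#'   N < folds).
#' @param seed Integer seed for the fold assignment.
#' @param hyper Passed to [gpr_fit()] per fold.
#' @param scale_mode Kernel scaling when `features` is a matrix.
#' @return A `cv_result`: `predictions` tibble (subject_id, age,
#'   predicted_age, brain_pad, fold), `metrics` tibble, `folds`, `seed`.
#' @export
cv_gpr <- function(features, ages, folds = 10, seed = 1L, hyper = "optimize",
                   scale_mode = "by_voxel_count") {
  kern <- if (inherits(features, "similarity_kernel")) features
          else build_kernel(features, scale_mode = scale_mode)
  K <- kern$matrix
  n <- nrow(K)
  stopifnot(length(ages) == n)
  fold_assign <- make_folds(n, folds, seed)
  pred <- cv_on_kernel(K, ages, fold_assign, hyper)
  structure(
    list(
      predictions = tibble::tibble(
        subject_id = kern$subject_ids %||% sprintf("s%03d", seq_len(n)),
        age = as.numeric(ages),
        predicted_age = pred,
        brain_pad = pred - as.numeric(ages),
        fold = fold_assign
      ),
      metrics = age_prediction_metrics(pred, ages),
      folds = length(unique(fold_assign)),
      seed = as.integer(seed)
    ),
    class = "cv_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<cv_result> %d-fold CV, n = %d: r = %.3f, R^2 = %.3f, MAE = %.2f y, RMSE = %.2f y\n",
    x$folds, nrow(x$predictions), m$r, m$r2, m$mae, m$rmse))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) x$predictions

#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble::tibble(folds = x$folds, n = nrow(x$predictions)))
}

#' Permutation test of cross-validated prediction accuracy
#'
#' Significance of the CV correlation between predicted and chronological
#' age: ages are permuted uniformly, the full cross-validation (same
#' kernel — a dot-product kernel does not depend on the ages — and same
#' fold assignment) is repeated per permutation, and the one-sided
#' upper-tail p-value is smoothed as
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams cv_gpr
#' @param n_perm Number of permutations (>= 1; 1000 for publication-grade
#'   runs, smaller for calibration experiments).
#' @return A `perm_test`: `p`, `r_obs`, `r_perm`, `n_perm`.
#' @export
permutation_test_gpr <- function(features, ages, n_perm = 1000, seed = 1L,
                                 folds = 10, hyper = "optimize",
                                 scale_mode = "by_voxel_count") {
  stopifnot(n_perm >= 1)
  kern <- if (inherits(features, "similarity_kernel")) features
          else build_kernel(features, scale_mode = scale_mode)
  K <- kern$matrix
  n <- nrow(K)
  stopifnot(length(ages) == n)
  fold_assign <- make_folds(n, folds, seed)
  r_obs <- safe_cor(cv_on_kernel(K, ages, fold_assign, hyper), ages)
  set.seed(as.integer(seed) + 1L)
  r_perm <- vapply(seq_len(n_perm), function(b) {
    yp <- ages[sample.int(n)]
    safe_cor(cv_on_kernel(K, yp, fold_assign, hyper), yp)
  }, numeric(1))
  structure(
    list(p = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
         r_obs = r_obs, r_perm = r_perm, n_perm = n_perm),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> r_obs = %.3f, p = %.4g (%d permutations)\n",
              x$r_obs, x$p, x$n_perm))
  invisible(x)
}
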