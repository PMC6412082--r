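#' Build the subject-by-subject similarity kernel
#'
#' The Gram matrix of pairwise dot products between subjects' concatenated
#' GM+WM feature vectors: `K[i, j] = x_i . x_j`, optionally scaled. By
#' default dot products are divided by the feature length
#' (`by_voxel_count`), which keeps kernel entries on an O(1) scale and the
#' marginal-likelihood optimization well conditioned; scaling by a positive
#' constant does not change what the model can express.
#'
#' @param features Numeric matrix, one row per subject (rownames used as
#'   subject ids), or a list of equal-length feature vectors from
#'   [vectorize_concat()].
#' @param scale_mode One of `"by_voxel_count"`, `"none"`,
#'   `"trace_normalized"` (divides by `trace(K)/N`).
#' @return A `similarity_kernel`: list with `matrix`, `subject_ids`,
#'   `scale_mode`, `scale` (the divisor applied), `n_features`.
#' @export
build_kernel <- function(features,
                         scale_mode = c("by_voxel_count", "none",
                                        "trace_normalized")) {
  scale_mode <- match.arg(scale_mode)
  X <- as_feature_matrix(features)
  if (nrow(X) < 2L) stop("need at least 2 subjects to build a kernel",
                         call. = FALSE)
  K <- tcrossprod(X)
  scale <- switch(scale_mode,
    none = 1,
    by_voxel_count = ncol(X),
    trace_normalized = sum(diag(K)) / nrow(K)
  )
  if (scale <= 0) scale <- 1  # all-zero features: leave unscaled
  K <- K / scale
  K <- (K + t(K)) / 2  # enforce exact symmetry against fp round-off
  structure(
    list(matrix = K, subject_ids = rownames(X), scale_mode = scale_mode,
         scale = scale, n_features = ncol(X)),
    class = "similarity_kernel"
  )
}

as_feature_matrix <- function(features) {
  if (is.list(features) && !is.data.frame(features)) {
    lens <- lengths(features)
    if (length(unique(lens)) != 1L) {
      stop("feature vectors differ in length: ",
           paste(unique(lens), collapse = ", "), call. = FALSE)
    }
    ids <- attr(features[[1]], "mask_id")
    if (!is.null(ids)) {
      ok <- vapply(features, function(f) identical(attr(f, "mask_id"), ids),
                   logical(1))
      if (!all(ok)) stop("feature vectors built under different masks",
                         call. = FALSE)
    }
    features <- do.call(rbind, features)
  }
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (is.null(rownames(X))) rownames(X) <- sprintf("s%03d", seq_len(nrow(X)))
  X
}

#' @export
print.similarity_kernel <- function(x, ...) {
  cat(sprintf("<similarity_kernel> %d x %d, scale_mode '%s' (p = %d)\n",
              nrow(x$matrix), ncol(x$matrix), x$scale_mode, x$n_features))
  invisible(x)
}

#' Cross-kernel between test and training subjects
#'
#' Entry (i, j) is the dot product of test feature i with training feature
#' j, under the *training* kernel's scale, so a trained model can be
#' applied to new subjects. Test features must come from the same mask
#' (same length) as the training features.
#'
#' @param test_features Matrix or list of feature vectors for test subjects.
#' @param train_features Matrix or list for the training subjects.
#' @param kernel The training `similarity_kernel` (supplies scale);
#'   alternatively pass `scale_mode`/`scale` via this argument being NULL
#'   and defaults applying.
#' @return Matrix `n_test x n_train` with dimnames from subject ids.
#' @export
build_cross_kernel <- function(test_features, train_features, kernel = NULL) {
  Xt <- as_feature_matrix(test_features)
  Xr <- as_feature_matrix(train_features)
  if (ncol(Xt) != ncol(Xr)) {
    stop("test features have length ", ncol(Xt),
         " but training features have length ", ncol(Xr),
         " (mask mismatch)", call. = FALSE)
  }
  scale <- if (is.null(kernel)) ncol(Xr) else kernel$scale
  Kc <- tcrossprod(Xt, Xr) / scale
  dimnames(Kc) <- list(rownames(Xt), rownames(Xr))
  Kc
}

#' Check kernel symmetry and positive semidefiniteness
#'
#' @param kernel A `similarity_kernel` or plain matrix.
#' @param tol_sym Max allowed relative asymmetry.
#' @param tol_psd Min eigenvalue bound as a multiple of `-trace/N`.
#' @return TRUE invisibly; errors otherwise.
#' @export
check_kernel <- function(kernel, tol_sym = 1e-10, tol_psd = 1e-8) {
  K <- if (inherits(kernel, "similarity_kernel")) kernel$matrix else kernel
  sc <- max(abs(K), 1e-300)
  if (max(abs(K - t(K))) / sc > tol_sym) {
    stop("kernel is not symmetric within tolerance", call. = FALSE)
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol_psd * sum(diag(K)) / nrow(K) - 1e-300) {
    stop("kernel is not positive semidefinite within tolerance: min eig ",
         signif(min(ev), 4), call. = FALSE)
  }
  invisible(TRUE)
}
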