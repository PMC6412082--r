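#' Construct a 3D volume
#'
#' A `volume3d` is a 3D scalar array (e.g. a tissue-probability map) together
#' with its voxel edge lengths in millimetres and a label for the common
#' space all cohort volumes are assumed to share. All volumes entering one
#' similarity kernel must agree in grid shape and space label.
#'
#' @param data Numeric 3D array.
#' @param voxel_mm Numeric length-3 vector of voxel edge lengths (mm), or a
#'   single number recycled to all three axes.
#' @param space_label Character identifier of the common space.
#' @return A `volume3d` object.
#' @export
volume3d <- function(data, voxel_mm = c(1, 1, 1), space_label = "synthetic") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array, got ", paste(dim(data), collapse = "x"),
         call. = FALSE)
  }
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0)) {
    stop("`voxel_mm` must be three positive finite numbers", call. = FALSE)
  }
  structure(
    list(data = data, voxel_mm = voxel_mm, space_label = as.character(space_label)),
    class = "volume3d"
  )
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf(
    "<volume3d> %s voxels @ %s mm, space '%s', range [%.4g, %.4g]\n",
    paste(dim(x$data), collapse = "x"),
    paste(format(x$voxel_mm, trim = TRUE), collapse = "x"),
    x$space_label, min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Volume of one voxel in mm^3
#' @param vol A `volume3d`.
#' @return Voxel volume in cubic millimetres.
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$voxel_mm)

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data))) {
    stop("grid shape mismatch between ", what, ": ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), call. = FALSE)
  }
  if (!identical(a$space_label, b$space_label)) {
    stop("space_label mismatch between ", what, ": '",
         a$space_label, "' vs '", b$space_label, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D NIfTI-1 file (`.nii` / `.nii.gz`) into a [volume3d()], taking
#' voxel dimensions from the header `pixdim`.
#'
#' @param path Path to a NIfTI-1 file.
#' @param space_label Space label to attach (the header carries no cohort
#'   space identifier).
#' @return A `volume3d`.
#' @export
read_volume <- function(path, space_label = "synthetic") {
  if (!file.exists(path)) stop("no such volume file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    stop("expected a 3D volume in '", path, "', got ",
         length(d), "D", call. = FALSE)
  }
  vox <- RNifti::pixdim(img)[1:3]
  volume3d(array(as.numeric(img), dim = d), voxel_mm = vox,
           space_label = space_label)
}

#' Write a volume as NIfTI-1
#'
#' Writes single-precision (float32) data with voxel dimensions in the
#' header; a write-then-read round trip preserves values to float32
#' precision and `voxel_mm` exactly.
#'
#' @param vol A `volume3d`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_mm
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Convert a Gaussian FWHM to its standard deviation
#'
#' sigma = FWHM / (2 * sqrt(2 * ln 2)) = FWHM / 2.35482.
#'
#' @param fwhm Full width at half maximum (any length unit).
#' @return Standard deviation in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 1D convolution along one axis of a 3D array with nearest-edge replication:
# out = sum_j w[j] * shift(x, offsets[j]) where out-of-range indices clamp
# to the boundary slice.
convolve_axis <- function(x, w, axis) {
  r <- (length(w) - 1L) %/% 2L
  n <- dim(x)[axis]
  out <- array(0, dim = dim(x))
  idx_all <- list(seq_len(dim(x)[1]), seq_len(dim(x)[2]), seq_len(dim(x)[3]))
  for (j in seq_along(w)) {
    off <- j - r - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n)
    idx <- idx_all
    idx[[axis]] <- src
    out <- out + w[j] * do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  }
  out
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian smoothing with per-axis sigma
#' `fwhm_mm / (2 sqrt(2 ln 2)) / voxel_mm`. Boundaries are handled by
#' nearest-edge replication; `fwhm_mm = 0` is the identity. The discrete
#' kernel is truncated at 3 sigma and renormalised to sum to one, so a
#' constant volume is left unchanged and the volume integral is conserved
#' wherever the support stays away from the grid boundary.
#'
#' @param vol A `volume3d`.
#' @param fwhm_mm Full width at half maximum of the kernel, in mm (>= 0).
#' @return Smoothed `volume3d`.
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "volume3d"))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) {
    stop("`fwhm_mm` must be a nonnegative number", call. = FALSE)
  }
  if (fwhm_mm == 0) return(vol)
  x <- vol$data
  for (axis in 1:3) {
    sigma <- fwhm_to_sigma(fwhm_mm) / vol$voxel_mm[axis]
    r <- max(1L, as.integer(ceiling(3 * sigma)))
    w <- stats::dnorm(seq(-r, r), sd = sigma)
    w <- w / sum(w)
    x <- convolve_axis(x, w, axis)
  }
  volume3d(x, voxel_mm = vol$voxel_mm, space_label = vol$space_label)
}

#' Vectorize and concatenate GM and WM maps under a mask
#'
#' Extracts the masked grey-matter voxels followed by the masked
#' white-matter voxels as one feature vector — one row of the model's data
#' matrix. Voxel ordering is fixed as column-major (R array order) over the
#' mask indices, so the ordering is deterministic across runs; any fixed
#' order gives the same dot-product kernel.
#'
#' @param gm,wm `volume3d` tissue maps on the same grid.
#' @param mask A `volume3d` with 0/1 values (or a logical/numeric 3D array).
#' @return Numeric vector of length `2 * sum(mask)`, with attributes
#'   `mask_id` (a digest of the mask) and `n_mask` (mask voxel count).
#' @export
vectorize_concat <- function(gm, wm, mask) {
  stopifnot(inherits(gm, "volume3d"), inherits(wm, "volume3d"))
  check_same_grid(gm, wm, "gm and wm")
  m <- if (inherits(mask, "volume3d")) mask$data else mask
  if (!identical(dim(m), dim(gm$data))) {
    stop("mask grid ", paste(dim(m), collapse = "x"),
         " does not match volume grid ", paste(dim(gm$data), collapse = "x"),
         call. = FALSE)
  }
  mv <- as.logical(m != 0)
  if (!all(m %in% c(0, 1) | is.logical(m))) {
    stop("mask must be binary (0/1)", call. = FALSE)
  }
  if (!any(mv)) {
    warning("mask is empty; returning a length-0 feature vector", call. = FALSE)
  }
  v <- c(gm$data[mv], wm$data[mv])
  attr(v, "mask_id") <- mask_id(mv)
  attr(v, "n_mask") <- sum(mv)
  v
}

#' @keywords internal
mask_id <- function(mask_logical) {
  rlang::hash(list(dim(mask_logical), which(mask_logical)))
}

#' Cohort mask from mean tissue maps
#'
#' Default analysis mask: voxels whose cohort-mean GM + WM probability
#' exceeds a threshold (0.05 by default).
#'
#' @param gm_list,wm_list Lists of `volume3d` maps, one per subject.
#' @param threshold Mean GM+WM cutoff.
#' @return A binary `volume3d` mask.
#' @export
cohort_mask <- function(gm_list, wm_list, threshold = 0.05) {
  stopifnot(length(gm_list) == length(wm_list), length(gm_list) >= 1L)
  ref <- gm_list[[1]]
  acc <- array(0, dim = dim(ref$data))
  for (i in seq_along(gm_list)) {
    check_same_grid(gm_list[[i]], ref, "cohort volumes")
    check_same_grid(wm_list[[i]], ref, "cohort volumes")
    acc <- acc + gm_list[[i]]$data + wm_list[[i]]$data
  }
  m <- (acc / length(gm_list)) > threshold
  volume3d(array(as.numeric(m), dim = dim(m)), voxel_mm = ref$voxel_mm,
           space_label = ref$space_label)
}

#' Tissue volume in millilitres
#'
#' Integrates a tissue-probability map: sum of voxel values times voxel
#' volume (mm^3), divided by 1000 to give ml.
#'
#' @param vol A `volume3d` with values in `[0, 1]` (a small tolerance is
#'   allowed for post-smoothing overshoot).
#' @param tol Tolerance outside `[0, 1]` before a validation error.
#' @return Volume in millilitres.
#' @export
tissue_volume <- function(vol, tol = 1e-6) {
  stopifnot(inherits(vol, "volume3d"))
  rng <- range(vol$data)
  if (rng[1] < -tol || rng[2] > 1 + tol) {
    stop("tissue-probability values outside [0, 1]: range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]", call. = FALSE)
  }
  sum(vol$data) * voxel_volume_mm3(vol) / 1000
}

#' Intracranial volume in millilitres
#'
#' ICV = GM volume + WM volume + CSF volume.
#'
#' @param gm,wm,csf Tissue-probability `volume3d` maps.
#' @return ICV in millilitres.
#' @export
icv_ml <- function(gm, wm, csf) {
  tissue_volume(gm) + tissue_volume(wm) + tissue_volume(csf)
}
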