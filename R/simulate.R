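#' Specify a synthetic two-group cohort
#'
#' Describes the study design of a patient/control cohort: group sizes, a
#' uniform chronological-age range, per-group male fractions, BMI and IQ
#' distributions (normals truncated to a stated range, since only
#' mean/SD/range are typically printed), and a group-level brain-aging
#' offset `delta_years` applied to the patient group's *effective* age —
#' the age their tissue maps express — while the recorded chronological age
#' is left untouched. That offset is exactly what brain-PAD is supposed to
#' detect.
#'
#' Defaults emulate a published case-control design: n = 20 patients
#' (Prader-Willi syndrome) vs n = 40 controls, ages 19-29, 70%/65% male,
#' BMI 30.1 +/- 7.2 (range 21.5-47.7) vs 24.1 +/- 3.8 (19.2-34.2),
#' IQ 63.1 +/- 11.9 (48-95) vs 112.9 +/- 11.2 (81-132).
#'
#' @param n_patient,n_control Group sizes (>= 2 for any group entering a
#'   two-sample test).
#' @param age_range Length-2 numeric, min < max, years.
#' @param male_fraction Named numeric `c(patient = , control = )` in `[0, 1]`.
#' @param delta_years Group aging offset (years) added to patients'
#'   effective age; finite.
#' @param bmi_params,iq_params Named lists with `patient` / `control`
#'   entries, each `c(mean, sd, min, max)` (truncation range optional).
#' @param labels Named character `c(patient = , control = )` group labels.
#' @param seed Master integer seed; all per-subject randomness derives from
#'   it (see [subject_seed()]).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patient = 20, n_control = 40,
                        age_range = c(19, 29),
                        male_fraction = c(patient = 0.70, control = 0.65),
                        delta_years = 0,
                        bmi_params = list(patient = c(30.1, 7.2, 21.5, 47.7),
                                          control = c(24.1, 3.8, 19.2, 34.2)),
                        iq_params = list(patient = c(63.1, 11.9, 48, 95),
                                         control = c(112.9, 11.2, 81, 132)),
                        labels = c(patient = "PWS", control = "Control"),
                        seed = 1L) {
  if (length(age_range) != 2L || !all(is.finite(age_range)) ||
      age_range[1] >= age_range[2]) {
    stop("`age_range` must be c(min, max) with min < max", call. = FALSE)
  }
  if (!is.finite(delta_years)) stop("`delta_years` must be finite", call. = FALSE)
  if (n_patient < 2 || n_control < 2) {
    stop("need n >= 2 per group for two-sample tests", call. = FALSE)
  }
  mf <- male_fraction[c("patient", "control")]
  if (any(is.na(mf)) || any(mf < 0) || any(mf > 1)) {
    stop("`male_fraction` must name patient and control values in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(n_patient = as.integer(n_patient), n_control = as.integer(n_control),
         age_range = as.numeric(age_range), male_fraction = mf,
         delta_years = as.numeric(delta_years),
         bmi_params = bmi_params, iq_params = iq_params,
         labels = labels, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Per-subject sub-seed from the master seed
#'
#' Deterministic counter scheme: subject `j` (1-based) of group
#' `group_code` (1 = patient, 2 = control) gets
#' `(master * 1000003 + group_code * 65537 + j) mod (2^31 - 1)`.
#' Growing a group appends subjects without reshuffling existing ones.
#'
#' @param master Master integer seed.
#' @param group_code 1 for patient, 2 for control.
#' @param j Within-group subject index, 1-based.
#' @return Integer seed below 2^31.
#' @export
subject_seed <- function(master, group_code, j) {
  as.integer((as.numeric(master) * 1000003 + group_code * 65537 + j) %% 2147483647)
}

rtruncnorm1 <- function(mean, sd, lo = -Inf, hi = Inf) {
  # inverse-CDF draw from a truncated normal; one value
  u <- stats::runif(1, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

draw_subject <- function(sseed, group, label, age_range, male_frac,
                         bmi_par, iq_par, delta) {
  set.seed(sseed)
  age <- stats::runif(1, age_range[1], age_range[2])
  sex <- if (stats::runif(1) < male_frac) "M" else "F"
  bmi <- rtruncnorm1(bmi_par[1], bmi_par[2],
                     if (length(bmi_par) >= 3) bmi_par[3] else -Inf,
                     if (length(bmi_par) >= 4) bmi_par[4] else Inf)
  iq <- rtruncnorm1(iq_par[1], iq_par[2],
                    if (length(iq_par) >= 3) iq_par[3] else -Inf,
                    if (length(iq_par) >= 4) iq_par[4] else Inf)
  eff_age <- age + if (identical(group, "patient")) delta else 0
  tibble::tibble(
    group = label, age = age, sex = sex, bmi = bmi, iq = iq,
    effective_age = eff_age,
    subject_seed = sseed
  )
}

#' Generate a synthetic cohort table
#'
#' Draws demographics per subject from the cohort specification: ages uniform in
#' `age_range`, sex by `male_fraction`, BMI/IQ from per-group truncated
#' normals, and `effective_age = age + delta_years` for patients (exactly
#' `age` for controls or when `delta_years = 0`). Each subject is drawn
#' from their own [subject_seed()], so the table is byte-identical across
#' runs and extensible in n without reshuffling.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `group`, `age`, `sex`,
#'   `bmi`, `iq`, `effective_age`, `subject_seed`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- list()
  for (g in c("patient", "control")) {
    code <- if (g == "patient") 1L else 2L
    n <- if (g == "patient") spec$n_patient else spec$n_control
    label <- spec$labels[[g]]
    for (j in seq_len(n)) {
      sseed <- subject_seed(spec$seed, code, j)
      row <- draw_subject(sseed, g, label, spec$age_range,
                          spec$male_fraction[[g]],
                          spec$bmi_params[[g]], spec$iq_params[[g]],
                          spec$delta_years)
      row$subject_id <- sprintf("%s_%03d", tolower(label), j)
      rows[[length(rows) + 1L]] <- row
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::select("subject_id", "group", "age", "sex", "bmi", "iq",
                  "effective_age", "subject_seed")
}

#' Define the linear-atrophy generative model for tissue maps
#'
#' Synthetic stand-in for spatially normalized, smoothed GM/WM/CSF
#' tissue-probability maps. The grid is treated as the intracranial
#' bounding region: baseline GM forms an outer shell and WM an inner core
#' of an ellipsoid, CSF fills the remainder, and each tissue shrinks
#' linearly with effective age at a spatially varying rate proportional to
#' its baseline (emulating widespread age-related volume loss). On top of
#' the deterministic trend each subject gets (a) a Gaussian brain-age
#' deviate (`subject_sd_years`) shifting the age their maps express, and
#' (b) i.i.d. per-voxel Gaussian noise (`noise_sd`).
#'
#' @param grid_shape Voxel counts per axis (default 24 x 28 x 24, desk
#'   scale, not MNI resolution).
#' @param voxel_mm Voxel edge lengths in mm (default 4 mm isotropic).
#' @param atrophy_rate_gm,atrophy_rate_wm Fractional tissue loss per year
#'   of effective age (slope fields = rate x baseline, so slopes are >= 0
#'   and probabilities stay nonnegative up to `age_max`).
#' @param noise_sd Per-voxel i.i.d. noise SD (probability units).
#' @param subject_sd_years SD of the per-subject brain-age deviate (years).
#' @param smoothing_fwhm_mm Post-generation Gaussian smoothing FWHM (mm).
#' @param age_max Oldest effective age the model is valid for.
#' @param gm_baseline,wm_baseline,gm_slope,wm_slope Optional explicit 3D
#'   arrays overriding the built-in ellipsoid phantom (all on
#'   `grid_shape`).
#' @return An `atrophy_model` object.
#' @export
atrophy_model <- function(grid_shape = c(24, 28, 24), voxel_mm = c(4, 4, 4),
                          atrophy_rate_gm = 0.004, atrophy_rate_wm = 0.0015,
                          noise_sd = 0.02, subject_sd_years = 5,
                          smoothing_fwhm_mm = 4, age_max = 90,
                          gm_baseline = NULL, wm_baseline = NULL,
                          gm_slope = NULL, wm_slope = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            noise_sd >= 0, subject_sd_years >= 0, smoothing_fwhm_mm >= 0)
  voxel_mm <- if (length(voxel_mm) == 1L) rep(voxel_mm, 3L) else as.numeric(voxel_mm)

  if (is.null(gm_baseline) || is.null(wm_baseline)) {
    # ellipsoid phantom in normalized coords u in [-1, 1]^3
    ax <- lapply(grid_shape, function(n) {
      if (n == 1L) 0 else seq(-1, 1, length.out = n)
    })
    u1 <- array(rep(ax[[1]], times = grid_shape[2] * grid_shape[3]), grid_shape)
    u2 <- array(rep(rep(ax[[2]], each = grid_shape[1]), times = grid_shape[3]),
                grid_shape)
    u3 <- array(rep(ax[[3]], each = grid_shape[1] * grid_shape[2]), grid_shape)
    r2 <- (u1 / 0.92)^2 + (u2 / 0.92)^2 + (u3 / 0.92)^2
    inside <- r2 <= 1
    gm_b <- 1.4 * (pmax(r2, 0) * pmax(1 - r2, 0))^0.7 * inside
    wm_b <- 0.85 * pmax(1 - r2, 0)^1.5 * inside
    # keep gm + wm strictly below 1 so csf >= 0 before noise
    tot <- gm_b + wm_b
    scl <- ifelse(tot > 0.995, 0.995 / tot, 1)
    if (is.null(gm_baseline)) gm_baseline <- gm_b * scl
    if (is.null(wm_baseline)) wm_baseline <- wm_b * scl
  }
  if (is.null(gm_slope)) gm_slope <- atrophy_rate_gm * gm_baseline
  if (is.null(wm_slope)) wm_slope <- atrophy_rate_wm * wm_baseline

  for (f in list(gm_baseline, wm_baseline, gm_slope, wm_slope)) {
    if (!identical(dim(f), grid_shape)) {
      stop("all model fields must have dim grid_shape", call. = FALSE)
    }
  }
  if (any(gm_slope < 0) || any(wm_slope < 0)) {
    stop("slope fields must be >= 0", call. = FALSE)
  }
  if (any(gm_baseline - gm_slope * age_max < -1e-12) ||
      any(wm_baseline - wm_slope * age_max < -1e-12)) {
    stop("baseline - slope * age_max must stay >= 0 ",
         "(tissue probabilities would go negative before noise)",
         call. = FALSE)
  }
  structure(
    list(grid_shape = grid_shape, voxel_mm = voxel_mm,
         gm_baseline = gm_baseline, gm_slope = gm_slope,
         wm_baseline = wm_baseline, wm_slope = wm_slope,
         noise_sd = noise_sd, subject_sd_years = subject_sd_years,
         smoothing_fwhm_mm = smoothing_fwhm_mm, age_max = age_max),
    class = "atrophy_model"
  )
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate GM/WM/CSF tissue maps for one subject
#'
#' gm = clip(gm_baseline - gm_slope * (effective_age + eta) + noise, 0, 1),
#' wm analogous with the same per-subject deviate eta ~ N(0,
#' subject_sd_years), csf = clip(1 - gm - wm, 0, 1); optional Gaussian
#' smoothing is applied to all three maps. Deterministic given the seed.
#'
#' @param subject One-row data frame (or list) with at least
#'   `effective_age`; if `seed` is missing its `subject_seed` is used.
#' @param model An [atrophy_model()].
#' @param seed Integer seed for this subject's noise draws. Internally a
#'   fixed Lehmer scramble (`seed * 48271 mod 2^31 - 1`) is applied before
#'   seeding, so the map-noise stream never shares draw positions with the
#'   demographics stream that was seeded from the same subject seed (the
#'   first draws of a reseeded stream would otherwise coincide and couple
#'   the subject's noise to their age).
#' @param smooth Apply the model's smoothing FWHM (default TRUE).
#' @return Named list of `volume3d`: `gm`, `wm`, `csf`.
#' @export
simulate_tissue_maps <- function(subject, model, seed = NULL, smooth = TRUE) {
  stopifnot(inherits(model, "atrophy_model"))
  eff <- as.numeric(subject$effective_age)
  if (is.null(seed)) seed <- subject$subject_seed
  stopifnot(length(eff) == 1L, is.finite(eff), !is.null(seed))
  if (eff < 0 || eff > model$age_max) {
    warning("effective age ", signif(eff, 4), " outside model validity [0, ",
            model$age_max, "]; tissue values clipped", call. = FALSE)
  }
  set.seed(as.integer((as.numeric(seed) * 48271) %% 2147483647))
  eta <- if (model$subject_sd_years > 0) {
    stats::rnorm(1, 0, model$subject_sd_years)
  } else 0
  nvox <- prod(model$grid_shape)
  noise_gm <- if (model$noise_sd > 0) {
    array(stats::rnorm(nvox, 0, model$noise_sd), model$grid_shape)
  } else 0
  noise_wm <- if (model$noise_sd > 0) {
    array(stats::rnorm(nvox, 0, model$noise_sd), model$grid_shape)
  } else 0
  a <- eff + eta
  gm <- clip01(model$gm_baseline - model$gm_slope * a + noise_gm)
  wm <- clip01(model$wm_baseline - model$wm_slope * a + noise_wm)
  csf <- clip01(1 - gm - wm)
  out <- list(
    gm = volume3d(gm, model$voxel_mm, "synthetic"),
    wm = volume3d(wm, model$voxel_mm, "synthetic"),
    csf = volume3d(csf, model$voxel_mm, "synthetic")
  )
  if (smooth && model$smoothing_fwhm_mm > 0) {
    out <- lapply(out, gaussian_smooth, fwhm_mm = model$smoothing_fwhm_mm)
  }
  out
}

#' Simulate maps for a whole cohort and build its feature matrix
#'
#' Generates tissue maps per subject, derives (or applies) the analysis
#' mask, vectorizes GM+WM under it, and computes per-subject tissue
#' volumes. This is the in-memory fast path the pipeline uses; use
#' [write_cohort_maps()] when files are wanted.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param model An [atrophy_model()].
#' @param mask Optional binary `volume3d`; default derives the cohort mask
#'   (mean GM+WM > `mask_threshold`) from these subjects.
#' @param mask_threshold Passed to [cohort_mask()] when `mask` is NULL.
#' @return List: `features` (matrix, one row per subject, rownames =
#'   subject ids), `mask` (`volume3d`), `mask_id`, and `volumes` (tibble of
#'   gm/wm/csf/icv in ml per subject).
#' @export
simulate_cohort_features <- function(cohort, model, mask = NULL,
                                     mask_threshold = 0.05) {
  maps <- lapply(seq_len(nrow(cohort)), function(i) {
    simulate_tissue_maps(cohort[i, ], model)
  })
  gm_list <- lapply(maps, `[[`, "gm")
  wm_list <- lapply(maps, `[[`, "wm")
  if (is.null(mask)) {
    mask <- cohort_mask(gm_list, wm_list, threshold = mask_threshold)
  }
  feats <- t(vapply(seq_along(maps),
                    function(i) vectorize_concat(gm_list[[i]], wm_list[[i]], mask),
                    numeric(2 * sum(mask$data != 0))))
  rownames(feats) <- cohort$subject_id
  vols <- purrr::map2_dfr(maps, cohort$subject_id, function(m, id) {
    tibble::tibble(
      subject_id = id,
      gm_ml = tissue_volume(m$gm, tol = 1e-6),
      wm_ml = tissue_volume(m$wm, tol = 1e-6),
      csf_ml = tissue_volume(m$csf, tol = 1e-6)
    )
  }) |>
    dplyr::mutate(icv_ml = .data$gm_ml + .data$wm_ml + .data$csf_ml)
  list(features = feats, mask = mask,
       mask_id = mask_id(mask$data != 0), volumes = vols)
}

#' Write a cohort's tissue maps and table to disk
#'
#' Maps are written as NIfTI-1 files `<subject_id>_{gm,wm,csf}.nii.gz` with
#' voxel dimensions in the header; the cohort table as CSV with header
#' `subject_id, group, age, sex, bmi, iq` (plus `effective_age` in oracle
#' mode, which reveals the simulated ground truth).
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param model An [atrophy_model()].
#' @param dir Output directory (created if needed).
#' @param oracle Include the `effective_age` column (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_cohort_maps <- function(cohort, model, dir, oracle = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    m <- simulate_tissue_maps(cohort[i, ], model)
    for (tt in names(m)) {
      write_volume(m[[tt]], file.path(dir, paste0(cohort$subject_id[i], "_",
                                                  tt, ".nii.gz")))
    }
  }
  tab <- cohort[, c("subject_id", "group", "age", "sex", "bmi", "iq",
                    if (oracle) "effective_age")]
  utils::write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort spec or atrophy model from a YAML/JSON config
#'
#' Flat keys matching the constructor arguments; nested `patient` /
#' `control` entries for `bmi_params` / `iq_params`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg), names(formals(cohort_spec)))]
  if (!is.null(args$male_fraction)) args$male_fraction <- unlist(args$male_fraction)
  if (!is.null(args$labels)) args$labels <- unlist(args$labels)
  for (p in c("bmi_params", "iq_params")) {
    if (!is.null(args[[p]])) args[[p]] <- lapply(args[[p]], unlist)
  }
  do.call(cohort_spec, args)
}
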