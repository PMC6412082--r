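# small builders shared across the suite; everything generated in code

tiny_model <- function(grid = c(6, 7, 6), voxel = 8, noise_sd = 0,
                       subject_sd = 0, smooth = 0, ...) {
  atrophy_model(grid_shape = grid, voxel_mm = voxel, noise_sd = noise_sd,
                subject_sd_years = subject_sd, smoothing_fwhm_mm = smooth, ...)
}

# one-voxel phantom for hand-computable arithmetic (valid to age 80)
single_voxel_model <- function(baseline = 0.8, slope = 0.01) {
  atrophy_model(grid_shape = c(1, 1, 1), voxel_mm = 1,
                gm_baseline = array(baseline, c(1, 1, 1)),
                wm_baseline = array(0.1, c(1, 1, 1)),
                gm_slope = array(slope, c(1, 1, 1)),
                wm_slope = array(0, c(1, 1, 1)),
                noise_sd = 0, subject_sd_years = 0, smoothing_fwhm_mm = 0,
                age_max = 80)
}

rand_volume <- function(dim = c(8, 8, 8), voxel = 1, seed = 1) {
  set.seed(seed)
  volume3d(array(stats::runif(prod(dim)), dim), voxel_mm = voxel)
}

# rescale a sample to exact target moments
match_moments <- function(x, m, s) (x - mean(x)) / stats::sd(x) * s + m

# a fast pipeline configuration for determinism / structure tests
small_run_config <- function(seed = 1, delta = 7, analyses = character(),
                             single_subject = NULL) {
  run_config(
    seed = seed,
    train = list(n = 40, age_range = c(18, 90)),
    test = list(n_patient = 6, n_control = 8, age_range = c(19, 29),
                delta_years = delta),
    model = list(grid_shape = c(8, 8, 8), voxel_mm = c(8, 8, 8)),
    gpr = list(folds = 10, n_perm = 0, hyper = "optimize",
               scale_mode = "by_voxel_count"),
    analyses = analyses,
    single_subject = single_subject
  )
}
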