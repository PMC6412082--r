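#' Configure a full brain-age pipeline run
#'
#' Collects every knob of the simulate -> volumes -> kernel -> train ->
#' predict -> stats chain in one validated list. All randomness in the run
#' derives from the single master `seed`. Defaults give the demo design: a
#' synthetic normative training set (n = 300, ages 18-90, no group
#' offset), a case-control test cohort (n = 20 patients with a
#' `delta_years = 7` aging offset vs n = 40 controls, ages 19-29), a
#' reduced 12 x 14 x 12 grid at 8 mm, and the group/covariate statistics.
#'
#' @param seed Master integer seed.
#' @param train List: `n`, `age_range` for the normative training cohort.
#' @param test Arguments for [cohort_spec()] (the master seed is injected).
#' @param model Arguments for [atrophy_model()].
#' @param gpr List: `folds`, `n_perm` (0 skips the permutation test),
#'   `hyper`, `scale_mode`.
#' @param analyses Covariate analyses to run: subset of
#'   `c("bmi", "iq", "gm", "wm", "icv")` plus `"interaction"` (group x GM
#'   and group x BMI slopes) and `"bmi_match"` (BMI-matched subcohort).
#' @param single_subject NULL, or a list `(age, delta_years, bmi)` for a
#'   single-subject-vs-norms comparison.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       train = list(n = 300, age_range = c(18, 90)),
                       test = list(n_patient = 20, n_control = 40,
                                   age_range = c(19, 29), delta_years = 7),
                       model = list(grid_shape = c(12, 14, 12),
                                    voxel_mm = c(8, 8, 8)),
                       gpr = list(folds = 10, n_perm = 0,
                                  hyper = "optimize",
                                  scale_mode = "by_voxel_count"),
                       analyses = c("bmi", "iq", "gm", "interaction",
                                    "bmi_match"),
                       single_subject = list(age = 24.5, delta_years = 10,
                                             bmi = 36.9)) {
  cfg <- list(seed = as.integer(seed), train = train, test = test,
              model = model, gpr = gpr, analyses = analyses,
              single_subject = single_subject)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  if (is.null(cfg$train$n) || cfg$train$n < 10) {
    stop("training cohort needs n >= 10 for 10-fold CV", call. = FALSE)
  }
  if (length(cfg$train$age_range) != 2L ||
      cfg$train$age_range[1] >= cfg$train$age_range[2]) {
    stop("train$age_range must be c(min, max)", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline config from YAML or JSON
#'
#' Flat structure mirroring [run_config()] arguments.
#'
#' @param path Config file path.
#' @param seed Optional override of the file's master seed.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg), names(formals(run_config)))]
  for (nm in c("train", "test", "model", "gpr")) {
    if (!is.null(args[[nm]])) {
      args[[nm]] <- utils::modifyList(formals(run_config)[[nm]] |>
                                        eval(), args[[nm]])
    }
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(run_config, args)
}

#' Normative training cohort (no group offset)
#'
#' Uniform ages over `age_range`; effective age equals chronological age.
#' Subject seeds use counter code 3, so training subjects never collide
#' with the test cohort's draws under the same master seed.
#'
#' @param n Cohort size.
#' @param age_range Years, c(min, max).
#' @param seed Master seed.
#' @return Cohort tibble compatible with [simulate_cohort_features()].
#' @export
training_cohort <- function(n, age_range, seed) {
  rows <- lapply(seq_len(n), function(j) {
    sseed <- subject_seed(seed, 3L, j)
    set.seed(sseed)
    age <- stats::runif(1, age_range[1], age_range[2])
    tibble::tibble(
      subject_id = sprintf("train_%04d", j), group = "Train",
      age = age, sex = NA_character_, bmi = NA_real_, iq = NA_real_,
      effective_age = age, subject_seed = sseed
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the full brain-age pipeline on synthetic data
#'
#' Executes the stages in order under one master seed: (1) simulate the
#' normative training cohort and the case-control test cohort; (2)
#' generate tissue maps, derive the analysis mask from the training
#' cohort, vectorize GM+WM; (3) build the similarity kernel, run k-fold CV
#' on the training set (optionally with a permutation test), and fit the
#' final GPR model on all training subjects; (4) apply the model to the
#' test cohort and score brain-PAD; (5) run the requested group and
#' covariate statistics, and optionally a single-subject-vs-norms
#' comparison. Returns a manifest whose content hashes make end-to-end
#' determinism checkable: the same config yields identical hashes.
#'
#' @param config A [run_config()].
#' @return A `brainpad_run`: config, cohort tables, CV result, fitted
#'   model, predictions (with demographics and tissue volumes joined),
#'   stats tables, optional single-subject comparison and permutation
#'   test, and `manifest` (stage -> content hash).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  # --- simulate ---------------------------------------------------------
  model <- do.call(atrophy_model, config$model)
  train_tab <- training_cohort(config$train$n, config$train$age_range, seed)
  test_spec <- do.call(cohort_spec, c(config$test, list(seed = seed)))
  test_tab <- simulate_cohort(test_spec)

  # --- volumes / features ----------------------------------------------
  train_feat <- simulate_cohort_features(train_tab, model)
  test_feat <- simulate_cohort_features(test_tab, model, mask = train_feat$mask)

  # --- kernel / train ---------------------------------------------------
  kern <- build_kernel(train_feat$features,
                       scale_mode = config$gpr$scale_mode)
  cv <- cv_gpr(kern, train_tab$age, folds = config$gpr$folds,
               seed = seed + 7L, hyper = config$gpr$hyper)
  perm <- NULL
  if (!is.null(config$gpr$n_perm) && config$gpr$n_perm > 0) {
    perm <- permutation_test_gpr(kern, train_tab$age,
                                 n_perm = config$gpr$n_perm,
                                 seed = seed + 7L, folds = config$gpr$folds,
                                 hyper = config$gpr$hyper)
  }
  fit <- gpr_fit(kern, train_tab$age, hyper = config$gpr$hyper)

  # --- predict ----------------------------------------------------------
  Kc <- build_cross_kernel(test_feat$features, train_feat$features, kern)
  preds <- gpr_predict(fit, Kc, ages = test_tab$age,
                       subject_ids = test_tab$subject_id) |>
    dplyr::left_join(test_tab[, c("subject_id", "group", "sex", "bmi", "iq")],
                     by = "subject_id") |>
    dplyr::left_join(test_feat$volumes, by = "subject_id")

  # --- stats ------------------------------------------------------------
  patient_label <- test_spec$labels[["patient"]]
  stats_out <- pipeline_stats(preds, patient_label, config$analyses)

  single <- NULL
  if (!is.null(config$single_subject)) {
    ss <- config$single_subject
    subj <- tibble::tibble(
      subject_id = "single_001", group = patient_label,
      age = ss$age, bmi = ss$bmi %||% NA_real_,
      effective_age = ss$age + ss$delta_years,
      subject_seed = subject_seed(seed, 4L, 1L)
    )
    sfeat <- simulate_cohort_features(subj, model, mask = train_feat$mask)
    sKc <- build_cross_kernel(sfeat$features, train_feat$features, kern)
    spred <- gpr_predict(fit, sKc, ages = subj$age,
                         subject_ids = subj$subject_id)
    norms <- preds$brain_pad[preds$group != patient_label]
    single <- list(
      prediction = spred,
      comparison = single_subject_vs_norm(spred$brain_pad, norms)
    )
  }

  manifest <- list(
    seed = seed,
    config = rlang::hash(unclass(config)),
    train_cohort = rlang::hash(train_tab),
    test_cohort = rlang::hash(test_tab),
    mask = rlang::hash(train_feat$mask$data),
    train_features = rlang::hash(train_feat$features),
    test_features = rlang::hash(test_feat$features),
    cv = rlang::hash(cv$predictions),
    model = rlang::hash(list(fit$signal_scale, fit$noise_var, fit$mu,
                             fit$alpha)),
    predictions = rlang::hash(preds),
    stats = rlang::hash(stats_out),
    single_subject = if (!is.null(single)) rlang::hash(single$comparison)
  )

  structure(
    list(config = config, model_spec = model,
         train_cohort = train_tab, test_cohort = test_tab,
         cv = cv, perm = perm, fit = fit,
         predictions = preds, volumes = test_feat$volumes,
         stats = stats_out, single_subject = single,
         manifest = manifest),
    class = "brainpad_run"
  )
}

pipeline_stats <- function(preds, patient_label, analyses) {
  pat <- preds$brain_pad[preds$group == patient_label]
  ctl <- preds$brain_pad[preds$group != patient_label]
  preds$group_f <- stats::relevel(factor(preds$group),
                                  ref = setdiff(unique(preds$group),
                                                patient_label)[1])
  rows <- list(group = dplyr::mutate(t_test_pooled(pat, ctl),
                                     analysis = "group"))
  cov_map <- c(bmi = "bmi", iq = "iq", gm = "gm_ml", wm = "wm_ml",
               icv = "icv_ml")
  for (a in intersect(names(cov_map), analyses)) {
    rows[[a]] <- dplyr::mutate(
      group_effect_row(preds, "brain_pad", "group_f", cov_map[[a]]),
      analysis = paste0("group_adj_", a))
  }
  comparisons <- dplyr::bind_rows(rows) |>
    dplyr::relocate("analysis")

  interactions <- NULL
  if ("interaction" %in% analyses) {
    interactions <- dplyr::bind_rows(
      dplyr::mutate(interaction_test(preds, "brain_pad", "group_f", "gm_ml"),
                    analysis = "group_x_gm"),
      dplyr::mutate(interaction_test(preds, "brain_pad", "group_f", "bmi"),
                    analysis = "group_x_bmi")
    ) |> dplyr::relocate("analysis")
  }

  bmi_match <- NULL
  if ("bmi_match" %in% analyses) {
    sub <- bmi_match_filter(preds, group = "group", bmi = "bmi",
                            patient_label = patient_label)
    bmi_match <- dplyr::mutate(
      t_test_pooled(sub$brain_pad[sub$group == patient_label],
                    sub$brain_pad[sub$group != patient_label]),
      analysis = "group_bmi_matched",
      n_patient = sum(sub$group == patient_label),
      n_control = sum(sub$group != patient_label)) |>
      dplyr::relocate("analysis")
  }

  list(comparisons = comparisons, interactions = interactions,
       bmi_match = bmi_match)
}

#' @export
print.brainpad_run <- function(x, ...) {
  cat("<brainpad_run> seed", x$manifest$seed, "\n")
  print(x$cv)
  grp <- x$stats$comparisons[x$stats$comparisons$analysis == "group", ]
  cat(sprintf("group brain-PAD effect: %.2f +/- %.2f y [%.2f, %.2f], p = %.3g\n",
              grp$effect, grp$se, grp$ci_lo, grp$ci_hi, grp$p_value))
  invisible(x)
}

#' Render a plain-text report for a pipeline run
#'
#' CV accuracy, per-group brain-PAD distributions, the group-comparison
#' and covariate-adjustment table, interaction tests, the BMI-matched
#' subcohort result, and any single-subject comparison. The body contains
#' no timestamps, so re-rendering the same run is byte-identical.
#'
#' @param run A `brainpad_run`.
#' @return Character vector of report lines (invisibly); also printed.
#' @export
make_report <- function(run) {
  stopifnot(inherits(run, "brainpad_run"))
  m <- run$cv$metrics
  fmt_cmp <- function(d) {
    sprintf("  %-18s effect %6.2f  se %5.2f  CI [%6.2f, %6.2f]  t %6.2f  p %.4g",
            d$analysis, d$effect, d$se, d$ci_lo, d$ci_hi, d$statistic,
            d$p_value)
  }
  by_group <- run$predictions |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$brain_pad),
                     sd = stats::sd(.data$brain_pad), .groups = "drop")
  lines <- c(
    "brainpad pipeline report",
    "========================",
    sprintf("master seed: %d", run$manifest$seed),
    "",
    sprintf("Training CV (%d-fold, n = %d): r = %.3f, R^2 = %.3f, MAE = %.2f y, RMSE = %.2f y",
            run$cv$folds, nrow(run$cv$predictions), m$r, m$r2, m$mae, m$rmse),
    if (!is.null(run$perm)) {
      sprintf("Permutation test: p = %.4g (%d permutations)",
              run$perm$p, run$perm$n_perm)
    },
    "",
    "Brain-PAD by group (years):",
    sprintf("  %-10s n = %3d  mean %6.2f  sd %5.2f",
            by_group$group, by_group$n, by_group$mean, by_group$sd),
    "",
    "Group comparisons:",
    vapply(seq_len(nrow(run$stats$comparisons)), function(i) {
      fmt_cmp(run$stats$comparisons[i, ])
    }, character(1)),
    if (!is.null(run$stats$bmi_match)) c(
      "",
      "BMI-matched subcohort:",
      fmt_cmp(run$stats$bmi_match),
      sprintf("  retained n: %d patients, %d controls",
              run$stats$bmi_match$n_patient, run$stats$bmi_match$n_control)
    ),
    if (!is.null(run$stats$interactions)) c(
      "",
      "Interaction tests (shared slope?):",
      sprintf("  %-12s beta %8.3f  se %7.3f  p %.4g",
              run$stats$interactions$analysis,
              run$stats$interactions$estimate,
              run$stats$interactions$se,
              run$stats$interactions$p_value)
    ),
    if (!is.null(run$single_subject)) c(
      "",
      sprintf("Single subject: predicted %.2f y at age %.2f -> brain-PAD %+.2f y (z = %.2f vs norms, %.0fth percentile)",
              run$single_subject$prediction$predicted_age,
              run$single_subject$prediction$age,
              run$single_subject$prediction$brain_pad,
              run$single_subject$comparison$z,
              run$single_subject$comparison$percentile)
    )
  )
  lines <- unlist(lines[!vapply(lines, is.null, logical(1))])
  cat(lines, sep = "\n")
  cat("\n")
  invisible(lines)
}
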