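test_that("cohort generation is deterministic and respects the design", {
  spec <- cohort_spec(delta_years = 7, seed = 11)
  coh1 <- simulate_cohort(spec)
  coh2 <- simulate_cohort(spec)
  expect_identical(coh1, coh2)
  expect_equal(sum(coh1$group == "PWS"), 20)
  expect_equal(sum(coh1$group == "Control"), 40)

  # growing a group appends without reshuffling existing subjects
  bigger <- simulate_cohort(cohort_spec(n_patient = 30, delta_years = 7,
                                        seed = 11))
  pws_small <- coh1[coh1$group == "PWS", ]
  pws_big <- bigger[bigger$group == "PWS", ][seq_len(20), ]
  expect_identical(pws_small, pws_big)
})

test_that("the aging offset enters effective age only, and exactly", {
  coh0 <- simulate_cohort(cohort_spec(delta_years = 0, seed = 3))
  expect_identical(coh0$effective_age, coh0$age)

  coh <- simulate_cohort(cohort_spec(n_patient = 200, n_control = 2,
                                     delta_years = 7, seed = 3))
  pat <- coh[coh$group == "PWS", ]
  ctl <- coh[coh$group == "Control", ]
  expect_equal(pat$effective_age - pat$age, rep(7, nrow(pat)),
               tolerance = 1e-12)
  expect_identical(ctl$effective_age, ctl$age)
  # group-level mean offset equals delta
  expect_equal(mean(pat$effective_age) - mean(pat$age), 7, tolerance = 1e-12)
})

test_that("demographics respect the stated ranges and age bounds", {
  coh <- simulate_cohort(cohort_spec(n_patient = 150, n_control = 150,
                                     seed = 5))
  expect_true(all(coh$age >= 19 & coh$age <= 29))
  pws <- coh[coh$group == "PWS", ]
  ctl <- coh[coh$group == "Control", ]
  expect_true(all(pws$bmi >= 21.5 & pws$bmi <= 47.7))
  expect_true(all(ctl$bmi >= 19.2 & ctl$bmi <= 34.2))
  expect_true(all(pws$iq >= 48 & pws$iq <= 95))
  expect_true(all(ctl$iq >= 81 & ctl$iq <= 132))
  expect_true(all(coh$sex %in% c("M", "F")))
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(age_range = c(29, 19)), "age_range")
  expect_error(cohort_spec(delta_years = Inf), "finite")
  expect_error(cohort_spec(n_patient = 1), "n >= 2")
  expect_error(cohort_spec(male_fraction = c(patient = 1.2, control = 0.5)),
               "male_fraction")
})

test_that("tissue maps close to 1 and shrink monotonically without noise", {
  m <- tiny_model()
  subj <- function(a) list(effective_age = a, subject_seed = 99)
  maps <- simulate_tissue_maps(subj(30), m)
  total <- maps$gm$data + maps$wm$data + maps$csf$data
  expect_equal(max(abs(total - 1)), 0, tolerance = 1e-12)

  tgm <- vapply(seq(20, 80, by = 10),
                function(a) tissue_volume(simulate_tissue_maps(subj(a), m)$gm),
                numeric(1))
  expect_true(all(diff(tgm) <= 0))
})

test_that("single-voxel map arithmetic matches the closed form", {
  m <- single_voxel_model(baseline = 0.8, slope = 0.01)
  mp <- simulate_tissue_maps(list(effective_age = 20, subject_seed = 1), m)
  expect_equal(as.numeric(mp$gm$data), 0.8 - 0.01 * 20, tolerance = 1e-12)

  # no slope, no noise: identical maps at any two ages
  m0 <- single_voxel_model(baseline = 0.8, slope = 0)
  a <- simulate_tissue_maps(list(effective_age = 20, subject_seed = 1), m0)
  b <- simulate_tissue_maps(list(effective_age = 70, subject_seed = 1), m0)
  expect_identical(a$gm$data, b$gm$data)
})

test_that("a delta offset shifts total GM by the closed-form amount", {
  m <- tiny_model()
  ctrl <- list(effective_age = 25, subject_seed = 4)
  pat <- list(effective_age = 35, subject_seed = 4)  # delta = 10
  gm_ctrl <- tissue_volume(simulate_tissue_maps(ctrl, m)$gm)
  gm_pat <- tissue_volume(simulate_tissue_maps(pat, m)$gm)
  expected_drop <- 10 * sum(m$gm_slope) * prod(m$voxel_mm) / 1000
  expect_equal(gm_ctrl - gm_pat, expected_drop, tolerance = 1e-9)
})

test_that("map generation is seeded-reproducible and warns out of range", {
  m <- tiny_model(noise_sd = 0.02, subject_sd = 5)
  s <- list(effective_age = 25, subject_seed = 7)
  a <- simulate_tissue_maps(s, m)
  b <- simulate_tissue_maps(s, m)
  expect_identical(a$gm$data, b$gm$data)
  c <- simulate_tissue_maps(list(effective_age = 25, subject_seed = 8), m)
  expect_false(identical(a$gm$data, c$gm$data))
  expect_warning(
    simulate_tissue_maps(list(effective_age = 200, subject_seed = 7), m),
    "validity"
  )
})

test_that("subject noise streams are decoupled from demographic draws", {
  # the per-subject brain-age deviate must not echo the age drawn from the
  # same subject seed, or maps would leak chronological age
  coh <- simulate_cohort(cohort_spec(n_patient = 150, n_control = 2,
                                     age_range = c(18, 60), seed = 2))
  pat <- coh[coh$group == "PWS", ]
  m <- tiny_model(subject_sd = 5)
  tgm <- vapply(seq_len(nrow(pat)), function(i) {
    tissue_volume(simulate_tissue_maps(pat[i, ], m)$gm)
  }, numeric(1))
  # residual (the deviate) after removing the age trend: uncorrelated with age
  eta_proxy <- stats::residuals(stats::lm(tgm ~ pat$age))
  expect_lt(abs(stats::cor(eta_proxy, pat$age)), 0.2)
  expect_gt(stats::sd(eta_proxy), 0)
})

test_that("cohort specs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(
    n_patient = 5, n_control = 6, age_range = c(20, 30), delta_years = 3,
    seed = 9
  )), path)
  spec <- read_cohort_spec(path)
  expect_s3_class(spec, "cohort_spec")
  coh <- simulate_cohort(spec)
  expect_equal(nrow(coh), 11)
  expect_equal(unique(coh$effective_age - coh$age),
               c(3, 0), tolerance = 1e-12)
})
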