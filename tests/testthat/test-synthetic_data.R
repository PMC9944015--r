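test_that("cohort generation is deterministic given (seed, spec)", {
  spec <- default_tcm_spec(n = 150)
  expect_identical(synthesize_cohort(spec, 13), synthesize_cohort(spec, 13))
  expect_false(identical(synthesize_cohort(spec, 13)$recorded_dap_dgycm2,
                         synthesize_cohort(spec, 14)$recorded_dap_dgycm2))
  # the generator leaves the caller's RNG state untouched
  set.seed(99); before <- .Random.seed
  invisible(synthesize_cohort(spec, 13))
  expect_identical(.Random.seed, before)
})

test_that("stratum allocation honours the specification", {
  dev <- default_devices()[["newtom_vgi_evo"]]
  mix <- matrix(1 / 7, 7, 4,
                dimnames = list(clinical_indications(), age_groups()))
  one <- cohort_spec(dev, 1000, data.frame(
    age_group = ">=15y", mode_raw = "Regular scan", fov_diameter_cm = 10,
    fov_height_cm = 10, prob = 1, dap_mean = 3.0, dap_cv = 0.2), mix)
  log <- synthesize_cohort(one, 21)
  expect_equal(nrow(log), 1000)
  expect_true(all(log$operation_mode_raw == "Regular scan"))
  expect_true(all(log$patient_age >= 15))
  expect_true(all(log$recorded_dap_dgycm2 > 0))

  # exact allocation reproduces the target composition of the default spec
  spec <- default_tcm_spec()
  log <- synthesize_cohort(spec, 5)
  counts <- table(paste(assign_age_group(log$patient_age),
                        log$operation_mode_raw, log$fov_diameter_cm))
  want <- round(spec$strata$prob * spec$n)
  got <- as.integer(counts[paste(spec$strata$age_group, spec$strata$mode_raw,
                                 spec$strata$fov_diameter_cm)])
  expect_equal(got, want)

  # multinomial allocation stays within 99% binomial bounds per stratum
  mspec <- default_tcm_spec(allocation = "multinomial")
  mlog <- synthesize_cohort(mspec, 31)
  mcounts <- as.integer(table(paste(assign_age_group(mlog$patient_age),
                                    mlog$operation_mode_raw, mlog$fov_diameter_cm))[
    paste(mspec$strata$age_group, mspec$strata$mode_raw,
          mspec$strata$fov_diameter_cm)])
  mcounts[is.na(mcounts)] <- 0L
  lo <- qbinom(0.005, mspec$n, mspec$strata$prob)
  hi <- qbinom(0.995, mspec$n, mspec$strata$prob)
  expect_true(all(mcounts >= lo & mcounts <= hi))
})

test_that("invalid specifications are rejected", {
  dev <- default_devices()[["newtom_vgi_evo"]]
  mix <- matrix(1 / 7, 7, 4, dimnames = list(clinical_indications(), age_groups()))
  base <- data.frame(age_group = ">=15y", mode_raw = "Regular scan",
                     fov_diameter_cm = 10, fov_height_cm = 10, prob = 0.5,
                     dap_mean = 3, dap_cv = 0.2)
  expect_error(cohort_spec(dev, 10, base, mix), "sum to 1")
  bad_fov <- base; bad_fov$prob <- 1; bad_fov$fov_diameter_cm <- 99
  expect_error(cohort_spec(dev, 10, bad_fov, mix), "protocol catalog")
  bad_mix <- mix; bad_mix[1, 1] <- 2
  good <- base; good$prob <- 1
  expect_error(cohort_spec(dev, 10, good, bad_mix), "probability vector")
})

test_that("fixed-exposure records carry exactly the protocol values", {
  log <- synthesize_cohort(default_fixed_spec(n = 196), 17)
  expect_equal(nrow(log), 196)
  acc <- default_devices()[["accuitomo170"]]
  key <- paste(tolower(log$operation_mode_raw), log$fov_diameter_cm, log$fov_height_cm)
  pkey <- paste(tolower(acc$protocols$mode_raw), acc$protocols$fov_diameter_cm,
                acc$protocols$fov_height_cm)
  hit <- match(key, pkey)
  expect_false(any(is.na(hit)))
  expect_equal(log$total_exposure_mas, acc$protocols$mas_min[hit])
  expect_equal(log$recorded_dap_dgycm2,
               acc$protocols$nominal_recorded_dap_dgycm2[hit])
})

test_that("synthetic QC recovers the true correction factor", {
  dev <- default_devices()[["accuitomo170"]]
  # zero noise: exact recovery
  qc0 <- synthesize_qc(dev, true_factor = 0.76, noise_cv = 0, n = 6, seed = 1)
  expect_equal(derive_correction_factor(qc0)$factor, 0.76)

  # cv 0.02, n 6: within 3 x cv / sqrt(n) of the truth
  qc <- synthesize_qc(dev, true_factor = 0.76, noise_cv = 0.02, n = 6, seed = 8)
  k <- derive_correction_factor(qc)$factor
  expect_lt(abs(k - 0.76), 0.76 * 3 * 0.02 / sqrt(6))
  expect_gt(k, 0.74); expect_lt(k, 0.78)

  # an accurate-display device is emulated with factor 1
  qc1 <- synthesize_qc(default_devices()[["newtom_vgi_evo"]], 1.0, 0, 3, 2)
  expect_equal(derive_correction_factor(qc1)$factor, 1.0)

  expect_error(synthesize_qc(dev, 0.76, -0.1, 3, 1), "non-negative")
  expect_error(synthesize_qc(dev, 0, 0.1, 3, 1), "positive")
})

test_that("synthetic stratum mean doses track the generator targets", {
  spec <- default_tcm_spec()
  doses <- compute_doses(synthesize_cohort(spec, 12))$doses
  summ <- summarize_strata(doses)
  cf <- cf_lookup(default_cf_table(), "newtom_vgi_evo", spec$strata$age_group)
  target <- cf * spec$strata$dap_mean
  n_i <- round(spec$strata$prob * spec$n)
  key <- paste(summ$age_group, summ$fov_category, summ$mode)
  smode <- as.character(normalize_mode(spec$strata$mode_raw))
  sfov <- as.character(classify_fov(spec$strata$fov_diameter_cm,
                                    spec$strata$fov_height_cm))
  got <- summ$mean_dose[match(paste(spec$strata$age_group, sfov, smode), key)]
  # generator 95% band around the target stratum mean: 1.96 x cv / sqrt(n);
  # about 1 stratum in 20 may legitimately fall outside, so require the
  # large-n strata to sit mostly inside the 95% band and always within 4 sd
  band <- 1.96 * target * spec$strata$dap_cv / sqrt(n_i)
  big <- n_i >= 5
  expect_gte(mean((abs(got - target) <= band)[big]), 0.85)
  expect_true(all((abs(got - target) <= band * 4 / 1.96)[big]))
})
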