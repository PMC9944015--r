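# a small deterministic dose_results frame built by hand
toy_doses <- function(dose, device = "dev1", age = ">=15y", fov = "medium",
                      mode = "standard", ind = "pedodontics") {
  n <- length(dose)
  structure(data.frame(
    exam_id = paste0(device, seq_len(n)), device_id = device,
    corrected_dap_dgycm2 = dose / 10,
    age_group = factor(age, levels = age_groups()),
    fov_category = factor(fov, levels = fov_categories()),
    mode = factor(mode, levels = operation_modes()),
    indication = factor(ind, levels = clinical_indications()),
    effective_dose_usv = dose),
    class = c("dose_results", "data.frame"))
}

test_that("stratum summaries report normal-approximation CIs with n-1 sd", {
  s <- summarize_strata(toy_doses(c(10, 20, 30)))
  expect_equal(s$n, 3L)
  expect_equal(s$mean_dose, 20)
  expect_equal(s$dose_lo, 20 - 1.96 * 10 / sqrt(3))
  expect_equal(s$dose_hi, 20 + 1.96 * 10 / sqrt(3))
  expect_equal(display_3sf(c(s$dose_lo, s$dose_hi)), c(8.68, 31.3))

  # identical values -> zero-width CI; singleton -> CI absent
  z <- summarize_strata(toy_doses(c(7, 7, 7)))
  expect_equal(z$dose_lo, z$dose_hi)
  one <- summarize_strata(toy_doses(42))
  expect_true(is.na(one$dose_lo) && is.na(one$dap_hi))

  expect_error(summarize_strata(toy_doses(1:3), by = "nope"), "nope")
})

test_that("CI width shrinks as 1/sqrt(n) for fixed sample sd", {
  set.seed(31)
  w <- sapply(c(3, 12, 60), function(n) {
    vals <- 20 + 10 * as.numeric(scale(rnorm(n)))  # sample sd exactly 10
    s <- summarize_strata(toy_doses(vals))
    s$dose_hi - s$dose_lo
  })
  expect_equal(w[1] / w[2], sqrt(12 / 3), tolerance = 1e-10)
  expect_equal(w[2] / w[3], sqrt(60 / 12), tolerance = 1e-10)
})

test_that("frequency percentages are exhaustive and ratios round to 1 decimal", {
  d <- rbind(toy_doses(rep(10, 7), mode = "standard"),
             toy_doses(rep(20, 3), mode = "HR", ind = "endodontics"))
  fr <- frequency_tables(d)
  expect_equal(unname(fr$mode_freq[c("standard", "HR")]), c(70, 30))
  expect_equal(sum(fr$indication_by_mode), 100)
  expect_equal(sum(fr$indication_by_fov), 100)
  expect_equal(unname(colSums(fr$indication_within_age)[">=15y"]), 100)

  single <- frequency_tables(toy_doses(10))
  expect_equal(max(single$indication_by_age), 100)

  # per-device freq_pct columns sum to 100 within rounding slack
  log <- synthesize_cohort(default_tcm_spec(n = 500), seed = 2)
  summ <- summarize_strata(compute_doses(log)$doses)
  expect_equal(sum(summ$freq_pct), 100, tolerance = 0.2)
})

test_that("headline ratios reproduce the quoted request and dose ratios", {
  # request ratio from marginal mode frequencies 78.6 / 21.4 -> 3.7
  d <- rbind(toy_doses(rep(10, 786), mode = "standard"),
             toy_doses(rep(20, 214), mode = "HR"))
  fr <- frequency_tables(d)
  summ <- summarize_strata(d)
  hr <- suppressWarnings(headline_ratios(summ, fr))  # no large-FOV records here
  expect_equal(hr$standard_to_hr_requests, 3.7)
  expect_equal(hr$hr_to_standard_dose$ratio, 2.0)

  # identical numerator and denominator strata -> 1.0
  same <- rbind(toy_doses(rep(50, 5), mode = "standard"),
                toy_doses(rep(50, 5), mode = "HR"))
  expect_equal(suppressWarnings(
    headline_ratios(summarize_strata(same),
                    frequency_tables(same)))$hr_to_standard_dose$ratio, 1.0)

  # missing large-FOV and HR strata: ratios omitted with warnings
  w <- capture_warnings(
    headline_ratios(summ, frequency_tables(toy_doses(1:5, fov = "small"))))
  expect_true(any(grepl("large FOV", w)))
})

test_that("protocol summaries for the fixed-exposure device match hand arithmetic", {
  acc <- default_devices()[["accuitomo170"]]
  ps <- protocol_dose_summary(acc)
  lg_std <- ps[ps$fov_category == "large" & ps$mode == "standard" &
                 ps$age_group == ">=15y", ]
  # unweighted mean over the two large standard protocols at full precision
  expect_equal(lg_std$mean_dap, mean(c(21.7, 25.6) * 0.76))
  expect_equal(display_3sf(lg_std$mean_dap), 18.0)
  expect_equal(lg_std$n_protocols, 2L)
  # TCM devices have no protocol-level dose table
  expect_error(protocol_dose_summary(default_devices()[["newtom_vgi_evo"]]), "TCM")
})

test_that("sum of n x stratum mean dose reconstructs the collective dose exactly", {
  log <- synthesize_cohort(default_tcm_spec(n = 800), seed = 9)
  doses <- compute_doses(log)$doses
  summ <- summarize_strata(doses)
  expect_equal(collective_dose_from_summary(summ), collective_dose(doses))
})

test_that("a report bundle is written with display rounding", {
  log <- synthesize_cohort(default_tcm_spec(n = 200), seed = 4)
  out <- file.path(tempdir(), "report_test")
  files <- write_report(compute_doses(log)$doses, out)
  expect_true(all(file.exists(files)))
  head <- jsonlite::read_json(files[["headline"]])
  expect_true(head$collective_dose_mansv > 0)
  expect_equal(head$n_examinations, 200)
})
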