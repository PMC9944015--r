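make_cf_mas <- function(device, indication, age_years, cf) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(device = device, indication = indication,
                              age_years = age_years, cf_usv_per_mas = cf),
                   f, row.names = FALSE)
  read_cf_table(f)
}

links_for <- function(device, indication, d = 4, h = 4) {
  data.frame(device = device, indication = indication,
             fov_diameter_cm = d, fov_height_cm = h)
}

test_that("per-mAs CFs average unweighted over linked indications and ages", {
  # a single entry passes through unchanged
  one <- average_cf_per_fov(make_cf_mas("dev", "single tooth", 10, 0.42),
                            links_for("dev", "single tooth"), "7-11y")
  expect_equal(one$cf_usv_per_mas, 0.42)
  expect_equal(one$n_entries, 1L)

  # two indications at one age: mean of 0.4 and 0.6 is 0.5
  two <- average_cf_per_fov(
    make_cf_mas("dev", c("upper jaw", "lower jaw"), 10, c(0.4, 0.6)),
    rbind(links_for("dev", "upper jaw"), links_for("dev", "lower jaw")),
    "7-11y")
  expect_equal(two$cf_usv_per_mas, 0.5)

  # three ages inside the group for one indication: mean of 0.3/0.3/0.6
  ages <- average_cf_per_fov(
    make_cf_mas("dev", "skull", c(7, 8, 9), c(0.3, 0.3, 0.6)),
    links_for("dev", "skull"), "7-11y")
  expect_equal(ages$cf_usv_per_mas, 0.4)

  # ages outside the group are excluded -> no entries -> error naming the FOV
  expect_error(
    average_cf_per_fov(make_cf_mas("dev", "skull", 5, 0.3),
                       links_for("dev", "skull"), "7-11y"),
    "FOV 4 x 4")
})

test_that("per-DAP derivation matches the closed form on a single protocol", {
  per_fov <- data.frame(device = "tiny", fov_diameter_cm = 4,
                        fov_height_cm = 4, age_group = "7-11y",
                        cf_usv_per_mas = 0.4)
  dev <- tiny_device(mas = 87.5, dap = 4.02, k = 0.76)
  got <- derive_cf_per_dap(per_fov, dev, "7-11y")
  expect_equal(got$cf_usv_per_dapcm2, 0.4 * 87.5 / 3.0552)
  expect_equal(display_3sf(got$cf_usv_per_dapcm2), 11.5)

  # closed-form collapse holds across random single-protocol devices
  set.seed(3)
  for (i in 1:10) {
    mas <- runif(1, 20, 200); dap <- runif(1, 1, 40)
    k <- runif(1, 0.5, 1.5); cf <- runif(1, 0.1, 2)
    d <- tiny_device(mas = mas, dap = dap, k = k)
    pf <- per_fov; pf$cf_usv_per_mas <- cf
    expect_equal(derive_cf_per_dap(pf, d, "7-11y")$cf_usv_per_dapcm2,
                 cf * mas / (dap * k))
  }
})

test_that("TCM derivation averages per-exam ratios and is permutation-invariant", {
  dev <- default_devices()[["newtom_vgi_evo"]]
  per_fov <- data.frame(device = dev$device_id,
                        fov_diameter_cm = c(10, 24), fov_height_cm = c(10, 19),
                        age_group = ">=15y", cf_usv_per_mas = c(0.5, 0.9))
  ex <- data.frame(
    exam_id = paste0("e", 1:4), device_id = dev$device_id,
    patient_age = c(20, 30, 40, 50),
    fov_diameter_cm = c(10, 10, 24, 24), fov_height_cm = c(10, 10, 19, 19),
    total_exposure_mas = c(20, 25, 30, 18),
    recorded_dap_dgycm2 = c(3.0, 3.4, 9.0, 8.1))
  got <- derive_cf_per_dap(per_fov, dev, ">=15y", exposures = ex)
  manual <- mean(c(0.5 * 20 / 3.0, 0.5 * 25 / 3.4, 0.9 * 30 / 9.0, 0.9 * 18 / 8.1))
  expect_equal(got$cf_usv_per_dapcm2, manual)
  expect_equal(got$n, 4L)

  shuf <- derive_cf_per_dap(per_fov, dev, ">=15y", exposures = ex[c(3, 1, 4, 2), ])
  expect_equal(shuf$cf_usv_per_dapcm2, got$cf_usv_per_dapcm2)

  # dose and DAP scaled by the same constant leave the ratio invariant
  ex2 <- ex
  ex2$total_exposure_mas <- ex$total_exposure_mas * 3
  ex2$recorded_dap_dgycm2 <- ex$recorded_dap_dgycm2 * 3
  expect_equal(derive_cf_per_dap(per_fov, dev, ">=15y", exposures = ex2)$cf_usv_per_dapcm2,
               got$cf_usv_per_dapcm2)

  expect_error(derive_cf_per_dap(per_fov, dev, "4-6y", exposures = ex),
               "no exposure samples")
  expect_error(derive_cf_per_dap(per_fov, dev, ">=15y"), "tube current modulation")
})

test_that("CF validation reports mean deviation and the within-20% fraction", {
  # identical doses: zero deviation, full coverage
  v0 <- validate_cf(c(10, 20), c(10, 20))
  expect_equal(v0$mean_relative_deviation, 0)
  expect_equal(v0$fraction_within_20pct, 1.0)

  # deviations 0.1, 0.1, 0.3, 0.5 -> mean 0.25, half within 20%
  e_mas <- c(100, 100, 100, 100)
  v <- validate_cf(e_mas, c(110, 90, 130, 150))
  expect_equal(v$mean_relative_deviation, 0.25)
  expect_equal(v$fraction_within_20pct, 0.5)
  expect_equal(v$n, 4L)

  # the 20% boundary is inclusive
  expect_equal(validate_cf(100, 119)$fraction_within_20pct, 1.0)
  expect_equal(validate_cf(100, 120)$fraction_within_20pct, 1.0)
  expect_equal(validate_cf(100, 121)$fraction_within_20pct, 0.0)

  expect_error(validate_cf(c(100, 0), c(90, 10)), "positive")
})

test_that("the shipped synthetic per-mAs inputs drive the full derivation", {
  cf_mas <- synthetic_cf_per_mas()
  links <- synthetic_fov_links()
  acc <- default_devices()[["accuitomo170"]]
  # every catalog FOV must be reachable from at least one indication
  cat_fovs <- unique(paste(acc$protocols$fov_diameter_cm, acc$protocols$fov_height_cm))
  expect_true(all(cat_fovs %in% paste(links$fov_diameter_cm, links$fov_height_cm)))
  for (g in age_groups()) {
    per_fov <- average_cf_per_fov(cf_mas, links, g)
    got <- derive_cf_per_dap(per_fov, acc, g)
    expect_gt(got$cf_usv_per_dapcm2, 0)
  }
})
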