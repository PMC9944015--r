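# Synthetic exposure-log generation. No patient-level CBCT dose data are
# publicly deposited, so the pipeline ships a generator that emulates the
# two scanner behaviours the analysis must handle: a fixed-exposure device
# whose protocols always deliver their nominal DAP, and a tube-current-
# modulated (TCM) device whose recorded DAP varies from patient to patient
# around a stratum-level mean. DAP noise is log-normal: DAP is positive and
# right-skewed under patient-size variation.

# run expr under a seed, restoring any pre-existing global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Specify a synthetic cohort
#'
#' A cohort specification pairs a device profile with a joint stratum table
#' — one row per (age group, operation mode, FOV) cell with its occupancy
#' probability and, for TCM devices, the target mean recorded DAP and its
#' coefficient of variation — plus an indication mix per age group. The age
#' mix is the row-sum marginal of the stratum table.
#'
#' @param device a `device_profile`.
#' @param n number of examinations to generate.
#' @param strata data frame with columns `age_group, mode_raw,
#'   fov_diameter_cm, fov_height_cm, prob` and, for TCM devices, `dap_mean`
#'   and `dap_cv`; probabilities must sum to 1 and every (mode, FOV) must
#'   exist in the device's protocol catalog.
#' @param indication_mix matrix of probabilities, clinical indications in
#'   rows and age groups in columns; each column sums to 1.
#' @param allocation `"exact"` (default) allocates stratum counts
#'   deterministically by largest-remainder rounding of `n x prob`, so the
#'   cohort composition is fixed and only exposure values are random;
#'   `"multinomial"` draws counts from the stratum probabilities.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(device, n, strata, indication_mix,
                        allocation = c("exact", "multinomial")) {
  stopifnot(inherits(device, "device_profile"), n >= 1)
  allocation <- match.arg(allocation)
  need <- c("age_group", "mode_raw", "fov_diameter_cm", "fov_height_cm", "prob")
  stopifnot(all(need %in% names(strata)))
  if (abs(sum(strata$prob) - 1) > 1e-8 || any(strata$prob < 0)) {
    stop_("stratum probabilities must be non-negative and sum to 1")
  }
  prot_key <- paste(tolower(trimws(device$protocols$mode_raw)),
                    device$protocols$fov_diameter_cm,
                    device$protocols$fov_height_cm)
  strat_key <- paste(tolower(trimws(strata$mode_raw)),
                     strata$fov_diameter_cm, strata$fov_height_cm)
  bad <- !(strat_key %in% prot_key)
  if (any(bad)) {
    stop_("stratum %d references a (mode, FOV) absent from the protocol catalog of '%s'",
          which(bad)[1], device$device_id)
  }
  if (device$tcm) {
    stopifnot(all(c("dap_mean", "dap_cv") %in% names(strata)))
    if (any(strata$dap_mean <= 0)) stop_("target mean DAPs must be positive")
    if (any(strata$dap_cv < 0)) stop_("DAP coefficients of variation must be non-negative")
  }
  stopifnot(is.matrix(indication_mix),
            setequal(rownames(indication_mix), INDICATIONS),
            all(AGE_GROUPS %in% colnames(indication_mix)))
  if (any(abs(colSums(indication_mix) - 1) > 1e-8) || any(indication_mix < 0)) {
    stop_("each indication-mix column must be a probability vector summing to 1")
  }
  structure(list(device = device, n = as.integer(n), strata = strata,
                 indication_mix = indication_mix, allocation = allocation),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s: n = %d, %d strata, %s allocation\n",
              x$device$device_id, x$n, nrow(x$strata), x$allocation))
  invisible(x)
}

# department emitting each indication under the shipped default map
department_for <- function(indication, mapping = default_indication_map()) {
  mapping$department[match(indication, mapping$indication)]
}

#' Generate a synthetic exposure log
#'
#' Draws `spec$n` examination records. Stratum membership follows the
#' specification's allocation rule; within a stratum, patient ages are
#' uniform over the group's integer years (15-80 for the adult group),
#' acquisition dates are uniform over 2019, and the referral department is
#' drawn from the age group's indication mix. Fixed-exposure records carry
#' exactly the protocol's mAs and nominal recorded DAP; TCM records draw the
#' recorded DAP from a log-normal with the stratum's target mean and CV, and
#' a mAs value uniform within the protocol's range.
#'
#' @param spec a `cohort_spec`.
#' @param seed integer seed; the same (seed, spec) always yields the same log.
#' @return An exposure-record data frame (same schema as
#'   [read_exposure_log()]).
#' @export
synthesize_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    dev <- spec$device
    counts <- switch(spec$allocation,
      exact = largest_remainder(spec$n, spec$strata$prob),
      multinomial = as.integer(stats::rmultinom(1, spec$n, spec$strata$prob))
    )
    prot_key <- paste(tolower(trimws(dev$protocols$mode_raw)),
                      dev$protocols$fov_diameter_cm,
                      dev$protocols$fov_height_cm)
    rows <- lapply(seq_len(nrow(spec$strata)), function(i) {
      m <- counts[i]
      if (m == 0) return(NULL)
      s <- spec$strata[i, ]
      prot <- dev$protocols[match(paste(tolower(trimws(s$mode_raw)),
                                        s$fov_diameter_cm, s$fov_height_cm),
                                  prot_key), ]
      rng <- age_group_range(s$age_group)
      ages <- sample(seq(rng[1], min(rng[2], 80L)), m, replace = TRUE)
      ind <- sample(INDICATIONS, m, replace = TRUE,
                    prob = spec$indication_mix[INDICATIONS, as.character(s$age_group)])
      if (dev$tcm) {
        dap <- rlnorm_mean_cv(m, s$dap_mean, s$dap_cv)
        mas <- round(stats::runif(m, prot$mas_min, prot$mas_max), 1)
      } else {
        dap <- rep(prot$nominal_recorded_dap_dgycm2, m)
        mas <- rep(prot$mas_min, m)
      }
      data.frame(
        exam_id = NA_character_,
        device_id = dev$device_id,
        acquired_on = as.Date("2019-01-01") + sample(0:364, m, replace = TRUE),
        patient_age = ages,
        referral_department = department_for(ind),
        operation_mode_raw = s$mode_raw,
        fov_diameter_cm = s$fov_diameter_cm,
        fov_height_cm = s$fov_height_cm,
        tube_voltage_kv = prot$tube_voltage_kv,
        total_exposure_mas = mas,
        recorded_dap_dgycm2 = dap,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out$exam_id <- sprintf("%s-%05d", dev$device_id, seq_len(nrow(out)))
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic QC measurement pairs
#'
#' Emulates an annual QC campaign: for each measurement the recorded DAP is
#' a standard-protocol nominal value (cycling through a small, a medium and
#' a large FOV) and the measured DAP is `recorded x true_factor` times
#' mean-one multiplicative log-normal noise with coefficient of variation
#' `noise_cv`. [derive_correction_factor()] recovers `true_factor` to within
#' about `3 x noise_cv / sqrt(n)`.
#'
#' @param device a `device_profile`.
#' @param true_factor the true measured/recorded ratio (> 0); 1.0 emulates a
#'   device whose displayed DAP is accurate.
#' @param noise_cv coefficient of variation of the measurement noise (>= 0).
#' @param n number of measurement pairs (>= 1).
#' @param seed integer seed.
#' @return A QC-measurement data frame (see [read_qc_file()]).
#' @export
synthesize_qc <- function(device, true_factor, noise_cv, n, seed) {
  stopifnot(inherits(device, "device_profile"), n >= 1)
  if (true_factor <= 0) stop_("true_factor must be positive")
  if (noise_cv < 0) stop_("noise_cv must be non-negative")
  with_seed(seed, {
    prot <- device$protocols
    std <- prot[normalize_mode(prot$mode_raw) == "standard", ]
    std <- std[order(std$fov_diameter_cm * std$fov_height_cm), ]
    pick <- std[unique(round(seq(1, nrow(std), length.out = min(3, nrow(std))))), ]
    idx <- rep_len(seq_len(nrow(pick)), n)
    recorded <- pick$nominal_recorded_dap_dgycm2[idx]
    measured <- recorded * true_factor * rlnorm_mean_cv(n, 1, noise_cv)
    data.frame(
      device_id = device$device_id,
      fov_label = sprintf("%gx%g", pick$fov_diameter_cm[idx],
                          pick$fov_height_cm[idx]),
      measured_dap_dgycm2 = measured,
      recorded_dap_dgycm2 = recorded,
      stringsAsFactors = FALSE
    )
  })
}

# default indication mixes per age group: surgery-dominant, with pediatric
# groups showing more pedodontic and orthodontic referrals and adults more
# implant placement (no pedodontic referrals for adults)
default_indication_mix <- function() {
  m <- rbind(
    "endodontics"                        = c(0.01, 0.02, 0.03, 0.03),
    "orthodontic planning"               = c(0.03, 0.12, 0.15, 0.05),
    "pedodontics"                        = c(0.20, 0.20, 0.15, 0.00),
    "implant placement"                  = c(0.01, 0.02, 0.03, 0.10),
    "surgical planning and follow-up"    = c(0.67, 0.50, 0.50, 0.67),
    "second opinion radiodiagnosis"      = c(0.06, 0.12, 0.12, 0.10),
    "medically compromised patient care" = c(0.02, 0.02, 0.02, 0.05)
  )
  colnames(m) <- AGE_GROUPS
  m
}

#' Default synthetic cohort specifications
#'
#' `default_tcm_spec()` targets the TCM scanner's audited composition: 19
#' strata over (age group, FOV category, mode) with the audited counts as
#' occupancy probabilities (n = 4967) and the audited per-stratum mean
#' corrected DAPs as log-normal targets; each FOV category is represented by
#' its most used FOV (5 x 5 small, 10 x 10 medium, 24 x 19 large). The DAP
#' coefficient of variation defaults to 0.25, chosen so synthetic stratum
#' confidence intervals have widths of the same order as audited ones.
#' `default_fixed_spec()` covers the fixed-exposure scanner's protocols with
#' an adult-dominated mix (n = 196).
#'
#' @param n cohort size.
#' @param dap_cv coefficient of variation of within-stratum DAP (TCM only).
#' @param allocation passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
default_tcm_spec <- function(n = 4967, dap_cv = 0.25, allocation = "exact") {
  dev <- default_devices()[["newtom_vgi_evo"]]
  g <- AGE_GROUPS
  s <- function(age, fov, mode, mean, count) {
    dims <- switch(fov, small = c(5, 5), medium = c(10, 10), large = c(24, 19))
    data.frame(age_group = age, mode_raw = mode, fov_diameter_cm = dims[1],
               fov_height_cm = dims[2], prob = count, dap_mean = mean,
               dap_cv = dap_cv, stringsAsFactors = FALSE)
  }
  strata <- rbind(
    s(g[1], "small",  "High-Resolution", 3.47, 1),
    s(g[1], "medium", "Regular scan",    3.15, 1),
    s(g[1], "medium", "High-Resolution", 4.71, 4),
    s(g[1], "large",  "Regular scan",    6.09, 3),
    s(g[2], "small",  "Regular scan",    0.94, 1),
    s(g[2], "small",  "High-Resolution", 3.78, 12),
    s(g[2], "medium", "Regular scan",    2.12, 52),
    s(g[2], "medium", "High-Resolution", 6.19, 144),
    s(g[2], "large",  "Regular scan",    7.51, 18),
    s(g[3], "small",  "Regular scan",    1.04, 3),
    s(g[3], "small",  "High-Resolution", 3.96, 10),
    s(g[3], "medium", "Regular scan",    2.48, 81),
    s(g[3], "medium", "High-Resolution", 7.14, 75),
    s(g[3], "large",  "Regular scan",    7.64, 55),
    s(g[4], "small",  "Regular scan",    1.16, 3),
    s(g[4], "small",  "High-Resolution", 4.72, 55),
    s(g[4], "medium", "Regular scan",    2.93, 2263),
    s(g[4], "medium", "High-Resolution", 8.59, 796),
    s(g[4], "large",  "Regular scan",    7.73, 1390)
  )
  strata$prob <- strata$prob / sum(strata$prob)
  cohort_spec(dev, n, strata, default_indication_mix(), allocation)
}

#' @rdname default_tcm_spec
#' @export
default_fixed_spec <- function(n = 196, allocation = "exact") {
  dev <- default_devices()[["accuitomo170"]]
  g <- AGE_GROUPS
  s <- function(age, mode, d, h, prob) {
    data.frame(age_group = age, mode_raw = mode, fov_diameter_cm = d,
               fov_height_cm = h, prob = prob, dap_mean = NA_real_,
               dap_cv = NA_real_, stringsAsFactors = FALSE)
  }
  strata <- rbind(
    s(g[4], "Standard", 4, 4, 0.04),  s(g[4], "Standard", 6, 6, 0.04),
    s(g[4], "Standard", 10, 5, 0.08), s(g[4], "Standard", 8, 8, 0.12),
    s(g[4], "Standard", 10, 10, 0.16), s(g[4], "Standard", 14, 10, 0.10),
    s(g[4], "Standard", 17, 12, 0.10),
    s(g[4], "High-Fidelity", 14, 10, 0.10),
    s(g[4], "High-Fidelity", 17, 12, 0.14),
    s(g[3], "Standard", 8, 8, 0.02), s(g[3], "Standard", 10, 10, 0.02),
    s(g[3], "High-Fidelity", 14, 10, 0.01),
    s(g[2], "Standard", 6, 6, 0.02), s(g[2], "Standard", 10, 10, 0.02),
    s(g[2], "High-Fidelity", 17, 12, 0.01),
    s(g[1], "Standard", 4, 4, 0.01), s(g[1], "Standard", 10, 10, 0.01)
  )
  cohort_spec(dev, n, strata, default_indication_mix(), allocation)
}
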