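# Conversion-factor derivation: indication- and age-specific effective dose
# conversion factors are published per unit tube loading (uSv/mAs), but a
# dose-monitoring system keyed on DICOM headers can only apply one DAP-based
# factor (uSv/dGy.cm2) per device and age group. This module averages the
# per-mAs factors over indications and ages, converts them to per-DAP
# factors through the device's exposure chain, and quantifies the error the
# averaging introduces.

#' Synthetic per-mAs CF example inputs
#'
#' The indication- and age-specific per-mAs conversion factors used in
#' practice come from Monte Carlo organ-dose studies and are not
#' redistributed here. These accessors load a clearly synthetic example
#' table (plausible magnitudes, decreasing with age, increasing with scanned
#' region) and a matching indication-to-FOV link table, so the derivation
#' workflow can be exercised end to end.
#'
#' @return `synthetic_cf_per_mas()`: a per-mAs `cf_table`;
#'   `synthetic_fov_links()`: a link data frame for [average_cf_per_fov()].
#' @export
synthetic_cf_per_mas <- function() {
  read_cf_table(system.file("extdata", "cf_per_mas_synthetic.csv",
                            package = "cbctdose", mustWork = TRUE))
}

#' @rdname synthetic_cf_per_mas
#' @export
synthetic_fov_links <- function() {
  utils::read.csv(system.file("extdata", "indication_fov_links_synthetic.csv",
                              package = "cbctdose", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

# integer-age bounds of each dosimetric age group (adults use the 15-y CFs)
age_group_range <- function(age_group) {
  switch(as.character(age_group),
         "4-6y" = c(4L, 6L),
         "7-11y" = c(7L, 11L),
         "12-14y" = c(12L, 14L),
         ">=15y" = c(15L, .Machine$integer.max),
         stop_("unknown age group '%s'", age_group))
}

#' Average per-mAs conversion factors onto FOVs
#'
#' For one age group, links each field of view in a device's catalog to the
#' anatomical indications that use it and takes the unweighted arithmetic
#' mean of the per-mAs conversion factors over all linked indications and
#' all integer ages inside the group. The result is one averaged factor
#' (uSv/mAs) per FOV and age group.
#'
#' @param cf_mas a `cf_table` with dialect `"per_mas"` (columns `device,
#'   indication, age_years, cf_usv_per_mas`).
#' @param links data frame linking indications to FOVs: columns `device,
#'   indication, fov_diameter_cm, fov_height_cm`, one row per link.
#' @param age_group a single age-group label.
#' @return Data frame `device, fov_diameter_cm, fov_height_cm, age_group,
#'   cf_usv_per_mas, n_entries`.
#' @export
average_cf_per_fov <- function(cf_mas, links, age_group) {
  stopifnot(identical(attr(cf_mas, "dialect"), "per_mas"))
  age_group <- match.arg(as.character(age_group), AGE_GROUPS)
  rng <- age_group_range(age_group)
  fovs <- unique(links[c("device", "fov_diameter_cm", "fov_height_cm")])
  out <- lapply(seq_len(nrow(fovs)), function(i) {
    f <- fovs[i, ]
    inds <- links$indication[links$device == f$device &
                               links$fov_diameter_cm == f$fov_diameter_cm &
                               links$fov_height_cm == f$fov_height_cm]
    sel <- cf_mas$device == f$device &
      cf_mas$indication %in% inds &
      cf_mas$age_years >= rng[1] & cf_mas$age_years <= rng[2]
    if (!any(sel)) {
      stop_("FOV %g x %g on device '%s' has no linked per-mAs CF entries in age group %s",
            f$fov_diameter_cm, f$fov_height_cm, f$device, age_group)
    }
    data.frame(device = f$device,
               fov_diameter_cm = f$fov_diameter_cm,
               fov_height_cm = f$fov_height_cm,
               age_group = age_group,
               cf_usv_per_mas = mean(cf_mas$cf_usv_per_mas[sel]),
               n_entries = sum(sel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# match a per-FOV averaged CF to exact FOV dimensions
fov_cf_lookup <- function(per_fov_cf, diameter, height) {
  key <- paste(diameter, height)
  hit <- match(key, paste(per_fov_cf$fov_diameter_cm, per_fov_cf$fov_height_cm))
  if (any(is.na(hit))) {
    i <- which(is.na(hit))[1]
    stop_("no averaged per-mAs CF for FOV %g x %g", diameter[i], height[i])
  }
  per_fov_cf$cf_usv_per_mas[hit]
}

#' Derive a per-DAP conversion factor for one device and age group
#'
#' Runs the per-mAs factors through the device's exposure chain to obtain a
#' single DAP-based factor. For each examination (TCM device) or protocol
#' (fixed-exposure device), the effective dose from tube loading is
#' `cf(FOV) x mAs` and the ratio `dose / corrected DAP` is formed; the
#' per-DAP factor is the unweighted arithmetic mean of these ratios.
#' Fixed-exposure devices need no patient data: the protocol catalog's fixed
#' mAs and nominal recorded DAP suffice. TCM devices need patient exposure
#' samples because their DAP varies with the patient.
#'
#' @param per_fov_cf output of [average_cf_per_fov()] for the age group.
#' @param device a `device_profile`.
#' @param age_group a single age-group label.
#' @param exposures exposure-record data frame (required for TCM devices;
#'   only rows of this device whose age falls in `age_group` are used).
#' @param correction DAP correction factor k; defaults to the profile's.
#' @return A one-row data frame `device, age_group, cf_usv_per_dapcm2, n`.
#' @export
derive_cf_per_dap <- function(per_fov_cf, device, age_group, exposures = NULL,
                              correction = device$dap_correction_factor) {
  stopifnot(inherits(device, "device_profile"))
  age_group <- match.arg(as.character(age_group), AGE_GROUPS)
  if (inherits(correction, "dap_correction")) correction <- correction$factor

  if (device$tcm) {
    if (is.null(exposures)) {
      stop_("device '%s' applies tube current modulation: patient exposure samples are required",
            device$device_id)
    }
    sel <- exposures$device_id == device$device_id &
      as.character(assign_age_group(exposures$patient_age, strict = FALSE)) == age_group
    sel[is.na(sel)] <- FALSE
    ex <- exposures[sel, , drop = FALSE]
    if (nrow(ex) == 0) {
      stop_("no exposure samples for device '%s' in age group %s",
            device$device_id, age_group)
    }
    cf <- fov_cf_lookup(per_fov_cf, ex$fov_diameter_cm, ex$fov_height_cm)
    dose_mas <- cf * ex$total_exposure_mas
    dap_corr <- apply_correction(ex$recorded_dap_dgycm2, correction)
    if (any(dap_corr <= 0)) {
      stop_("zero corrected DAP for exam '%s'", ex$exam_id[which(dap_corr <= 0)[1]])
    }
  } else {
    prot <- device$protocols
    cf <- fov_cf_lookup(per_fov_cf, prot$fov_diameter_cm, prot$fov_height_cm)
    dose_mas <- cf * prot$mas_min  # fixed exposure: mas_min == mas_max
    dap_corr <- apply_correction(prot$nominal_recorded_dap_dgycm2, correction)
    if (any(dap_corr <= 0)) {
      stop_("zero corrected nominal DAP in protocol %d of device '%s'",
            which(dap_corr <= 0)[1], device$device_id)
    }
  }
  data.frame(device = device$device_id, age_group = age_group,
             cf_usv_per_dapcm2 = mean(dose_mas / dap_corr),
             n = length(dose_mas), stringsAsFactors = FALSE)
}

#' Validate an averaged per-DAP factor against per-mAs doses
#'
#' The averaging over indications and ages introduces a per-examination
#' error. Given the effective dose of each examination computed both ways —
#' from the original per-mAs factors (`e_mas`) and from the averaged per-DAP
#' factor (`e_dap`) — this reports the mean relative deviation
#' `|e_dap - e_mas| / e_mas` and the fraction of examinations whose
#' deviation is within 20% (inclusive).
#'
#' @param e_mas,e_dap numeric vectors of per-examination effective doses in
#'   uSv, same length; `e_mas` strictly positive.
#' @param device_id,age_group optional labels carried into the result.
#' @return A `cf_validation` list: `device_id`, `age_group`,
#'   `mean_relative_deviation`, `fraction_within_20pct`, `n`, `deviations`.
#' @export
validate_cf <- function(e_mas, e_dap, device_id = NA_character_,
                        age_group = NA_character_) {
  stopifnot(length(e_mas) == length(e_dap))
  if (length(e_mas) == 0) stop_("validation needs at least one examination")
  if (any(e_mas <= 0)) {
    stop_("per-mAs effective dose must be positive (examination %d)",
          which(e_mas <= 0)[1])
  }
  dev <- abs(e_dap - e_mas) / e_mas
  structure(
    list(device_id = device_id, age_group = age_group,
         mean_relative_deviation = mean(dev),
         fraction_within_20pct = mean(dev <= 0.20),
         n = length(dev), deviations = dev),
    class = "cf_validation"
  )
}

#' @export
print.cf_validation <- function(x, ...) {
  cat(sprintf("<cf_validation>%s%s n = %d\n",
              if (!is.na(x$device_id)) paste0(" ", x$device_id) else "",
              if (!is.na(x$age_group)) paste0(" [", x$age_group, "]") else "",
              x$n))
  cat(sprintf("  mean relative deviation: %.1f%%; within 20%%: %.0f%%\n",
              100 * x$mean_relative_deviation, 100 * x$fraction_within_20pct))
  invisible(x)
}
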