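# Effective dose computation: E = CF_E x DAP_corrected, with E in uSv, CF_E
# in uSv/(dGy.cm2) and the corrected DAP in dGy.cm2. All arithmetic is
# carried at full precision; 3-significant-figure rounding happens only at
# report boundaries.

#' Effective dose from corrected DAP
#'
#' @param corrected_dap corrected DAP in dGy.cm2 (>= 0).
#' @param cf per-DAP conversion factor in uSv/(dGy.cm2) (> 0).
#' @return Effective dose in uSv, at full precision.
#' @examples
#' effective_dose(4.655, 7.55)               # 35.14525
#' display_3sf(effective_dose(4.655, 7.55))  # 35.1
#' @export
effective_dose <- function(corrected_dap, cf) {
  if (any(is.na(corrected_dap)) || any(corrected_dap < 0)) {
    stop_("corrected DAP must be non-negative")
  }
  if (any(cf <= 0)) stop_("conversion factor must be positive")
  corrected_dap * cf
}

#' Compute per-examination effective doses for a whole log
#'
#' Runs every exposure record through the full chain: DAP correction with
#' the device's factor, classification into age group / FOV category /
#' normalized mode / clinical indication, conversion-factor lookup, and
#' effective dose. Records whose age falls below the youngest covered group
#' are not silently dropped: they are routed to a rejects data frame.
#'
#' @param records exposure-record data frame ([read_exposure_log()]).
#' @param devices device registry (named list of `device_profile`).
#' @param cf_table per-DAP `cf_table`; defaults to the shipped table.
#' @param corrections optional named list/vector of correction factors by
#'   device_id (overriding the registry values), e.g. freshly derived from
#'   QC data with [derive_correction_factor()].
#' @param indication_map department-to-indication table.
#' @param unmapped passed to [map_indication()].
#' @return A list with `doses` (a `dose_results` data frame: the input
#'   columns plus `corrected_dap_dgycm2`, `age_group`, `fov_category`,
#'   `mode`, `indication`, `effective_dose_usv`) and `rejects` (records that
#'   could not be classified, with a `reject_reason` column).
#' @export
compute_doses <- function(records, devices = default_devices(),
                          cf_table = default_cf_table(),
                          corrections = NULL,
                          indication_map = default_indication_map(),
                          unmapped = "error") {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    empty <- records
    empty$corrected_dap_dgycm2 <- numeric(0)
    empty$age_group <- factor(character(0), levels = AGE_GROUPS)
    empty$fov_category <- factor(character(0), levels = FOV_CATEGORIES)
    empty$mode <- factor(character(0), levels = OPERATION_MODES)
    empty$indication <- factor(character(0), levels = INDICATIONS)
    empty$effective_dose_usv <- numeric(0)
    class(empty) <- c("dose_results", class(empty))
    return(list(doses = empty, rejects = cbind(records[0, ], reject_reason = character(0))))
  }

  k_for <- function(id) {
    if (!is.null(corrections) && !is.null(corrections[[id]])) {
      k <- corrections[[id]]
      if (inherits(k, "dap_correction")) k$factor else k
    } else {
      devices[[id]]$dap_correction_factor
    }
  }
  k <- vapply(records$device_id, k_for, numeric(1), USE.NAMES = FALSE)

  age_group <- assign_age_group(records$patient_age, strict = FALSE)
  rejected <- is.na(age_group)
  rejects <- records[rejected, , drop = FALSE]
  if (nrow(rejects) > 0) {
    rejects$reject_reason <- sprintf(
      "age %d y below youngest covered group (4-6 y)", rejects$patient_age)
  } else {
    rejects$reject_reason <- character(0)
  }

  out <- records[!rejected, , drop = FALSE]
  k <- k[!rejected]
  out$corrected_dap_dgycm2 <- apply_correction(out$recorded_dap_dgycm2, k)
  out$age_group <- age_group[!rejected]
  out$fov_category <- classify_fov(out$fov_diameter_cm, out$fov_height_cm)
  out$mode <- normalize_mode(out$operation_mode_raw)
  out$indication <- map_indication(out$referral_department, indication_map,
                                   unmapped = unmapped)
  cf <- cf_lookup(cf_table, out$device_id, out$age_group)
  out$effective_dose_usv <- effective_dose(out$corrected_dap_dgycm2, cf)
  rownames(out) <- NULL
  class(out) <- c("dose_results", class(out))
  list(doses = out, rejects = rejects)
}

#' Collective effective dose of a cohort
#'
#' The sum of all individual patient effective doses, expressed in
#' man-sievert (1 manSv = 1e6 uSv summed over patients).
#'
#' @param doses a `dose_results` data frame, or a numeric vector of
#'   per-examination effective doses in uSv.
#' @return Collective effective dose in manSv.
#' @examples
#' collective_dose(c(50, 100))  # 1.5e-4 manSv
#' @export
collective_dose <- function(doses) {
  e <- if (is.data.frame(doses)) doses$effective_dose_usv else doses
  if (length(e) == 0) return(0)
  if (any(e < 0)) stop_("effective doses must be non-negative")
  sum(e) * 1e-6
}
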