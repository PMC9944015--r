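# Classification of exposure records into the audit's reporting axes:
# age group, FOV size category, normalized operation mode, clinical
# indication. All classifiers are pure, vectorized functions.

#' Assign the dosimetric age group
#'
#' Buckets integer patient ages into the four groups the conversion-factor
#' tables are defined for: 4-6 y, 7-11 y, 12-14 y, and >=15 y. Adults fall in
#' the >=15 y group, whose conversion factors are taken as a good estimate
#' for adult head dosimetry (head circumference changes little after 15).
#'
#' Ages below 4 have no conversion-factor coverage. With `strict = TRUE`
#' (default) they raise an error; with `strict = FALSE` they return `NA` so
#' callers can route such records to a rejects report.
#'
#' @param age integer vector of patient ages in whole years (floor of
#'   chronological age).
#' @param strict logical; reject under-4 ages with an error (default) or
#'   return `NA` for them.
#' @return A factor with levels `age_groups()`.
#' @examples
#' assign_age_group(c(5, 12, 15, 40))
#' @export
assign_age_group <- function(age, strict = TRUE) {
  if (any(is.na(age)) || any(age < 0)) {
    stop_("patient age must be a non-negative integer (years)")
  }
  too_young <- age < 4
  if (strict && any(too_young)) {
    stop_("age %d y is below the youngest covered group (4-6 y): no conversion factor exists for this age",
          min(age[too_young]))
  }
  idx <- findInterval(age, c(4, 7, 12, 15))
  idx[too_young] <- NA_integer_
  factor(AGE_GROUPS[idx], levels = AGE_GROUPS)
}

#' Classify a field of view by area
#'
#' The cylindrical FOV is given as diameter x height in cm; its area product
#' (cm^2) drives the size category: small (< 40 cm^2), medium (40-100 cm^2,
#' both ends included), large (> 100 cm^2). The 40 cm^2 boundary (the 8 x 5
#' FOV) belongs to the medium group.
#'
#' @param diameter_cm,height_cm positive numeric vectors, FOV diameter and
#'   height in cm (diameter first, height second).
#' @return A factor with levels `fov_categories()`.
#' @examples
#' classify_fov(c(4, 8, 10, 14), c(4, 5, 10, 10))
#' @export
classify_fov <- function(diameter_cm, height_cm) {
  if (any(is.na(diameter_cm)) || any(is.na(height_cm)) ||
      any(diameter_cm <= 0) || any(height_cm <= 0)) {
    stop_("FOV diameter and height must both be positive")
  }
  area <- diameter_cm * height_cm
  out <- ifelse(area < 40, "small", ifelse(area <= 100, "medium", "large"))
  factor(out, levels = FOV_CATEGORIES)
}

# device-native labels -> normalized mode
MODE_SYNONYMS <- c(
  "standard" = "standard",
  "regular scan" = "standard",
  "high-fidelity" = "HR",
  "high-resolution" = "HR",
  "hr" = "HR",
  "hq" = "HR"
)

#' Normalize a device-native operation-mode label
#'
#' Scanners name their modes differently; for reporting, standard and regular
#' scan modes are pooled as "standard" and high-fidelity / high-resolution
#' modes as "HR". Matching is case-insensitive after trimming. When a device
#' profile is supplied the raw label must appear in its protocol catalog.
#'
#' @param raw_label character vector of device-native mode labels.
#' @param device optional `device_profile`; if given, labels are validated
#'   against its protocol catalog.
#' @return A factor with levels `operation_modes()`.
#' @export
normalize_mode <- function(raw_label, device = NULL) {
  key <- tolower(trimws(raw_label))
  if (!is.null(device)) {
    known <- unique(device$protocols$mode_raw)
    bad <- !(key %in% tolower(trimws(known)))
    if (any(bad)) {
      stop_("unknown operation mode '%s' for device '%s' (known: %s)",
            raw_label[which(bad)[1]], device$device_id,
            paste(known, collapse = ", "))
    }
  }
  mapped <- MODE_SYNONYMS[key]
  if (any(is.na(mapped))) {
    stop_("operation mode label '%s' has no normalization (known labels: %s)",
          raw_label[which(is.na(mapped))[1]],
          paste(names(MODE_SYNONYMS), collapse = ", "))
  }
  factor(unname(mapped), levels = OPERATION_MODES)
}

#' Map a referral department to a clinical indication
#'
#' The scanned anatomical region is not available from DICOM headers, so the
#' referral department stands in for the clinical indication. The mapping is
#' a user-editable two-column table (department, indication) validated
#' against the seven-category vocabulary; matching is case-insensitive after
#' trimming.
#'
#' @param department character vector of referral department names.
#' @param mapping data frame with columns `department` and `indication`
#'   (see [read_indication_map()]); defaults to the shipped example map.
#' @param unmapped `"error"` (strict, default) or `"fallback"`.
#' @param fallback indication used for unmapped departments in lenient mode.
#' @return A factor with levels `clinical_indications()`.
#' @export
map_indication <- function(department, mapping = default_indication_map(),
                           unmapped = c("error", "fallback"),
                           fallback = "second opinion radiodiagnosis") {
  unmapped <- match.arg(unmapped)
  stopifnot(fallback %in% INDICATIONS)
  key <- tolower(trimws(department))
  map_key <- tolower(trimws(mapping$department))
  hit <- match(key, map_key)
  out <- mapping$indication[hit]
  if (any(is.na(hit))) {
    if (unmapped == "error") {
      stop_("referral department '%s' is not in the indication mapping",
            department[which(is.na(hit))[1]])
    }
    out[is.na(hit)] <- fallback
  }
  factor(out, levels = INDICATIONS)
}
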