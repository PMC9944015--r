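# Reading, validating and writing the pipeline's file formats: exposure
# logs (CSV), the device registry (YAML), QC measurement files (CSV),
# conversion-factor tables (CSV, two dialects) and the department-to-
# indication map (CSV). All delimited files are comma-separated UTF-8 with
# dot decimal separators; dates are ISO-8601 only.

LOG_COLUMNS <- c(
  "exam_id", "device_id", "acquired_on", "patient_age",
  "referral_department", "operation_mode_raw", "fov_diameter_cm",
  "fov_height_cm", "tube_voltage_kv", "total_exposure_mas",
  "recorded_dap_dgycm2"
)
LOG_NUMERIC <- c("patient_age", "fov_diameter_cm", "fov_height_cm",
                 "tube_voltage_kv", "total_exposure_mas",
                 "recorded_dap_dgycm2")

#' Read and validate a CBCT exposure log
#'
#' An exposure log is a CSV emulating a DICOM-header extract, one row per
#' acquisition, with columns `exam_id, device_id, acquired_on, patient_age,
#' referral_department, operation_mode_raw, fov_diameter_cm, fov_height_cm,
#' tube_voltage_kv, total_exposure_mas, recorded_dap_dgycm2`. Duplicate
#' `exam_id`s are removed keeping the first occurrence; the number removed is
#' reported via `message()` and stored in the `n_duplicates` attribute.
#'
#' @param path path to the log CSV.
#' @param devices device registry (list of `device_profile`, see
#'   [read_device_registry()]); every `device_id` in the log must resolve.
#' @param exclude optional predicate `function(records) logical` marking
#'   non-routine acquisitions to drop (the audit's exclusion rule is
#'   site-specific, so it is user-supplied rather than guessed).
#' @return A data frame of validated exposure records with attribute
#'   `n_duplicates`.
#' @export
read_exposure_log <- function(path, devices = default_devices(),
                              exclude = NULL) {
  if (!file.exists(path)) stop_("exposure log not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(LOG_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop_("exposure log %s is missing mandatory column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  raw <- raw[LOG_COLUMNS]
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1
  for (col in LOG_NUMERIC) raw[[col]] <- check_numeric_col(raw, col, path, lines)
  raw$patient_age <- as.integer(raw$patient_age)
  raw$acquired_on <- as.Date(raw$acquired_on, format = "%Y-%m-%d")
  if (any(is.na(raw$acquired_on))) {
    stop_("unparseable ISO-8601 date in %s (line %d)", path,
          lines[which(is.na(raw$acquired_on))[1]])
  }

  known <- vapply(devices, function(d) d$device_id, character(1))
  bad <- !(raw$device_id %in% known)
  if (any(bad)) {
    stop_("unknown device_id '%s' in %s (known ids: %s)",
          raw$device_id[which(bad)[1]], path, paste(known, collapse = ", "))
  }
  if (any(raw$fov_diameter_cm <= 0) || any(raw$fov_height_cm <= 0)) {
    stop_("FOV dimensions must be positive (%s line %d)", path,
          lines[which(raw$fov_diameter_cm <= 0 | raw$fov_height_cm <= 0)[1]])
  }
  if (any(raw$total_exposure_mas <= 0)) {
    stop_("total exposure (mAs) must be positive (%s line %d)", path,
          lines[which(raw$total_exposure_mas <= 0)[1]])
  }
  if (any(raw$recorded_dap_dgycm2 < 0)) {
    stop_("recorded DAP must be non-negative (%s line %d)", path,
          lines[which(raw$recorded_dap_dgycm2 < 0)[1]])
  }

  dup <- duplicated(raw$exam_id)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    message(sprintf("removed %d duplicate examination(s) by exam_id", n_dup))
    raw <- raw[!dup, , drop = FALSE]
  }
  if (!is.null(exclude)) {
    drop <- exclude(raw)
    stopifnot(is.logical(drop), length(drop) == nrow(raw))
    raw <- raw[!drop, , drop = FALSE]
  }
  rownames(raw) <- NULL
  attr(raw, "n_duplicates") <- n_dup
  raw
}

#' Write an exposure log
#'
#' Inverse of [read_exposure_log()]: writes the records as CSV with the
#' canonical column order. Numeric fields are written at full precision so a
#' write/read round trip reproduces every field.
#'
#' @param records exposure-record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exposure_log <- function(records, path) {
  stopifnot(all(LOG_COLUMNS %in% names(records)))
  out <- records[LOG_COLUMNS]
  out$acquired_on <- format(out$acquired_on, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a device registry
#'
#' The registry is a YAML file (with a `schema_version` field) describing
#' each scanner: `device_id`, `display_name`, whether it applies tube
#' current modulation (`tcm`), its QC-derived DAP correction factor, and its
#' protocol catalog (operation mode, FOV, kV, mAs — a fixed value for
#' non-TCM devices, a `[min, max]` range under TCM — and the nominal
#' recorded DAP, a mean value for TCM devices).
#'
#' @param path path to the YAML registry.
#' @return A named list of `device_profile` objects, keyed by `device_id`.
#' @export
read_device_registry <- function(path) {
  if (!file.exists(path)) stop_("device registry not found: %s", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version)) {
    stop_("device registry %s lacks a schema_version field", path)
  }
  devices <- lapply(doc$devices, as_device_profile)
  ids <- vapply(devices, function(d) d$device_id, character(1))
  if (anyDuplicated(ids)) {
    stop_("duplicate device_id '%s' in registry", ids[duplicated(ids)][1])
  }
  names(devices) <- ids
  devices
}

as_device_profile <- function(x) {
  stopifnot(!is.null(x$device_id), !is.null(x$tcm))
  k <- as.numeric(x$dap_correction_factor)
  if (is.na(k) || k <= 0 || k > 2) {
    stop_("device '%s': dap_correction_factor must lie in (0, 2]", x$device_id)
  }
  prot <- do.call(rbind, lapply(x$protocols, function(p) {
    data.frame(
      mode_raw = p$mode_raw,
      fov_diameter_cm = as.numeric(p$fov_diameter_cm),
      fov_height_cm = as.numeric(p$fov_height_cm),
      tube_voltage_kv = as.numeric(p$tube_voltage_kv),
      mas_min = as.numeric(if (!is.null(p$total_exposure_mas)) p$total_exposure_mas else p$total_exposure_mas_min),
      mas_max = as.numeric(if (!is.null(p$total_exposure_mas)) p$total_exposure_mas else p$total_exposure_mas_max),
      nominal_recorded_dap_dgycm2 = as.numeric(p$nominal_recorded_dap_dgycm2),
      stringsAsFactors = FALSE
    )
  }))
  if (!isTRUE(x$tcm) && any(prot$mas_min != prot$mas_max)) {
    stop_("device '%s' is non-TCM: total_exposure_mas must be a single fixed value per protocol",
          x$device_id)
  }
  structure(
    list(device_id = x$device_id,
         display_name = if (!is.null(x$display_name)) x$display_name else x$device_id,
         tcm = isTRUE(x$tcm),
         dap_correction_factor = k,
         protocols = prot),
    class = "device_profile"
  )
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf("<device_profile> %s (%s)\n", x$device_id, x$display_name))
  cat(sprintf("  TCM: %s; DAP correction factor k = %g\n", x$tcm,
              x$dap_correction_factor))
  cat(sprintf("  %d protocol(s)\n", nrow(x$protocols)))
  invisible(x)
}

#' Shipped default device registry
#'
#' The two scanners of the audited imaging centre: a Morita 3D Accuitomo 170
#' (fixed exposure per protocol, DAP correction factor 0.76) and a Newtom
#' VGI EVO (tube current modulation, accurate displayed DAP, factor 1.0),
#' with their clinical protocol catalogs.
#'
#' @return A named list of `device_profile` objects.
#' @export
default_devices <- function() {
  read_device_registry(system.file("extdata", "devices.yaml",
                                   package = "cbctdose", mustWork = TRUE))
}

#' Read a conversion-factor table
#'
#' Two dialects exist, distinguished by their columns. The per-mAs dialect
#' (`device, indication, age_years, cf_usv_per_mas`) carries indication- and
#' age-specific factors in uSv per unit tube loading, as produced by Monte
#' Carlo organ-dose studies. The per-DAP dialect (`device, age_group,
#' cf_usv_per_dapcm2`) carries the age-group-averaged factors in
#' uSv/(dGy.cm2) that the dose engine consumes; it must cover all four age
#' groups for every device present.
#'
#' @param path path to the CSV.
#' @return A `cf_table` data frame with attribute `dialect` (`"per_mas"` or
#'   `"per_dap"`).
#' @export
read_cf_table <- function(path) {
  if (!file.exists(path)) stop_("CF table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  per_mas_cols <- c("device", "indication", "age_years", "cf_usv_per_mas")
  per_dap_cols <- c("device", "age_group", "cf_usv_per_dapcm2")
  has_mas <- all(per_mas_cols %in% names(df))
  has_dap <- all(per_dap_cols %in% names(df))
  if (has_mas && has_dap) stop_("CF table %s mixes per_mas and per_dap dialects", path)
  if (!has_mas && !has_dap) {
    stop_("CF table %s matches neither dialect (need columns %s or %s)",
          path, paste(per_mas_cols, collapse = ","),
          paste(per_dap_cols, collapse = ","))
  }
  if (has_mas) {
    df <- df[per_mas_cols]
    df$age_years <- as.integer(df$age_years)
    df$cf_usv_per_mas <- as.numeric(df$cf_usv_per_mas)
    if (any(df$cf_usv_per_mas <= 0) || any(is.na(df$cf_usv_per_mas))) {
      stop_("per_mas CF values must be positive")
    }
    return(structure(df, dialect = "per_mas", class = c("cf_table", "data.frame")))
  }
  df <- df[per_dap_cols]
  df$cf_usv_per_dapcm2 <- as.numeric(df$cf_usv_per_dapcm2)
  if (any(df$cf_usv_per_dapcm2 <= 0) || any(is.na(df$cf_usv_per_dapcm2))) {
    stop_("per_dap CF values must be positive")
  }
  bad_grp <- setdiff(unique(df$age_group), AGE_GROUPS)
  if (length(bad_grp) > 0) {
    stop_("unknown age group '%s' in CF table (expected: %s)", bad_grp[1],
          paste(AGE_GROUPS, collapse = ", "))
  }
  for (dev in unique(df$device)) {
    gap <- setdiff(AGE_GROUPS, df$age_group[df$device == dev])
    if (length(gap) > 0) {
      stop_("per_dap CF table does not cover age group(s) %s for device '%s'",
            paste(gap, collapse = ", "), dev)
    }
    if (anyDuplicated(df$age_group[df$device == dev])) {
      stop_("duplicate (device, age_group) CF entry for device '%s'", dev)
    }
  }
  structure(df, dialect = "per_dap", class = c("cf_table", "data.frame"))
}

#' @export
print.cf_table <- function(x, ...) {
  cat(sprintf("<cf_table> dialect: %s, %d entries\n", attr(x, "dialect"), nrow(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Shipped per-DAP conversion-factor table
#'
#' The working default: effective dose conversion factors in uSv/(dGy.cm2)
#' per device and age group for the two shipped scanners, so the dose engine
#' works out of the box.
#'
#' @return A `cf_table` with dialect `"per_dap"`.
#' @export
default_cf_table <- function() {
  read_cf_table(system.file("extdata", "cf_per_dap_default.csv",
                            package = "cbctdose", mustWork = TRUE))
}

#' Look up a per-DAP conversion factor
#'
#' @param cf_table a per-DAP `cf_table`.
#' @param device_id scanner id.
#' @param age_group vector of age-group labels (see [age_groups()]).
#' @return Numeric vector of conversion factors in uSv/(dGy.cm2).
#' @export
cf_lookup <- function(cf_table, device_id, age_group) {
  stopifnot(identical(attr(cf_table, "dialect"), "per_dap"))
  key <- paste(device_id, as.character(age_group))
  tab_key <- paste(cf_table$device, cf_table$age_group)
  hit <- match(key, tab_key)
  if (any(is.na(hit) & !is.na(age_group))) {
    miss <- which(is.na(hit) & !is.na(age_group))[1]
    stop_("no CF coverage for (device '%s', age group '%s')",
          device_id[min(miss, length(device_id))], as.character(age_group)[miss])
  }
  cf_table$cf_usv_per_dapcm2[hit]
}

#' Read a QC measurement file
#'
#' CSV with columns `device_id, fov_label, measured_dap_dgycm2,
#' recorded_dap_dgycm2` — one row per annual quality-control DAP measurement
#' (phantom-free DAP-meter reading vs the value displayed by the scanner).
#'
#' @param path path to the CSV.
#' @return A data frame of QC measurements.
#' @export
read_qc_file <- function(path) {
  if (!file.exists(path)) stop_("QC file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("device_id", "fov_label", "measured_dap_dgycm2", "recorded_dap_dgycm2")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop_("QC file %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  df$measured_dap_dgycm2 <- as.numeric(df$measured_dap_dgycm2)
  df$recorded_dap_dgycm2 <- as.numeric(df$recorded_dap_dgycm2)
  if (any(df$measured_dap_dgycm2 <= 0) || any(df$recorded_dap_dgycm2 <= 0)) {
    stop_("QC DAP values must be strictly positive (%s)", path)
  }
  df[need]
}

#' Read a department-to-indication map
#'
#' Two-column CSV (`department, indication`); indications are validated
#' against the seven-category vocabulary `clinical_indications()`.
#'
#' @param path path to the CSV.
#' @return A data frame with columns `department` and `indication`.
#' @export
read_indication_map <- function(path) {
  if (!file.exists(path)) stop_("indication map not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("department", "indication") %in% names(df))) {
    stop_("indication map %s needs columns: department, indication", path)
  }
  bad <- setdiff(unique(df$indication), INDICATIONS)
  if (length(bad) > 0) {
    stop_("indication '%s' is not in the seven-category vocabulary", bad[1])
  }
  df[c("department", "indication")]
}

#' @rdname read_indication_map
#' @export
default_indication_map <- function() {
  read_indication_map(system.file("extdata", "indication_map.csv",
                                  package = "cbctdose", mustWork = TRUE))
}
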