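# Aggregation and reporting: the stratified dose table (device x age group x
# FOV category x mode with means and 95% CIs), the indication frequency
# tables, and the headline ratios quoted in a dose audit.

# normal-approximation 95% CI on a mean; NA for singleton strata
ci_normal <- function(mean, sd, n, z = 1.96) {
  half <- ifelse(n >= 2, z * sd / sqrt(n), NA_real_)
  cbind(lo = mean - half, hi = mean + half)
}

#' Stratified DAP and dose summary
#'
#' Groups dose results by the requested fields (default: device, age group,
#' FOV category, operation mode) and reports per stratum the examination
#' count, frequency percentage relative to the device total, the mean
#' corrected DAP and mean effective dose, and their 95% confidence intervals
#' `mean +/- 1.96 x sd / sqrt(n)` (sample sd, n - 1 denominator). CIs are
#' absent (`NA`) for singleton strata.
#'
#' @param doses a `dose_results` data frame ([compute_doses()]).
#' @param by character vector of grouping columns.
#' @return A `stratum_summary` data frame with columns `by`, `n`,
#'   `freq_pct`, `mean_dap`, `dap_lo`, `dap_hi`, `mean_dose`, `dose_lo`,
#'   `dose_hi`, ordered by the grouping fields.
#' @export
summarize_strata <- function(doses, by = c("device_id", "age_group",
                                           "fov_category", "mode")) {
  stopifnot(is.data.frame(doses))
  if (nrow(doses) == 0) stop_("cannot summarize zero dose results")
  bad <- setdiff(by, names(doses))
  if (length(bad) > 0) stop_("unknown grouping field(s): %s", paste(bad, collapse = ", "))

  grp <- interaction(doses[by], drop = TRUE, sep = "\r")
  split_idx <- split(seq_len(nrow(doses)), grp)
  rows <- lapply(split_idx, function(idx) {
    d <- doses[idx, , drop = FALSE]
    n <- nrow(d)
    m_dap <- mean(d$corrected_dap_dgycm2)
    m_dose <- mean(d$effective_dose_usv)
    ci_dap <- ci_normal(m_dap, stats::sd(d$corrected_dap_dgycm2), n)
    ci_dose <- ci_normal(m_dose, stats::sd(d$effective_dose_usv), n)
    cbind(d[1, by, drop = FALSE],
          data.frame(n = n, freq_pct = NA_real_, mean_dap = m_dap,
                     dap_lo = ci_dap[, "lo"], dap_hi = ci_dap[, "hi"],
                     mean_dose = m_dose,
                     dose_lo = ci_dose[, "lo"], dose_hi = ci_dose[, "hi"]))
  })
  out <- do.call(rbind, rows)
  if ("device_id" %in% by) {
    dev_total <- table(doses$device_id)
    out$freq_pct <- 100 * out$n / as.numeric(dev_total[out$device_id])
  } else {
    out$freq_pct <- 100 * out$n / nrow(doses)
  }
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stratum_summary", class(out))
  out
}

#' Collective dose reconstructed from a stratum summary
#'
#' The reconstruction identity: the sum over strata of `n x mean dose`
#' equals the cohort's collective dose. Useful when only a published summary
#' table is available rather than patient-level data.
#'
#' @param summary a `stratum_summary`, or any data frame with columns `n`
#'   and `mean_dose` (uSv).
#' @return Collective effective dose in manSv.
#' @export
collective_dose_from_summary <- function(summary) {
  stopifnot(all(c("n", "mean_dose") %in% names(summary)))
  sum(summary$n * summary$mean_dose) * 1e-6
}

#' Protocol-level dose summary for a fixed-exposure device
#'
#' A device without tube current modulation delivers the same DAP to every
#' patient scanned with a given protocol, so its dose table needs no patient
#' log: per (FOV category, operation mode) cell the mean corrected DAP is
#' the unweighted mean over the protocols in the cell, and the effective
#' dose per age group is that mean times the age group's conversion factor.
#'
#' @param device a non-TCM `device_profile`.
#' @param cf_table per-DAP `cf_table`.
#' @param correction DAP correction factor k; defaults to the profile's.
#' @return Data frame `device_id, age_group, fov_category, mode, n_protocols,
#'   mean_dap, mean_dose` (full precision; use [display_3sf()] to display).
#' @export
protocol_dose_summary <- function(device, cf_table = default_cf_table(),
                                  correction = device$dap_correction_factor) {
  stopifnot(inherits(device, "device_profile"))
  if (device$tcm) {
    stop_("device '%s' applies TCM: protocol summaries need a patient log (use compute_doses + summarize_strata)",
          device$device_id)
  }
  if (inherits(correction, "dap_correction")) correction <- correction$factor
  prot <- device$protocols
  prot$fov_category <- classify_fov(prot$fov_diameter_cm, prot$fov_height_cm)
  prot$mode <- normalize_mode(prot$mode_raw, device)
  prot$dap_corr <- apply_correction(prot$nominal_recorded_dap_dgycm2, correction)

  cells <- unique(prot[c("fov_category", "mode")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- prot$fov_category == cells$fov_category[i] & prot$mode == cells$mode[i]
    m_dap <- mean(prot$dap_corr[sel])
    cf <- cf_lookup(cf_table, device$device_id, AGE_GROUPS)
    data.frame(device_id = device$device_id,
               age_group = factor(AGE_GROUPS, levels = AGE_GROUPS),
               fov_category = cells$fov_category[i],
               mode = cells$mode[i],
               n_protocols = sum(sel),
               mean_dap = m_dap,
               mean_dose = effective_dose(m_dap, cf),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$age_group, out$fov_category, out$mode), ]
  rownames(out) <- NULL
  out
}

#' Indication frequency tables
#'
#' The audit's request-pattern surfaces: percentage of imaging requests per
#' clinical indication crossed with age group, FOV category, and operation
#' mode (percentages relative to the combined total of examinations), the
#' marginal mode and FOV frequencies, and the per-age-group indication
#' profile (percentages within each age group, combining devices).
#'
#' @param doses a `dose_results` data frame.
#' @return A list of class `cbct_frequencies`: matrices
#'   `indication_by_age`, `indication_by_fov`, `indication_by_mode` (cells
#'   sum to 100 per table), named vectors `mode_freq` and `fov_freq`
#'   (marginal percentages), and matrix `indication_within_age` (columns sum
#'   to 100).
#' @export
frequency_tables <- function(doses) {
  stopifnot(is.data.frame(doses))
  if (nrow(doses) == 0) stop_("cannot tabulate zero dose results")
  n <- nrow(doses)
  pct_of_total <- function(tab) 100 * unclass(tab) / n
  pct_vec <- function(tab) stats::setNames(100 * as.numeric(tab) / n, names(tab))
  by_age <- pct_of_total(table(doses$indication, doses$age_group))
  by_fov <- pct_of_total(table(doses$indication, doses$fov_category))
  by_mode <- pct_of_total(table(doses$indication, doses$mode))
  within_age <- 100 * prop.table(table(doses$indication, doses$age_group),
                                 margin = 2)
  structure(
    list(indication_by_age = by_age,
         indication_by_fov = by_fov,
         indication_by_mode = by_mode,
         indication_within_age = unclass(within_age),
         mode_freq = pct_vec(table(doses$mode)),
         fov_freq = pct_vec(table(doses$fov_category)),
         age_freq = pct_vec(table(doses$age_group)),
         n_total = n),
    class = "cbct_frequencies"
  )
}

#' @export
print.cbct_frequencies <- function(x, digits = 1, ...) {
  cat(sprintf("<cbct_frequencies> %d examinations\n", x$n_total))
  cat("mode frequencies [%]:\n")
  print(round(x$mode_freq, digits))
  cat("FOV category frequencies [%]:\n")
  print(round(x$fov_freq, digits))
  invisible(x)
}

#' Headline ratios of a dose audit
#'
#' The quotable ratios: (a) standard:HR request ratio from the marginal mode
#' frequencies; (b) medium:large FOV request ratio; (c) per-device HR:standard
#' mean-dose ratio for every (age group, FOV category) stratum where both
#' modes exist; (d) cross-device standard-mode mean-dose ratio for matching
#' strata. All ratios are rounded to 1 decimal for display. Ratios whose
#' strata are missing are omitted with a warning.
#'
#' @param summary a `stratum_summary` grouped by device, age group, FOV
#'   category and mode.
#' @param freq a `cbct_frequencies` object.
#' @return A list: scalars `standard_to_hr_requests` and
#'   `medium_to_large_requests`, and data frames `hr_to_standard_dose` (per
#'   device/age/FOV) and `cross_device_standard_dose` (per age/FOV, first
#'   device over second in registry order).
#' @export
headline_ratios <- function(summary, freq) {
  ratio1 <- function(a, b) round(a / b, 1)
  std_hr <- if (all(c("standard", "HR") %in% names(freq$mode_freq)) &&
                freq$mode_freq[["HR"]] > 0) {
    ratio1(freq$mode_freq[["standard"]], freq$mode_freq[["HR"]])
  } else {
    warning("HR mode stratum missing: standard:HR request ratio omitted")
    NA_real_
  }
  med_lg <- if (all(c("medium", "large") %in% names(freq$fov_freq)) &&
                freq$fov_freq[["large"]] > 0) {
    ratio1(freq$fov_freq[["medium"]], freq$fov_freq[["large"]])
  } else {
    warning("large FOV stratum missing: medium:large request ratio omitted")
    NA_real_
  }

  key <- paste(summary$device_id, summary$age_group, summary$fov_category)
  hr <- summary[summary$mode == "HR", , drop = FALSE]
  std <- summary[summary$mode == "standard", , drop = FALSE]
  hit <- match(paste(hr$device_id, hr$age_group, hr$fov_category),
               paste(std$device_id, std$age_group, std$fov_category))
  hr_std <- data.frame(device_id = hr$device_id, age_group = hr$age_group,
                       fov_category = hr$fov_category,
                       ratio = ratio1(hr$mean_dose, std$mean_dose[hit]))
  hr_std <- hr_std[!is.na(hr_std$ratio), , drop = FALSE]

  devs <- unique(summary$device_id)
  cross <- NULL
  if (length(devs) >= 2) {
    a <- std[std$device_id == devs[1], , drop = FALSE]
    b <- std[std$device_id == devs[2], , drop = FALSE]
    hit2 <- match(paste(a$age_group, a$fov_category),
                  paste(b$age_group, b$fov_category))
    cross <- data.frame(age_group = a$age_group, fov_category = a$fov_category,
                        numerator = devs[1], denominator = devs[2],
                        ratio = ratio1(a$mean_dose, b$mean_dose[hit2]))
    cross <- cross[!is.na(cross$ratio), , drop = FALSE]
  }
  list(standard_to_hr_requests = std_hr,
       medium_to_large_requests = med_lg,
       hr_to_standard_dose = hr_std,
       cross_device_standard_dose = cross)
}

#' Write a report bundle
#'
#' Writes one CSV per summary surface (stratified dose table, indication
#' frequency tables, per-age indication profile) plus a JSON file with the
#' headline ratios and collective dose.
#'
#' @param doses a `dose_results` data frame.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(doses, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- summarize_strata(doses)
  freq <- frequency_tables(doses)
  ratios <- headline_ratios(summ, freq)
  files <- c(
    table5_dose_summary = file.path(out_dir, "table5_dose_summary.csv"),
    table3_fov_freq = file.path(out_dir, "table3_fov_freq.csv"),
    table4_mode_freq = file.path(out_dir, "table4_mode_freq.csv"),
    fig2_indication_by_age = file.path(out_dir, "fig2_indication_by_age.csv"),
    headline = file.path(out_dir, "headline.json")
  )
  disp <- summ
  num <- c("mean_dap", "dap_lo", "dap_hi", "mean_dose", "dose_lo", "dose_hi")
  disp[num] <- lapply(disp[num], display_3sf)
  disp$freq_pct <- round(disp$freq_pct, 1)
  utils::write.csv(disp, files["table5_dose_summary"], row.names = FALSE, na = "-")
  utils::write.csv(round(freq$indication_by_fov, 1), files["table3_fov_freq"])
  utils::write.csv(round(freq$indication_by_mode, 1), files["table4_mode_freq"])
  utils::write.csv(round(freq$indication_within_age, 1),
                   files["fig2_indication_by_age"])
  jsonlite::write_json(
    list(collective_dose_mansv = collective_dose(doses),
         n_examinations = nrow(doses),
         standard_to_hr_requests = ratios$standard_to_hr_requests,
         medium_to_large_requests = ratios$medium_to_large_requests,
         hr_to_standard_dose = ratios$hr_to_standard_dose,
         cross_device_standard_dose = ratios$cross_device_standard_dose),
    files["headline"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}

#' Plot the per-age-group indication profile
#'
#' Stacked bar chart of the percentage of imaging requests per clinical
#' indication within each age group (devices combined).
#'
#' @param freq a `cbct_frequencies` object.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the matrix plotted.
#' @export
plot_indication_profile <- function(freq, ...) {
  stopifnot(inherits(freq, "cbct_frequencies"))
  m <- freq$indication_within_age
  graphics::barplot(m, legend.text = rownames(m),
                    ylab = "share of examinations per age group [%]",
                    xlab = "age group",
                    col = grDevices::hcl.colors(nrow(m), "Spectral"), ...)
  invisible(m)
}
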