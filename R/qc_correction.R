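# QC-based DAP correction: scanners may display inaccurate dose-area-product
# values; annual QC measurements with a calibrated DAP meter give, per
# device, a set of measured/recorded ratios whose mean is the correction
# factor k applied to every recorded DAP before dose conversion.

#' Derive a DAP correction factor from QC measurements
#'
#' The factor k for a device is the arithmetic mean of the ratios
#' measured/recorded over all pooled QC measurement pairs (campaigns are
#' pooled per-measurement, not weighted per-campaign). The maximum relative
#' deviation of any single ratio from k is reported, and flagged as a
#' warning-level condition when it exceeds 5%.
#'
#' @param measurements data frame of QC pairs for one device, with columns
#'   `measured_dap_dgycm2` and `recorded_dap_dgycm2` (and optionally
#'   `device_id`, which must then be constant).
#' @return A `dap_correction` list: `device_id`, `factor` (k),
#'   `per_measurement_ratios`, `max_relative_deviation`, `deviation_flagged`.
#' @examples
#' qc <- data.frame(measured_dap_dgycm2 = c(3.0, 6.0, 1.5),
#'                  recorded_dap_dgycm2 = c(4.0, 8.0, 2.0))
#' derive_correction_factor(qc)$factor  # 0.75
#' @export
derive_correction_factor <- function(measurements) {
  stopifnot(is.data.frame(measurements))
  if (nrow(measurements) == 0) {
    stop_("cannot derive a correction factor from zero QC measurements")
  }
  dev <- unique(measurements$device_id)
  if (length(dev) > 1) {
    stop_("QC measurements span several devices (%s); derive one factor per device",
          paste(dev, collapse = ", "))
  }
  m <- measurements$measured_dap_dgycm2
  r <- measurements$recorded_dap_dgycm2
  if (any(r <= 0)) {
    stop_("non-positive recorded DAP in QC measurement %d",
          which(r <= 0)[1])
  }
  if (any(m <= 0)) {
    stop_("non-positive measured DAP in QC measurement %d", which(m <= 0)[1])
  }
  ratios <- m / r
  k <- mean(ratios)
  max_dev <- max(abs(ratios - k)) / k
  structure(
    list(device_id = if (length(dev) == 1) dev else NA_character_,
         factor = k,
         per_measurement_ratios = ratios,
         max_relative_deviation = max_dev,
         deviation_flagged = max_dev > 0.05),
    class = "dap_correction"
  )
}

#' @export
print.dap_correction <- function(x, ...) {
  cat(sprintf("<dap_correction>%s k = %.4f (n = %d QC pairs)\n",
              if (!is.na(x$device_id)) paste0(" ", x$device_id) else "",
              x$factor, length(x$per_measurement_ratios)))
  cat(sprintf("  ratios: %s\n", paste(round(x$per_measurement_ratios, 4),
                                      collapse = ", ")))
  cat(sprintf("  max relative deviation: %.2f%%%s\n",
              100 * x$max_relative_deviation,
              if (x$deviation_flagged) "  [exceeds 5% - review QC data]" else ""))
  invisible(x)
}

#' Apply a DAP correction factor
#'
#' Multiplies recorded DAP values by the dimensionless factor k at full
#' precision; rounding to 3 significant figures is a display concern only
#' (see [display_3sf()]). Intermediate values in the dose chain are never
#' rounded.
#'
#' @param recorded_dap numeric vector of recorded DAP values, dGy.cm2 (>= 0).
#' @param factor correction factor k (> 0), or a `dap_correction` object.
#' @return Corrected DAP in dGy.cm2.
#' @examples
#' apply_correction(4.02, 0.76)              # 3.0552
#' display_3sf(apply_correction(4.02, 0.76)) # 3.06
#' @export
apply_correction <- function(recorded_dap, factor) {
  if (inherits(factor, "dap_correction")) factor <- factor$factor
  if (any(is.na(recorded_dap)) || any(recorded_dap < 0)) {
    stop_("recorded DAP must be non-negative")
  }
  if (!is.numeric(factor) || any(factor <= 0)) {
    stop_("correction factor must be positive")
  }
  recorded_dap * factor
}
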