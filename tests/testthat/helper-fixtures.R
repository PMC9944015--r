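# In-code fixtures shared across test files.

log_header <- paste(
  "exam_id", "device_id", "acquired_on", "patient_age",
  "referral_department", "operation_mode_raw", "fov_diameter_cm",
  "fov_height_cm", "tube_voltage_kv", "total_exposure_mas",
  "recorded_dap_dgycm2", sep = ",")

# one CSV line per record; fields in canonical column order
write_log_lines <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(c(log_header, lines), file)
  file
}

acc_row <- function(id, age = 30, mode = "Standard", d = 4, h = 4,
                    mas = 87.5, dap = 4.02, dept = "radiology") {
  sprintf('%s,accuitomo170,2019-03-01,%d,%s,%s,%g,%g,90,%g,%g',
          id, age, dept, mode, d, h, mas, dap)
}

newtom_row <- function(id, age = 30, mode = "Regular scan", d = 10, h = 10,
                       mas = 20, dap = 3.1, dept = "oral and maxillofacial surgery") {
  sprintf('%s,newtom_vgi_evo,2019-03-01,%d,%s,%s,%g,%g,110,%g,%g',
          id, age, dept, mode, d, h, mas, dap)
}

# tiny single-protocol non-TCM device for closed-form CF checks
tiny_device <- function(mas = 87.5, dap = 4.02, k = 0.76) {
  reg <- tempfile(fileext = ".yaml")
  writeLines(sprintf(
    "schema_version: 1\ndevices:\n  - device_id: tiny\n    tcm: false\n    dap_correction_factor: %.17g\n    protocols:\n      - {mode_raw: Standard, fov_diameter_cm: 4, fov_height_cm: 4, tube_voltage_kv: 90, total_exposure_mas: %.17g, nominal_recorded_dap_dgycm2: %.17g}",
    k, mas, dap), reg)
  read_device_registry(reg)[["tiny"]]
}
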