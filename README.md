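# cbctdose

Patient dose monitoring for dental cone-beam CT (CBCT).

Hospitals that run CBCT scanners accumulate exposure logs — DICOM-header
extracts with the operation mode, field of view (FOV), tube loading and the
scanner-recorded dose-area product (DAP) of every acquisition. `cbctdose`
turns such logs into an auditable effective-dose overview for medical
physicists and radiology QA teams:

1. **QC-based DAP correction.** Displayed DAP values on dental systems can
   be off by tens of percent. From annual QC pairs of (measured, recorded)
   DAP the package derives a per-device correction factor
   *k* = mean(measured/recorded) and applies it to every record, flagging
   devices whose single-measurement deviations exceed 5%.
2. **Conversion-factor derivation.** Published effective-dose conversion
   factors are indication- and age-specific, in µSv/mAs. A header-driven
   monitoring system can only apply one DAP-based factor per device and age
   group, so the package averages the per-mAs factors over linked
   indications and integer ages, pushes them through the exposure chain
   (`dose = CF(FOV) × mAs`, `ratio = dose / DAP_corrected`) and averages the
   per-exam (or per-protocol) ratios into CF_E in µSv/(dGy·cm²), with a
   relative-error validation of what the averaging costs.
3. **Dose engine.** Per examination, `E = CF_E × DAP_corrected` (µSv), with
   collective dose Σ E in manSv.
4. **Stratified reporting.** Summaries by device × age group (4–6, 7–11,
   12–14, ≥15 y) × FOV category (small < 40 cm², medium 40–100 cm², large
   > 100 cm²) × operation mode (standard / HR), with normal-approximation
   95% CIs, indication frequency tables and headline ratios.
5. **Synthetic cohorts.** A generator emulating both scanner types — fixed
   exposure per protocol, and tube-current-modulated (TCM) with log-normal
   patient-varying DAP — so the whole pipeline is testable without patient
   data.

Two device profiles ship with the package (a fixed-exposure 3D Accuitomo
170 with *k* = 0.76 and a TCM Newtom VGI EVO with accurate displayed DAP),
together with their per-DAP conversion-factor table.

## Worked example

```r
library(cbctdose)

# a fixed-exposure scanner needs no patient log: its dose table follows
# from the protocol catalog, k, and the conversion factors
acc <- default_devices()[["accuitomo170"]]
ps  <- protocol_dose_summary(acc)
subset(ps, age_group == ">=15y" & mode == "standard",
       select = c(fov_category, mean_dap, mean_dose)) |>
  transform(mean_dap = display_3sf(mean_dap), mean_dose = display_3sf(mean_dose))
#>    fov_category mean_dap mean_dose
#> 13        small     4.66      35.1
#> 14       medium    10.50      79.0
#> 15        large    18.00     136.0

# a TCM scanner needs patient-level records; here a synthetic cohort with
# the audited composition (4967 exams)
log   <- synthesize_cohort(default_tcm_spec(), seed = 42)
doses <- compute_doses(log)$doses
round(collective_dose(doses), 3)
#> [1] 0.222
```

Reading: an adult small-FOV standard scan on the fixed-exposure device
delivers a mean corrected DAP of 4.66 dGy·cm² and an effective dose of
35.1 µSv; the synthetic TCM cohort's collective dose is 0.222 manSv (about
the yearly dose footprint of that scanner's workload).

`summarize_strata(doses)` gives the full stratified table with 95% CIs,
`frequency_tables(doses)` the indication request patterns, and
`write_report(doses, "out/")` a CSV/JSON report bundle. A thin CLI wrapper
lives in `inst/scripts/cbctdose.R`.

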