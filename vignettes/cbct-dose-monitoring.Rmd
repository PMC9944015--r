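---
title: "Methods: CBCT patient dose monitoring with cbctdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CBCT patient dose monitoring with cbctdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctdose)
```

## The dose model

`cbctdose` estimates the effective dose of a dental cone-beam CT
examination from quantities available in the image DICOM header. The chain
is deliberately simple and fully deterministic:

$$E = \mathrm{CF}_E \times \mathrm{DAP}_{\mathrm{corrected}}, \qquad
  \mathrm{DAP}_{\mathrm{corrected}} = k \times \mathrm{DAP}_{\mathrm{recorded}}$$

with $E$ in µSv, the dose-area product (DAP) in dGy·cm², the conversion
factor $\mathrm{CF}_E$ in µSv/(dGy·cm²) specific to the device and the
patient's age group, and $k$ a dimensionless, device-specific DAP
correction factor. Collective dose is the plain sum of individual doses,
expressed in manSv ($10^6$ µSv).

The model's assumptions are inherited from its inputs: $\mathrm{CF}_E$
absorbs everything anatomical (organ fractions in the beam, patient size),
so it must come from age-resolved dosimetry of the same device class, and a
single factor per (device, age group) necessarily averages over clinical
indications — the error this introduces is quantified, not ignored (see
*Conversion-factor derivation*).

## DAP correction ($k$)

Displayed DAP values on dental X-ray systems are frequently inaccurate.
Annual QC campaigns measure DAP with a calibrated meter for a small, a
medium and a large standard-protocol FOV; campaigns are pooled
per-measurement (not weighted per-campaign) and

$$k = \frac{1}{n}\sum_i \frac{\mathrm{DAP}^{\mathrm{meas}}_i}
                              {\mathrm{DAP}^{\mathrm{rec}}_i}.$$

`derive_correction_factor()` also reports the largest relative deviation of
any single ratio from $k$ and flags (as a warning, never a failure) when it
exceeds 5% — at that point a single pooled factor is a questionable summary
of the device's behaviour. A device whose display is accurate simply gets
$k = 1$ and the correction is the identity. The shipped fixed-exposure
profile carries $k = 0.76$; the TCM profile $k = 1.0$.

A consequence worth stating explicitly: **intermediate values are never
rounded**. The corrected DAP 21.7 × 0.76 = 16.492 enters downstream means
as 16.492, not 16.5; only report surfaces round, to 3 significant figures
(`display_3sf()`). Several published-table values are reproducible only
under this convention.

## Classification axes

* **Age groups** 4–6, 7–11, 12–14, ≥15 years, the resolution at which the
  conversion factors exist. Adults use the 15-year factors (head
  circumference changes little after 15). Ages **below 4 are rejected**,
  not extrapolated — no factor covers them; `compute_doses()` routes such
  records to a rejects report rather than dropping them silently.
* **FOV categories** by the area product diameter × height: small
  < 40 cm², medium 40–100 cm² (both ends included), large > 100 cm². The
  40 cm² boundary (the 8 × 5 FOV) is deliberately placed in *medium*,
  matching how such FOVs are grouped in practice; the package treats this
  as the authoritative convention even though "small ≤ 40" also circulates.
* **Operation modes** normalized to `standard` (standard / regular scan)
  and `HR` (high-fidelity / high-resolution), case-insensitively, because
  the vendor-native labels play equivalent dose/image-quality roles.
* **Clinical indication** is a lookup from the referral department
  (the scanned region is not in the header), against a user-editable
  seven-category map; strict by default, with an optional fallback
  category.

## Conversion-factor derivation

Published CFs are per unit tube loading (µSv/mAs), resolved by anatomical
indication and integer age (5–15 y). Converting them to per-DAP factors
proceeds in two steps per device and age group:

1. **Averaging onto FOVs.** Each FOV is linked to the indications scanned
   with it; the per-FOV factor is the *unweighted* arithmetic mean over all
   linked indications and all integer ages inside the group. Unweighted,
   because no defensible patient-frequency weights exist at derivation
   time.
2. **Through the exposure chain.** Per examination (TCM device) or per
   protocol (fixed-exposure device), $E_{\mathrm{mAs}} = \mathrm{CF(FOV)}
   \times \mathrm{mAs}$ and the ratio $E_{\mathrm{mAs}} /
   \mathrm{DAP}_{\mathrm{corrected}}$ is formed; $\mathrm{CF}_E$ is the
   unweighted mean of these ratios. For a single-protocol device this
   collapses to the closed form $\mathrm{CF}_E = \mathrm{cf} \times
   \mathrm{mAs} / (\mathrm{DAP} \times k)$, which the tests exploit.
   Per-exam ratios are averaged directly (not per-FOV-then-pooled); with
   TCM the DAP varies per patient, so only per-exam averaging is faithful.

`validate_cf()` quantifies the cost of averaging: per-exam relative
deviation $|E_{\mathrm{DAP}} - E_{\mathrm{mAs}}| / E_{\mathrm{mAs}}$, its
mean, and the fraction of examinations within 20% — **inclusive** at the
boundary (a deviation of exactly 0.20 counts as within). No pass/fail
threshold is imposed; the statistics are descriptive.

The genuine per-mAs tables are third-party Monte Carlo results and are not
redistributed; the package ships a clearly labelled synthetic example
(`cf_per_mas_synthetic.csv`, plausible magnitudes only) to exercise the
workflow, and the derived per-DAP table for the two shipped devices as the
working default, so the dose engine runs out of the box.

## Aggregation and reporting

`summarize_strata()` reports, per device × age group × FOV category × mode:
count, frequency percentage relative to the device total, mean corrected
DAP, mean dose, and 95% confidence intervals
$\bar{x} \pm 1.96\, s / \sqrt{n}$ with the $n-1$ sample standard deviation.
The CI method is the normal approximation on the standard error — singleton
strata show no interval, which is the only behaviour observable in typical
published tables; the choice is isolated in one internal function so a
t-based variant is a one-line swap. The reconstruction identity
$\sum_{\text{strata}} n \times \overline{E} = \text{collective dose}$
holds exactly and is tested.

Display conventions mirror audit tables: 3 significant figures for doses
and DAP, 1 decimal for percentages and ratios. One reported ratio —
medium:large FOV requests — is known to be sensitive to upstream rounding
of the frequency table it is computed from; it is reported but not treated
as a validation quantity.

## The synthetic cohort generator

`synthesize_cohort()` exists because no patient-level CBCT dose data are
publicly deposited. It emulates exactly the two behaviours the pipeline
must distinguish:

* **Fixed-exposure device** — records carry the protocol's exact mAs and
  nominal recorded DAP; all randomness is in which protocol/age/indication
  a record gets.
* **TCM device** — recorded DAP is drawn from a log-normal with a
  stratum-specific target mean and coefficient of variation (DAP is
  positive and right-skewed under patient-size variation), and mAs is
  uniform within the protocol's modulation range.

A `cohort_spec` is a joint stratum table (age group × mode × FOV with
occupancy probability, target DAP mean and CV) plus an indication mix per
age group. This single joint table is an equivalent factorisation of
age-mix / indication-mix / FOV-mode-mix kept separately; it makes the
target composition auditable at a glance.

Defaults are the study conditions, not dials. `default_tcm_spec()` encodes
the audited TCM cohort: 4967 examinations over 19 strata with the audited
per-stratum counts as probabilities and the audited mean corrected DAPs as
targets; each FOV category is represented by its most used FOV (5 × 5,
10 × 10, 24 × 19). The DAP coefficient of variation defaults to 0.25,
chosen once so that synthetic stratum CI widths are of the same order as
audited ones (the large adult medium-standard stratum implies a CV near
0.25; dispersion is only indirectly constrained, and no claim is made that
it matches any particular clinic). `default_fixed_spec()` covers the
fixed-exposure scanner with 196 examinations; its per-stratum usage was
never published, so the mix is a package choice: adult-dominated (88%),
medium FOVs most frequent, HR only on large FOVs, mirroring how such a
scanner is used alongside a TCM workhorse. Allocation is **exact** by
default (largest-remainder rounding of $n p_i$, so composition is a fixed
study condition and only exposures are stochastic); `"multinomial"`
allocation is available and is what the sampling-variability tests use. A
single integer seed drives each generation and the caller's RNG state is
restored afterwards.

What passing tests on synthetic cohorts show — and what they do not: they
verify the pipeline's arithmetic, classification, aggregation and
parameter-recovery behaviour under the assumed log-normal, independent-
record model. Real logs have features the generator omits: repeat patients,
protocol drift over time, transcription artefacts, departments missing from
the indication map, and DAP distributions that need not be log-normal.
The I/O layer's validation errors are the first line of defence there.

## Numerical choices and degenerate inputs

* Full-precision arithmetic end to end; rounding only at display.
* Boundary conventions: 40 and 100 cm² are medium; age 15 is adult;
  deviation 0.20 is "within 20%"; duplicate = identical `exam_id`, first
  occurrence kept.
* Degenerate inputs fail loudly and early: empty QC lists, non-positive
  DAPs or mAs, unknown devices/modes/departments, CF tables with age-group
  gaps or mixed dialects all raise errors naming the offending item.
* Dates are ISO-8601 only, avoiding locale ambiguity.

## Problem sizes

The shipped tests and the acceptance script run the full synthetic TCM
cohort at its audited size (4967 records) plus smaller cohorts (150–800
records) for property checks; everything completes in well under a minute
on a single CPU.

## Known limitations

* No DICOM networking or vendor dose-report parsing: the input is a flat
  CSV extract, by design.
* One CF per (device, age group) — the indication-averaging error is
  measured but unavoidable until headers carry the indication.
* Effective dose is a population risk surrogate; the package computes no
  organ doses and no individual risk projections.
* The normal-approximation CI undercovers badly for the tiny strata
  (n ≤ 4) that pediatric cells often are; those intervals should be read
  as order-of-magnitude only.
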