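# sabrqa

Quality-assurance analysis for multicenter stereotactic ablative
radiotherapy (SABR) dummy runs.

Before a multicenter SABR trial enrolls patients, participating centers
contour and plan a set of standard cases so the coordinating center can
quantify inter-institutional variability and protocol adherence. `sabrqa`
implements both analysis phases of such an exercise, for radiation
oncology physicists and trial QA teams:

* **Phase 1 — target-volume agreement.** Per-center Dice similarity of
  the pooled ("summed") gross tumor volumes and planning target volumes
  against the reference set,
  `DSC = 2|A ∩ B| / (|A| + |B|)`,
  pairwise inter-center DSC, reliability as the intraclass correlation
  ICC(2,1) from the two-way random-effects, absolute-agreement model,

  `ICC = (MS_R − MS_E) / (MS_R + (k−1) MS_E + k (MS_C − MS_E)/n)`,

  and non-parametric bootstrap 95% CIs (1,000 resampling iterations over
  axial slices, percentile intervals).
* **Phase 2 — treatment-plan review.** Dose-volume evaluation of each
  plan against a configurable constraint table: PTV coverage, the SBRT
  moderate-dose spillage indices R50% (50%-isodose volume over target
  volume) and D2cm (maximum dose at 2 cm from the target surface, % of
  prescription), high-dose spillage, and organ-at-risk limits (Dmax,
  dose to the hottest *v* cc, volume above a dose). Deviations grade
  *minor* within a 1 Gy (dose) / 3% (volume) tolerance and *major*
  beyond it; R50%/D2cm deviations of multi-target prescriptions can be
  exempted, and coverage can be judged on PTV-EVAL (PTV minus OARs).

Because the clinical DICOM data behind such exercises are not public, the
package also ships a **synthetic cohort generator** (four case
archetypes, contour variants with controllable Dice agreement, dose
fields with closed-form metrics) and plain-text **reference fixtures**
transcribed from the printed per-center tables of a 10-center, four-case
dummy-run exercise. Everything downstream of ingestion is testable with
no external data.

## Worked example

```r
library(sabrqa)

# Phase-1 summaries of the packaged reference table
tab <- fixture_agreement_table()
head(per_case_dsc_summary(tab), 4)
#>   case_id volume_kind  mean    sd  n
#> 1   Case1         GTV 0.463 0.187 10
#> 2   Case1         PTV 0.315 0.121 10
#> 3   Case2         GTV 0.515 0.252 10
#> 4   Case2         PTV 0.428 0.197 10
```

Mean (SD) DSC per case over the ten centers: agreement is moderate for
the clearly visible nodal and lung targets (0.463, 0.515) and collapses
for the ill-defined seeding cases.

```r
# A dose phantom with analytically known compliance metrics
g    <- voxel_grid(c(64, 64, 64), spacing_mm = 2)
ptv  <- ellipsoid_mask(g, center_mm = c(63, 63, 63), radii_mm = 16,
                       label = "PTV1", role = "PTV")
rx   <- prescription("PTV1", total_dose_gy = 40, fractions = 10)
dose <- synth_dose(ptv, rx, falloff_mm = 16, hotspot_pct = 108)

r50(ptv, dose, rx)         # continuum value (24/16)^3 = 3.375
#> [1] 3.433824
d2cm_pct(ptv, dose, rx)    # 16 mm falloff -> nothing reaches the 2 cm shell
#> [1] 0

rep <- evaluate_plan(plan_submission("A", "demo", dose, list(rx), list(ptv)))
rep$records[, c("metric", "observed_value", "limit", "grade")]
#>                   metric observed_value limit grade
#> 1           COVERAGE_PCT     100.000000  95.0  NONE
#> 2                    R50       3.433824   4.5  NONE
#> 3               D2CM_PCT       0.000000  60.0  NONE
#> 4 HIGH_DOSE_SPILLAGE_PCT       0.000000  15.0  NONE

# A synthetic institutional contour tuned to DSC 0.5, with a bootstrap CI
variant <- perturb_contour(ptv, perturbation_config(target_dsc = 0.5, seed = 7))
dice(variant, ptv)
#> [1] 0.512
bootstrap_ci(variant, ptv, n_boot = 1000, seed = 1)
#>        lo        hi
#> 0.4160757 0.5829111
```

The plan phantom is compliant on every default rule (grade `NONE`); the
R50% of 3.43 sits within 2% of the continuum value for this geometry, the
expected discretization accuracy at 2 mm voxels.

## Analysis workflow

The numbered drivers under `analysis/` run the full study shape (ten
centers by four cases on a 128³ × 2 mm grid) and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R    # archetypes + DSC-scheduled cohort
Rscript analysis/02_target_agreement.R   # DSC tables, pairwise, ICC, CIs
Rscript analysis/03_plan_review.R        # compliance, exemptions, PTV-EVAL
Rscript analysis/04_reference_tables.R   # summaries of the packaged tables
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/core-model.R` | voxel grids, structure masks, dose fields, submissions, geometry (distance transform, expansion, components) |
| `R/synthetic-cohort.R` | case archetypes, DSC-controlled contour perturbation, analytic dose fields, cohort builder |
| `R/agreement.R` | DSC, pairwise DSC, ICC(2,1), bootstrap CIs, agreement tables |
| `R/dosimetry.R` | DVH, Dmax/D_cc/V_Gy, coverage, R50%, D2cm, spillage, PTV-EVAL |
| `R/compliance.R` | constraint specs, deviation grading, plan evaluation, exemptions |
| `R/reporting.R` | mean (SD) summaries, deviation tallies, fixture access |
| `R/io.R` | plain-text mask/dose formats, slice-wise contour rasterization |
| `inst/extdata/` | reference-table fixtures and the default constraint file |
| `vignettes/` | methods vignette (model, conventions, limitations) |

See `vignettes/sabr-dummy-run-qa.Rmd` for the modeling assumptions,
numerical conventions and known limitations.
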