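---
title: "Methods: contour agreement and plan compliance for SABR dummy runs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contour agreement and plan compliance for SABR dummy runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sabrqa)
```

## What this package computes

Before a multicenter stereotactic ablative radiotherapy (SABR) trial can
enroll patients, the participating centers typically run a *dummy run*: each
institution contours and plans a set of standard cases, and the coordinating
center quantifies how much the submissions disagree and how well the plans
respect the protocol's dose constraints. `sabrqa` implements the two analysis
phases of such an exercise:

1. **Target-volume agreement.** For each case, each center's gross tumor
   volumes (GTVs) and planning target volumes (PTVs) are pooled by voxelwise
   union ("the sum of GTVs / sum of PTVs") and compared with the reference
   set by the Dice similarity coefficient,
   $\mathrm{DSC} = 2|A \cap B| / (|A| + |B|)$. Pairwise inter-center DSC and
   a reliability coefficient, ICC(2,1), summarize the cohort, and 95%
   confidence intervals come from a non-parametric bootstrap with 1,000
   resampling iterations.
2. **Plan compliance.** Each submitted plan is evaluated against a
   constraint table: PTV coverage, the moderate-dose spillage indices R50%
   and D2cm, high-dose spillage, and organ-at-risk (OAR) point/volume dose
   limits (Dmax, dose to the hottest $v$ cc, volume above a dose).
   Violations are graded *minor* when they exceed the tolerance by no more
   than 1 Gy (dose-type limits) or 3% (volume-type limits) and *major*
   beyond that; R50%/D2cm deviations of prescriptions that cover several
   disconnected targets can be exempted, and coverage can be judged on
   PTV-EVAL (PTV minus OARs).

The clinical structure sets and dose grids of such exercises are generally
not public. The package therefore ships (a) plain-text fixtures transcribed
from the printed per-center tables of a 10-center, four-case exercise, from
which every derivable summary cell is recomputed, and (b) a synthetic
cohort generator that reproduces the *statistical shape* of the exercise so
the whole pipeline is testable end to end.

## The synthetic cohort

`make_case()` builds one of four reference archetypes on a common voxel
grid (default $128^3$ voxels at 2 mm isotropic spacing, which keeps every
geometric operation under a second while leaving a 10-voxel margin for the
2 cm D2cm shell):

* `NODAL` — a single ellipsoidal nodal target at the 165 cc PTV scale,
  with bowel-like OARs nearby;
* `LUNG_MULTI` — five well-separated nodules with PTVs of roughly
  3-11 cc;
* `LIVER_RIND` — a thin spherical-shell cap (a sub-diaphragmatic rind,
  PTV about 45 cc);
* `PERITONEAL_MULTI` — one large (about 530 cc) and two small (about
  15 cc) blobs, the large one abutting a bowel-like OAR slab.

Volumes are randomized within a few percent of these scales
(volume-preserving anisotropy jitter), and each PTV is its GTV expanded
isotropically by a configurable margin (default 5 mm; the protocol margin
of the motivating exercise is not public, so this is a declared package
default). Prescriptions default to the coordinating center's choices in
the reference tables (35 Gy/10 fx nodal and peritoneal, 40 Gy/5 fx lung,
24 Gy/3 fx rind).

**Contour variability.** `perturb_contour()` emulates an institution's
delineation: a smooth random displacement field (a $6^3$ control lattice of
Gaussian vectors, trilinearly upsampled and RMS-normalized) is applied to
the reference mask, and its magnitude is tuned by bisection until the Dice
coefficient against the reference is within 0.015 of the requested target
(error if 0.05 cannot be reached within the iteration cap). A target of 1
returns an exact copy; a target of 0 translates the structure past its
bounding box, which is how the near-zero "gross mismatch" column of the
reference table is emulated — the exercise reports no mechanism for it, so
none is modeled. Calibration is tight: the mean absolute error at targets
0.2/0.5/0.8 is below 0.03 over 20 seeds (verified in the test suite).

**Dose fields.** `synth_dose()` produces a plateau of
$TD \times \mathrm{hotspot}/100$ inside the target union and a linear
falloff $TD \cdot \max(0, 1 - d/\mathrm{falloff})$ with distance $d$ from
the target surface, so R50%, D2cm and Dmax have closed-form values against
which the dosimetry engine is checked (e.g. a 16 mm sphere with 16 mm
falloff puts the 50% isodose at 24 mm: $R_{50\%} = (24/16)^3 = 3.375$).

The generator emulates the *statistics* the analysis consumes — agreement
levels, dose-falloff geometry, compliance outcomes — not the anatomy:
there is no CT simulation, no deformable registration, no planning-system
dose algorithm. Passing tests therefore validate the analysis machinery,
not any claim about real patients.

## Numerical choices

* **Distances.** All distances use an exact anisotropic 3D Euclidean
  distance transform (separable lower-envelope algorithm, compiled).
  Distance-to-structure for the dose falloff and the D2cm shell uses a
  quarter-voxel surface correction (`surface_distance_mm()`):
  center-to-center distances overstate the distance to the voxelized
  boundary by up to half a voxel, while lattice slack around the query
  direction takes back roughly half of that; subtracting a quarter of the
  mean spacing centres the bias (on the 2 mm sphere phantom the R50%
  error drops from about −8% to under 2%).
* **DVH conventions.** Dose-at-volume $D_{v\,cc}$ takes the
  $\lceil v / v_{\mathrm{voxel}} \rceil$-th hottest voxel, so
  $D_{v \to 0^+}$ equals Dmax. Cumulative DVHs use a 0.1 Gy default bin.
* **Dice of empty structures.** Two empty masks score 1 (flagged
  `vacuous`); empty against non-empty scores 0. The reference table
  contains genuine 0.000 rows, so empties must tally as total misses, not
  errors.
* **Bootstrap.** Resampling units are axial slices of the union support by
  default (cubic 4-voxel blocks are available). The motivating exercise
  does not state its resampling unit; slices preserve in-plane spatial
  correlation and give interval widths of the order seen in the reference
  table. Intervals are raw 2.5/97.5 percentiles of the replicate
  distribution (inverse-ECDF quantiles, no bias correction), matching a
  plain "relative frequency distribution" reading.
* **ICC(2,1).** Computed from the explicit two-way ANOVA mean squares
  $(MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E)/n)$, with the mean
  squares attached for audit and a base-R `aov()` cross-check in the
  tests. Two ratings layouts are offered — cases x flattened pairwise
  DSCs, and cases x centers of reference DSCs — because the layout used in
  such exercises is rarely stated. The published reliability coefficients
  of the motivating exercise used the full pairwise data, which the
  printed tables do not contain, so they cannot be recomputed here; the
  cases x centers layout on the shipped table gives 0.661 (GTV) and is
  reported as this package's own, differently-laid-out quantity.
* **Rounding.** Reported DSC and Gy summaries round half-up at 3 decimals,
  percentages at 1 decimal, matching the printed precision of the
  reference tables (base R's round-half-even would disagree on exact
  halves).
* **Grading.** The boundary is compliant (`observed == limit` is NONE,
  with a 1e-9 guard against float noise). The 3% volume tolerance is
  applied as 3 percentage points for %-scale metrics and 3% relative for
  absolute cc limits, since one number must serve both unit families. PTV
  coverage defaults to "at least 95% of the target at prescription, major
  below 90%" via an explicit margin override — the motivating protocol's
  exact coverage rule is not public, so the default is declared in the
  constraint file, not asserted.
* **Exemptions.** Granted per prescription (dose cloud): R50%/D2cm
  deviation records whose prescription covers two or more disconnected
  target components are marked exempt but kept in the report, so tallies
  with and without the policy satisfy an exact conservation identity.
  The binary per-prescription rule is a declared approximation of the
  review's "exempted to some extent".

## Problem sizes

The test suite runs phantoms of $32^3$ to $72^3$ voxels (seconds each);
the calibration and coverage properties use 20-50 seeds on $64^3$ grids.
The analysis drivers and the acceptance script run the full study shape —
ten centers by four cases on the default $128^3$ grid with 1,000 bootstrap
replicates — in a few minutes on one core.

## Known limitations

* Contour exchange (`contours_from_mask()`) extracts per-slice convex
  hulls: faithful for convex or per-slice-convex structures (volume
  round-trips within 2%, Dice at least 0.99 on such phantoms), but
  concave in-slice detail is not recovered. Masks and doses round-trip
  exactly through their run-length text format.
* Structure ingestion reads the package's plain-text formats; clinical
  DICOM RT objects must be converted upstream.
* Dose metrics are voxel-count metrics on the common case grid; no
  sub-voxel interpolation, no biologically effective dose conversion, and
  no re-optimization advice.
* The overall-mean aggregation of the motivating exercise's headline DSC
  figures is not derivable from its printed per-center values (the
  printed overall means match neither the grand mean of the 40 values nor
  the mean of case or center means), so the package reports grand means
  of whatever table it is given and leaves the discrepancy alone.
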