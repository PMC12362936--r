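#!/usr/bin/env Rscript
# Step 1 — simulate the dummy-run cohort.
#
# Builds the four reference case archetypes (nodal target, five lung
# nodules, sub-diaphragmatic rind, peritoneal blobs with a bowel-like OAR)
# and ten institutional contour/plan submissions whose Dice agreement
# follows the published per-center schedule. Writes the reference-volume
# inventory and the achieved per-submission DSC to results/.

source("analysis/00_config.R")
ensure_results()

obj <- build_cohort()
archetypes <- obj$archetypes
cohort <- obj$cohort

vols <- do.call(rbind, lapply(archetypes, function(cs) {
  data.frame(
    case_id = cs$case_id, archetype = cs$archetype,
    target = vapply(cs$reference_ptvs, function(m) m$label, character(1)),
    gtv_cc = round_half_up(
      vapply(cs$reference_gtvs, volume_cc, numeric(1)), 1),
    ptv_cc = round_half_up(
      vapply(cs$reference_ptvs, volume_cc, numeric(1)), 1),
    prescription_gy = cs$default_prescription$total_dose_gy,
    fractions = cs$default_prescription$fractions
  )
}))
write.csv(vols, "results/reference_volumes.csv", row.names = FALSE)

sched <- build_schedule()
ach <- do.call(rbind, lapply(cohort$contours, function(sub) {
  d <- reference_dsc(sub, archetypes[[sub$case_id]])
  data.frame(
    case_id = sub$case_id, center_id = sub$center_id,
    scheduled_dsc = sched[sub$center_id, sub$case_id],
    achieved_gtv_dsc = round_half_up(d[["dsc_gtv"]], 3),
    achieved_ptv_dsc = round_half_up(d[["dsc_ptv"]], 3)
  )
}))
write.csv(ach, "results/cohort_achieved_dsc.csv", row.names = FALSE)

cat("reference volumes (cc):\n")
print(vols, row.names = FALSE)
cat(sprintf(
  "\n%d contour and %d plan submissions generated (%d centers x %d cases)\n",
  length(cohort$contours), length(cohort$plans), N_CENTERS,
  length(archetypes)
))
cat(sprintf(
  "max |achieved - scheduled| GTV DSC: %.3f\n",
  max(abs(ach$achieved_gtv_dsc - ach$scheduled_dsc))
))
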