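#!/usr/bin/env Rscript
# Step 4 — summaries of the packaged reference tables.
#
# Recomputes every summary cell that is derivable from the shipped
# per-center tables of the published dummy-run exercise: per-case and
# per-center mean (SD) DSC, prescription means, ICC(2,1) of the reference
# layout, and the deviation-rate tallies. Writes them to results/.

library(sabrqa)
dir.create("results", showWarnings = FALSE)

tab <- fixture_agreement_table()
per_case <- per_case_dsc_summary(tab)
per_center <- per_center_dsc_summary(tab)
write.csv(per_case, "results/reference_per_case_dsc.csv", row.names = FALSE)
write.csv(per_center, "results/reference_per_center_dsc.csv",
  row.names = FALSE
)

ps <- prescription_summary(qa_fixture("table2"))
write.csv(ps, "results/reference_prescriptions.csv", row.names = FALSE)

icc <- data.frame(
  volume_kind = c("GTV", "PTV"),
  icc21_cases_x_centers = round_half_up(c(
    as.numeric(icc_2_1(ratings_from_reference(tab, "GTV"))),
    as.numeric(icc_2_1(ratings_from_reference(tab, "PTV")))
  ), 3)
)
write.csv(icc, "results/reference_icc.csv", row.names = FALSE)

centers <- qa_fixture("centers")
conventional <- centers$center_id[centers$phase2 &
  centers$ptv_eval_case4 == "none"]
adopters <- centers$center_id[centers$ptv_eval_case4 != "none"]
t3 <- qa_fixture("table3")
t4 <- qa_fixture("table4")
tallies <- rbind(
  data.frame(
    stratum = "Case4 conventional PTV", what = "PTV coverage",
    t(deviation_tally(t3, conventional,
      case_id = "Case4", metric = "COVERAGE_PCT"))
  ),
  data.frame(
    stratum = "Case4 PTV-EVAL adopters", what = "PTV coverage",
    t(deviation_tally(t3, adopters,
      case_id = "Case4", metric = "COVERAGE_PCT"))
  ),
  data.frame(
    stratum = "Case4 conventional PTV", what = "small bowel",
    t(deviation_tally(t4, conventional,
      case_id = "Case4", structure = "small_bowel"))
  ),
  data.frame(
    stratum = "Case4 PTV-EVAL adopters", what = "small bowel",
    t(deviation_tally(t4, adopters,
      case_id = "Case4", structure = "small_bowel"))
  )
)
write.csv(tallies, "results/reference_tallies.csv", row.names = FALSE)

cat("per-case mean (SD) DSC:\n")
print(per_case, row.names = FALSE)
cat("\nprescription summaries (Gy / fractions):\n")
print(ps, row.names = FALSE)
cat("\nICC(2,1), cases x centers layout:\n")
print(icc, row.names = FALSE)
cat("\ndeviation-rate tallies:\n")
print(tallies, row.names = FALSE)
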