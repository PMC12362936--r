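# Shared configuration for the analysis drivers: the synthetic study
# conditions (four case archetypes on a 128^3 x 2 mm grid, ten centers)
# and a cohort builder with a scratch-file cache so the numbered scripts
# can run independently.

library(sabrqa)

COHORT_SEED <- 20260301
GRID <- voxel_grid(c(128, 128, 128), 2)
N_CENTERS <- 10
# the four centers that plan the peritoneal case on PTV-EVAL
PTV_EVAL_CENTERS <- c("G", "H", "I", "J")

build_archetypes <- function() {
  list(
    Case1 = make_case("NODAL", GRID, seed = COHORT_SEED, case_id = "Case1"),
    Case2 = make_case("LUNG_MULTI", GRID,
      seed = COHORT_SEED + 1, case_id = "Case2"),
    Case3 = make_case("LIVER_RIND", GRID,
      seed = COHORT_SEED + 2, case_id = "Case3"),
    Case4 = make_case("PERITONEAL_MULTI", GRID,
      seed = COHORT_SEED + 3, case_id = "Case4")
  )
}

# Delineation-variability schedule: each synthetic center re-enacts one
# published center's per-case GTV agreement (centers A..L of the reference
# table mapped onto generator centers A..J), including the near-zero
# "gross mismatch" column.
build_schedule <- function() {
  tab <- fixture_agreement_table()
  gtv <- tab[tab$volume_kind == "GTV", ]
  src_centers <- sort(unique(gtv$center_id)) # A C D E F G H J K L
  sched <- matrix(NA_real_, N_CENTERS, 4,
    dimnames = list(LETTERS[seq_len(N_CENTERS)], paste0("Case", 1:4))
  )
  for (i in seq_along(src_centers)) {
    for (cs in paste0("Case", 1:4)) {
      sched[LETTERS[i], cs] <-
        gtv$dsc[gtv$center_id == src_centers[i] & gtv$case_id == cs]
    }
  }
  sched
}

build_cohort <- function(cache = "scratch/cohort.rds") {
  if (file.exists(cache)) {
    message("using cached cohort: ", cache)
    return(readRDS(cache))
  }
  archetypes <- build_archetypes()
  cohort <- make_cohort(archetypes, N_CENTERS,
    dsc_schedule = build_schedule(),
    seed = COHORT_SEED, ptv_eval_centers = PTV_EVAL_CENTERS
  )
  obj <- list(archetypes = archetypes, cohort = cohort)
  dir.create(dirname(cache), showWarnings = FALSE, recursive = TRUE)
  saveRDS(obj, cache)
  obj
}

ensure_results <- function() {
  dir.create("results", showWarnings = FALSE)
}
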