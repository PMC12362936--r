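# Summary tables and tallies: mean (sample SD) cells of the agreement and
# prescription tables, and deviation-rate tallies of the plan review.
# Rounding is half-up at the precision the tables print (3 dp for DSC and
# Gy, 1 dp for percentages).

#' Mean and sample standard deviation of a value list
#'
#' The `mean (STD)` cell of a summary table: arithmetic mean and sample SD
#' (n - 1 denominator), rounded half-up. SD is `NA` for a single value.
#'
#' @param values numeric vector, length >= 1.
#' @param round_dp decimals (default 3); `Inf` to skip rounding.
#' @return Named numeric `c(mean = , sd = , n = )`.
#' @export
summarize_stat <- function(values, round_dp = 3) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty value list")
  m <- mean(values)
  s <- if (length(values) >= 2) sd(values) else NA_real_
  if (is.finite(round_dp)) {
    m <- round_half_up(m, round_dp)
    if (!is.na(s)) s <- round_half_up(s, round_dp)
  }
  c(mean = m, sd = s, n = length(values))
}

group_summary <- function(df, value_col, keys, round_dp = 3) {
  key_df <- unique(df[keys])
  rownames(key_df) <- NULL
  out <- lapply(seq_len(nrow(key_df)), function(i) {
    sel <- rep(TRUE, nrow(df))
    for (k in keys) sel <- sel & df[[k]] == key_df[[k]][i]
    if (!any(sel)) stop("empty group")
    st <- summarize_stat(df[[value_col]][sel], round_dp)
    cbind(key_df[i, , drop = FALSE],
      data.frame(mean = st[["mean"]], sd = st[["sd"]], n = st[["n"]])
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-case and per-center DSC summaries
#'
#' The margin cells of the agreement table: mean (sample SD) of DSC over
#' centers for each (case, volume kind), and over cases for each (center,
#' volume kind).
#'
#' @param table agreement table (see [agreement_table()]): columns
#'   `case_id`, `volume_kind`, `center_id`, `dsc`.
#' @param round_dp decimals (default 3).
#' @return Data.frame with the grouping keys plus `mean`, `sd`, `n`.
#' @export
per_case_dsc_summary <- function(table, round_dp = 3) {
  group_summary(table, "dsc", c("case_id", "volume_kind"), round_dp)
}

#' @rdname per_case_dsc_summary
#' @export
per_center_dsc_summary <- function(table, round_dp = 3) {
  group_summary(table, "dsc", c("center_id", "volume_kind"), round_dp)
}

#' Prescription summary per target volume
#'
#' Mean (sample SD) of total dose and fraction count across centers, per
#' (case, target volume).
#'
#' @param rx_table long data.frame with columns `case_id`, `target_label`,
#'   `center_id`, `total_dose_gy`, `fractions`.
#' @param round_dp decimals (default 3).
#' @return Data.frame with per-target `td_mean`, `td_sd`, `fx_mean`,
#'   `fx_sd`, `n`.
#' @export
prescription_summary <- function(rx_table, round_dp = 3) {
  td <- group_summary(rx_table, "total_dose_gy", c("case_id", "target_label"),
    round_dp)
  fx <- group_summary(rx_table, "fractions", c("case_id", "target_label"),
    round_dp)
  out <- data.frame(
    case_id = td$case_id, target_label = td$target_label,
    td_mean = td$mean, td_sd = td$sd, fx_mean = fx$mean, fx_sd = fx$sd,
    n = td$n, stringsAsFactors = FALSE
  )
  out
}

#' Deviation tally: centers with at least one non-exempted deviation
#'
#' Counts, over an explicit denominator set of centers, those with one or
#' more non-exempted deviations matching the filters, and the corresponding
#' percentage (half-up, 1 decimal).
#'
#' @param records deviation-record data.frame (engine output via
#'   [deviation_records_df()], or a transcribed review table with columns
#'   `center_id`, `case_id`, `metric`, `grade`, `exempted`).
#' @param denominator_centers character vector of center ids forming the
#'   denominator.
#' @param case_id optional case filter.
#' @param metric optional metric filter (e.g. `"COVERAGE_PCT"`).
#' @param structure optional `target_or_oar_label` filter (prefix match, so
#'   `"small_bowel"` covers per-metric variants).
#' @return Named numeric `c(count = , denominator = , pct = )`.
#' @export
deviation_tally <- function(records, denominator_centers, case_id = NULL,
                            metric = NULL, structure = NULL) {
  if (length(denominator_centers) == 0) stop("empty denominator")
  sel <- records$grade != "NONE" & !records$exempted &
    records$center_id %in% denominator_centers
  if (!is.null(case_id)) sel <- sel & records$case_id %in% case_id
  if (!is.null(metric)) sel <- sel & records$metric %in% metric
  if (!is.null(structure)) {
    sel <- sel & startsWith(records$target_or_oar_label, structure)
  }
  hit <- unique(records$center_id[sel])
  n <- length(denominator_centers)
  c(
    count = length(hit), denominator = n,
    pct = round_half_up(100 * length(hit) / n, 1)
  )
}

#' Packaged reference fixtures
#'
#' Reads one of the plain-text reference tables shipped with the package:
#' per-center DSC values with bootstrap CIs (`"table1"`), per-center dose
#' prescriptions (`"table2"`), the PTV-compliance review (`"table3"`), the
#' OAR-compliance review (`"table4"`), or the per-case center roster with
#' PTV-EVAL adoption (`"centers"`). The tables encode the printed results
#' of a 10-center, four-case multicenter dummy-run exercise and are test
#' inputs, not outputs.
#'
#' @param name `"table1"`, `"table2"`, `"table3"`, `"table4"` or
#'   `"centers"`.
#' @return A data.frame.
#' @export
qa_fixture <- function(name = c("table1", "table2", "table3", "table4",
                                "centers")) {
  name <- match.arg(name)
  file <- c(
    table1 = "table1_dsc.csv", table2 = "table2_rx.csv",
    table3 = "table3_ptv_dev.csv", table4 = "table4_oar_dev.csv",
    centers = "centers.csv"
  )[[name]]
  path <- system.file("extdata", file, package = "sabrqa")
  if (path == "") stop("fixture not found: ", file)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("exempted" %in% names(df)) df$exempted <- as.logical(df$exempted)
  df
}

#' Build an agreement-table view of the DSC fixture
#'
#' @return The `"table1"` fixture with the columns of [agreement_table()].
#' @export
fixture_agreement_table <- function() {
  df <- qa_fixture("table1")
  df[, c("case_id", "volume_kind", "center_id", "dsc", "ci_low", "ci_high")]
}
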