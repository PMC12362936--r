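# Phase-2 rule engine: evaluate each plan against a constraint table, grade
# deviations minor/major (tolerance 1 Gy in dose, 3% in volume), and apply
# the multi-target exemption for the moderate-dose spillage indices.

CONSTRAINT_METRICS <- c(
  "DMAX", "D_CC", "V_GY", "COVERAGE_PCT", "R50", "D2CM_PCT",
  "HIGH_DOSE_SPILLAGE_PCT"
)
GRADES <- c("NONE", "MINOR", "MAJOR")

#' Protocol constraint specification
#'
#' One dose-constraint rule: the structure (by label, e.g. `"small_bowel"`,
#' or by role `"PTV"` for per-target rules), the metric, an optional metric
#' parameter (cc for `D_CC`, Gy for `V_GY`, percent-of-prescription for
#' `HIGH_DOSE_SPILLAGE_PCT`), the limit and its sense, and which deviation
#' tolerance family applies.
#'
#' @param structure structure label or the role `"PTV"`.
#' @param metric one of `"DMAX"`, `"D_CC"`, `"V_GY"`, `"COVERAGE_PCT"`,
#'   `"R50"`, `"D2CM_PCT"`, `"HIGH_DOSE_SPILLAGE_PCT"`.
#' @param limit constraint limit (Gy, cc, %, or ratio as the metric
#'   requires).
#' @param limit_sense `"max"` (observed must not exceed) or `"min"`.
#' @param tolerance_type `"dose_gy"` (minor band is 1 Gy wide) or
#'   `"volume_pct"` (3 percentage points for %-scale metrics, 3% relative
#'   otherwise).
#' @param parameter metric parameter; required iff the metric needs one.
#' @param percent_scale is the observed value on a 0-100 percent scale?
#'   Determines how the 3%-volume tolerance is applied. Defaults to `TRUE`
#'   for the %-valued metrics.
#' @param margin_override optional explicit minor-band width in the limit's
#'   units, overriding the tolerance family (used for the PTV-coverage
#'   default, whose major threshold is a protocol choice).
#' @return An object of class `constraint_spec`.
#' @export
constraint_spec <- function(structure, metric, limit,
                            limit_sense = c("max", "min"),
                            tolerance_type = c("dose_gy", "volume_pct"),
                            parameter = NA_real_, percent_scale = NULL,
                            margin_override = NA_real_) {
  metric <- match.arg(metric, CONSTRAINT_METRICS)
  limit_sense <- match.arg(limit_sense)
  tolerance_type <- match.arg(tolerance_type)
  if (!is.finite(limit)) stop("`limit` must be finite")
  needs_par <- metric %in% c("D_CC", "V_GY")
  if (needs_par && !is.finite(parameter)) {
    stop(sprintf("metric %s requires a parameter", metric))
  }
  if (!needs_par && metric != "HIGH_DOSE_SPILLAGE_PCT" &&
    is.finite(parameter)) {
    stop(sprintf("metric %s takes no parameter", metric))
  }
  if (is.null(percent_scale)) {
    percent_scale <- metric %in%
      c("COVERAGE_PCT", "D2CM_PCT", "HIGH_DOSE_SPILLAGE_PCT")
  }
  structure(
    list(
      structure = as.character(structure), metric = metric,
      parameter = parameter, limit = as.numeric(limit),
      limit_sense = limit_sense, tolerance_type = tolerance_type,
      percent_scale = isTRUE(percent_scale),
      margin_override = as.numeric(margin_override)
    ),
    class = "constraint_spec"
  )
}

constraint_margin <- function(spec) {
  if (is.finite(spec$margin_override)) {
    return(spec$margin_override)
  }
  if (spec$tolerance_type == "dose_gy") {
    1.0
  } else if (spec$percent_scale) {
    3.0 # percentage points
  } else {
    0.03 * abs(spec$limit) # 3% relative for absolute cc (or ratio) limits
  }
}

#' Grade an observed value against a limit
#'
#' The boundary is compliant: `observed == limit` grades `NONE`. A violation
#' within the tolerance margin (1 Gy for dose-type limits, 3 percentage
#' points for %-scale volume limits, 3% relative for absolute volume
#' limits) grades `MINOR`; beyond it, `MAJOR`. Mirrored for minimum-type
#' limits.
#'
#' @param observed observed metric value (finite).
#' @param limit constraint limit.
#' @param limit_sense `"max"` or `"min"`.
#' @param tolerance_type `"dose_gy"` or `"volume_pct"`.
#' @param percent_scale for `"volume_pct"`: is the metric on a 0-100 scale
#'   (3 points) or an absolute scale (3% relative)?
#' @param margin explicit minor-band width, overriding the tolerance family.
#' @return `"NONE"`, `"MINOR"` or `"MAJOR"`.
#' @export
grade_deviation <- function(observed, limit, limit_sense = c("max", "min"),
                            tolerance_type = c("dose_gy", "volume_pct"),
                            percent_scale = TRUE, margin = NULL) {
  limit_sense <- match.arg(limit_sense)
  tolerance_type <- match.arg(tolerance_type)
  stopifnot(is.finite(observed), is.finite(limit))
  if (is.null(margin)) {
    margin <- constraint_margin(list(
      margin_override = NA_real_, tolerance_type = tolerance_type,
      percent_scale = percent_scale, limit = limit
    ))
  }
  excess <- if (limit_sense == "max") observed - limit else limit - observed
  eps <- 1e-9
  if (excess <= eps) {
    "NONE"
  } else if (excess <= margin + eps) {
    "MINOR"
  } else {
    "MAJOR"
  }
}

#' Default protocol constraint table
#'
#' The constraint limits shipped here are documented package defaults for
#' synthetic-cohort review (the values are configurable and are not claimed
#' to be any trial's protocol): small-bowel Dmax and D_120cc, duodenum Dmax
#' and D_10cc, PTV coverage (at least 95% of the target receiving the
#' prescription, major below 90%), R50%, D2cm and high-dose spillage.
#'
#' @param path optional CSV to read instead of the packaged defaults
#'   (columns as in `inst/extdata/default_constraints.csv`).
#' @return List of [constraint_spec()]s.
#' @export
default_constraints <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_constraints.csv",
      package = "sabrqa"
    )
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    constraint_spec(
      structure = df$structure[i], metric = df$metric[i],
      limit = df$limit[i], limit_sense = df$limit_sense[i],
      tolerance_type = df$tolerance_type[i],
      parameter = if (is.na(df$parameter[i])) NA_real_ else df$parameter[i],
      margin_override = if (is.na(df$margin_override[i])) NA_real_ else
        df$margin_override[i]
    )
  })
}

new_deviation_record <- function(center_id, case_id, label, metric, observed,
                                 limit, grade, exempted = FALSE,
                                 exemption_reason = "") {
  data.frame(
    center_id = center_id, case_id = case_id, target_or_oar_label = label,
    metric = metric, observed_value = observed, limit = limit,
    grade = grade, exempted = exempted, exemption_reason = exemption_reason,
    stringsAsFactors = FALSE
  )
}

#' Evaluate one plan against a constraint table
#'
#' Computes every applicable rule's metric with the dosimetry operations,
#' grades each observation, and (optionally) applies the multi-target
#' exemption policy. Per-target rules (`COVERAGE_PCT`, `R50`, `D2CM_PCT`,
#' `HIGH_DOSE_SPILLAGE_PCT`) are evaluated once per prescription; coverage
#' is evaluated on the PTV-EVAL companion (PTV minus OARs) when the plan
#' declares `uses_ptv_eval`. OAR rules are evaluated against the highest
#' prescription when several exist.
#'
#' @param plan a [plan_submission()].
#' @param case the matching [make_case()] archetype (supplies OARs when the
#'   plan's structure set has none).
#' @param rules list of [constraint_spec()]s; default
#'   [default_constraints()].
#' @param exemption_policy `"NONE"` or `"MULTI_PTV"` (see
#'   [apply_exemptions()]).
#' @return An object of class `compliance_report`: list with `center_id`,
#'   `case_id`, `uses_ptv_eval`, and `records` (a data.frame of deviation
#'   records, one per evaluated constraint, grade `"NONE"` allowed).
#' @export
evaluate_plan <- function(plan, case = NULL, rules = default_constraints(),
                          exemption_policy = c("MULTI_PTV", "NONE")) {
  exemption_policy <- match.arg(exemption_policy)
  if (length(rules) == 0) stop("`rules` must be non-empty")
  if (length(plan$prescriptions) == 0) stop("plan has no prescription")
  oars <- plan_oars(plan)
  if (length(oars) == 0 && !is.null(case)) oars <- case$oars
  oar_labels <- vapply(oars, function(s) s$label, character(1))
  recs <- list()
  k <- 0L
  ptv_components <- setNames(
    integer(length(plan$prescriptions)),
    vapply(plan$prescriptions, function(r) r$target_label, character(1))
  )
  for (rx in plan$prescriptions) {
    target <- plan_structure(plan, rx$target_label, c("PTV", "PTV_EVAL"))
    ptv_components[rx$target_label] <- n_components(target)
    eval_target <- target
    if (plan$uses_ptv_eval && target$role == "PTV" && length(oars) > 0) {
      eval_target <- ptv_eval(target, oars)
    }
    for (rule in rules) {
      if (!rule$metric %in%
        c("COVERAGE_PCT", "R50", "D2CM_PCT", "HIGH_DOSE_SPILLAGE_PCT")) {
        next
      }
      if (!rule$structure %in% c("PTV", rx$target_label)) next
      obs <- switch(rule$metric,
        COVERAGE_PCT = {
          tgt <- if (any(eval_target$voxels)) eval_target else target
          coverage_pct(tgt, plan$dose, rx)
        },
        R50 = r50(target, plan$dose, rx),
        D2CM_PCT = d2cm_pct(target, plan$dose, rx),
        HIGH_DOSE_SPILLAGE_PCT = high_dose_spillage_pct(
          target, plan$dose, rx,
          threshold_pct = if (is.finite(rule$parameter)) rule$parameter else 105
        )
      )
      k <- k + 1L
      recs[[k]] <- new_deviation_record(
        plan$center_id, plan$case_id, rx$target_label, rule$metric, obs,
        rule$limit,
        grade_deviation(obs, rule$limit, rule$limit_sense,
          rule$tolerance_type, rule$percent_scale,
          margin = if (is.finite(rule$margin_override)) {
            rule$margin_override
          } else {
            NULL
          }
        )
      )
    }
  }
  # OAR rules graded against the plan's highest prescription
  rx_main <- plan$prescriptions[[
    which.max(vapply(plan$prescriptions, function(r) r$total_dose_gy,
      numeric(1)))
  ]]
  for (rule in rules) {
    if (rule$metric %in%
      c("COVERAGE_PCT", "R50", "D2CM_PCT", "HIGH_DOSE_SPILLAGE_PCT")) {
      next
    }
    hit <- which(oar_labels == rule$structure)
    if (length(hit) == 0) next # rule not applicable to this case
    oar <- oars[[hit[1]]]
    obs <- switch(rule$metric,
      DMAX = d_max(oar, plan$dose),
      D_CC = {
        if (rule$parameter > volume_cc(oar)) {
          d_max(oar, plan$dose) # hottest-v of a smaller organ: use Dmax
        } else {
          d_cc(oar, plan$dose, rule$parameter)
        }
      },
      V_GY = v_gy(oar, plan$dose, rule$parameter)
    )
    k <- k + 1L
    recs[[k]] <- new_deviation_record(
      plan$center_id, plan$case_id, rule$structure,
      metric_display_name(rule), obs, rule$limit,
      grade_deviation(obs, rule$limit, rule$limit_sense, rule$tolerance_type,
        rule$percent_scale,
        margin = if (is.finite(rule$margin_override)) {
          rule$margin_override
        } else {
          NULL
        }
      )
    )
  }
  records <- do.call(rbind, recs)
  records <- apply_exemptions(records, ptv_components, exemption_policy)
  structure(
    list(
      center_id = plan$center_id, case_id = plan$case_id,
      uses_ptv_eval = plan$uses_ptv_eval, records = records
    ),
    class = "compliance_report"
  )
}

metric_display_name <- function(rule) {
  if (rule$metric == "D_CC") {
    sprintf("D_%gcc", rule$parameter)
  } else if (rule$metric == "V_GY") {
    sprintf("V_%gGy", rule$parameter)
  } else {
    rule$metric
  }
}

#' @export
print.compliance_report <- function(x, ...) {
  dev <- x$records[x$records$grade != "NONE", , drop = FALSE]
  cat(sprintf(
    "<compliance_report %s/%s: %d constraints, %d deviation(s)%s%s>\n",
    x$center_id, x$case_id, nrow(x$records), nrow(dev),
    if (any(dev$exempted)) sprintf(" (%d exempted)", sum(dev$exempted)) else "",
    if (x$uses_ptv_eval) ", PTV-EVAL" else ""
  ))
  invisible(x)
}

#' Apply the multi-target exemption policy to deviation records
#'
#' Under policy `"MULTI_PTV"`, `R50` and `D2CM_PCT` deviation records whose
#' prescription covers two or more disconnected target components are
#' marked `exempted = TRUE` (kept in the report but excluded from tallies),
#' reproducing the with/without-exemption views of a plan review. Policy
#' `"NONE"` leaves records untouched.
#'
#' @param records deviation-record data.frame (see [evaluate_plan()]).
#' @param ptv_geometry named integer vector: connected-component count per
#'   prescription target label.
#' @param policy `"NONE"` or `"MULTI_PTV"`.
#' @return The records with `exempted`/`exemption_reason` updated.
#' @export
apply_exemptions <- function(records, ptv_geometry,
                             policy = c("MULTI_PTV", "NONE")) {
  policy <- match.arg(policy)
  if (policy == "NONE" || is.null(records) || nrow(records) == 0) {
    return(records)
  }
  for (i in seq_len(nrow(records))) {
    lbl <- records$target_or_oar_label[i]
    multi <- lbl %in% names(ptv_geometry) && ptv_geometry[[lbl]] >= 2
    if (multi && records$metric[i] %in% c("R50", "D2CM_PCT") &&
      records$grade[i] != "NONE") {
      records$exempted[i] <- TRUE
      records$exemption_reason[i] <-
        sprintf("prescription covers %d target components", ptv_geometry[[lbl]])
    }
  }
  records
}

#' Flatten compliance reports to one deviation-record data.frame
#'
#' @param reports list of [evaluate_plan()] results.
#' @return A data.frame of all records, with a `uses_ptv_eval` column.
#' @export
deviation_records_df <- function(reports) {
  out <- do.call(rbind, lapply(reports, function(r) {
    df <- r$records
    df$uses_ptv_eval <- r$uses_ptv_eval
    df
  }))
  rownames(out) <- NULL
  out
}

#' Serialize a compliance report to JSON
#'
#' @param report an [evaluate_plan()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_compliance_json <- function(report, path) {
  jsonlite::write_json(
    list(
      center_id = report$center_id, case_id = report$case_id,
      uses_ptv_eval = report$uses_ptv_eval, records = report$records
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
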