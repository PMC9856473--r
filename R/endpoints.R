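#' Derive analysis endpoints from raw outcome fields
#'
#' Builds the three time-to-event endpoints from the raw outcome columns:
#'
#' * **TTR** (time to recurrence): event at the recurrence time when a
#'   recurrence was observed; otherwise censored at the earlier of the
#'   death time and the administrative censoring time (death without prior
#'   recurrence censors TTR).
#' * **DFS** (disease-free survival): event at the first of recurrence or
#'   death when either was observed; otherwise censored.
#' * **OS** (overall survival): event at the death time when death was
#'   observed; otherwise censored.
#'
#' @param data Cohort tibble with columns `recurrence_time`,
#'   `recurrence_observed`, `death_time`, `death_observed`, `censor_time`
#'   (months / logical).
#' @return The input tibble with `ttr_time`, `ttr_event`, `dfs_time`,
#'   `dfs_event`, `os_time`, `os_event` appended.
#' @examples
#' df <- tibble::tibble(
#'   recurrence_time = c(20, 40, 72), recurrence_observed = c(TRUE, FALSE, FALSE),
#'   death_time = c(30, 40, 72), death_observed = c(TRUE, TRUE, FALSE),
#'   censor_time = c(80, 75, 72)
#' )
#' derive_endpoints(df)
#' @export
derive_endpoints <- function(data) {
  req <- c(
    "recurrence_time", "recurrence_observed",
    "death_time", "death_observed", "censor_time"
  )
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing outcome columns: ", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  with(out, {
    if (any(recurrence_time < 0 | death_time < 0 | censor_time < 0)) {
      abort("negative event times")
    }
    both <- recurrence_observed & death_observed
    if (any(recurrence_time[both] > death_time[both] + 1e-9)) {
      abort("recurrence after death: contradictory record")
    }
  })
  out$ttr_event <- out$recurrence_observed
  out$ttr_time <- ifelse(out$recurrence_observed,
    out$recurrence_time,
    pmin(out$death_time, out$censor_time)
  )
  any_event <- out$recurrence_observed | out$death_observed
  out$dfs_event <- any_event
  out$dfs_time <- ifelse(any_event,
    pmin(
      ifelse(out$recurrence_observed, out$recurrence_time, Inf),
      ifelse(out$death_observed, out$death_time, Inf)
    ),
    out$censor_time
  )
  out$os_event <- out$death_observed
  out$os_time <- ifelse(out$death_observed, out$death_time, out$censor_time)
  out
}

#' Apply study exclusions
#'
#' Removes preoperatively treated patients and QC failures, keeping a
#' consort-style exclusion log as the `"exclusion_log"` attribute
#' (retrievable with [exclusion_log()]).
#'
#' @param data Cohort tibble; exclusion uses `preoperative_treatment`
#'   (logical, optional) and `qc_pass`/`qc_reasons` (from [qc_cohort()],
#'   optional).
#' @return Filtered tibble with an exclusion-log attribute.
#' @export
apply_exclusions <- function(data) {
  out <- tibble::as_tibble(data)
  n0 <- nrow(out)
  reasons <- rep("", n0)
  if ("preoperative_treatment" %in% names(out)) {
    reasons[out$preoperative_treatment] <- "PREOP"
  }
  if ("qc_pass" %in% names(out)) {
    fail <- !out$qc_pass & reasons == ""
    reasons[fail] <- out$qc_reasons[fail]
  }
  log <- dplyr::count(
    tibble::tibble(reason = reasons[reasons != ""]), .data$reason,
    name = "n"
  )
  log <- dplyr::bind_rows(
    tibble::tibble(reason = "assessed", n = n0),
    log,
    tibble::tibble(reason = "analyzed", n = sum(reasons == ""))
  )
  kept <- out[reasons == "", , drop = FALSE]
  attr(kept, "exclusion_log") <- log
  kept
}

#' @rdname apply_exclusions
#' @export
exclusion_log <- function(data) {
  attr(data, "exclusion_log") %||%
    tibble::tibble(reason = character(), n = integer())
}

subgroup_names <- function() {
  c(
    "all", "stage1", "stage2", "stage1_mss", "stage2_mss",
    "stage2_untreated", "high_risk_stage2", "low_risk_stage2",
    "very_high_risk_stage2", "t4n0", "t4n0_untreated"
  )
}

# high-risk stage II feature flags; NA when a needed field is unknown
high_risk_features <- function(data) {
  velipi_pos <- dplyr::case_when(
    data$velipi == "positive" ~ TRUE,
    data$velipi == "negative" ~ FALSE,
    TRUE ~ NA
  )
  poor_diff <- dplyr::case_when(
    data$differentiation == "poor" ~ TRUE,
    data$differentiation == "well/moderate" ~ FALSE,
    TRUE ~ NA
  )
  tibble::tibble(
    velipi_pos = velipi_pos,
    t4 = data$t_stage == "T4",
    perforation = data$perforation,
    poor_diff = poor_diff,
    few_ln = data$ln_examined < 12
  )
}

#' Clinical subgroups of the study design
#'
#' Filters a derived cohort to one of the named analysis subgroups.
#' High-risk Stage II means at least one of: VELIPI positive (venous
#' emboli, lymphatic or perineural invasion), T4 tumor, perforation, poor
#' differentiation, or fewer than 12 lymph nodes examined; low-risk means
#' T1-T3 with none of these features. Patients with unknown VELIPI or
#' differentiation are left out of the risk partition (only). The very
#' high-risk group is T4 *and* VELIPI positive by default (`very_high_rule
#' = "and"`); `"or"` gives the disjunctive reading. "Untreated" means no
#' chemotherapy. MSS subgroups drop patients with unknown MSI status.
#'
#' @param data Cohort tibble with the clinical covariate columns produced
#'   by [generate_cohort()].
#' @param name One of `"all"`, `"stage1"`, `"stage2"`, `"stage1_mss"`,
#'   `"stage2_mss"`, `"stage2_untreated"`, `"high_risk_stage2"`,
#'   `"low_risk_stage2"`, `"very_high_risk_stage2"`, `"t4n0"`,
#'   `"t4n0_untreated"`.
#' @param very_high_rule `"and"` (default) or `"or"`.
#' @return Filtered tibble.
#' @export
filter_subgroup <- function(data, name, very_high_rule = c("and", "or")) {
  very_high_rule <- match.arg(very_high_rule)
  if (!name %in% subgroup_names()) {
    abort(paste0(
      "unknown subgroup '", name, "'; expected one of: ",
      paste(subgroup_names(), collapse = ", ")
    ))
  }
  d <- tibble::as_tibble(data)
  stage2 <- d[d$stage == "II", , drop = FALSE]
  risk <- function(dd) {
    f <- high_risk_features(dd)
    any_feature <- f$velipi_pos | f$t4 | f$perforation | f$poor_diff | f$few_ln
    complete <- stats::complete.cases(f)
    list(high = any_feature, complete = complete, f = f)
  }
  switch(name,
    all = d,
    stage1 = d[d$stage == "I", , drop = FALSE],
    stage2 = stage2,
    stage1_mss = d[d$stage == "I" & d$msi == "MSS", , drop = FALSE],
    stage2_mss = stage2[stage2$msi == "MSS", , drop = FALSE],
    stage2_untreated = stage2[!stage2$chemotherapy, , drop = FALSE],
    high_risk_stage2 = {
      r <- risk(stage2)
      stage2[r$complete & r$high, , drop = FALSE]
    },
    low_risk_stage2 = {
      r <- risk(stage2)
      stage2[r$complete & !r$high, , drop = FALSE]
    },
    very_high_risk_stage2 = {
      r <- risk(stage2)
      f <- r$f
      keep <- if (very_high_rule == "and") f$t4 & f$velipi_pos else f$t4 | f$velipi_pos
      stage2[r$complete & !is.na(keep) & keep, , drop = FALSE]
    },
    t4n0 = stage2[stage2$t_stage == "T4", , drop = FALSE],
    t4n0_untreated = stage2[stage2$t_stage == "T4" & !stage2$chemotherapy, ,
      drop = FALSE
    ]
  )
}
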