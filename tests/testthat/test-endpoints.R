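test_that("endpoints follow the TTR/DFS/OS definitions", {
  df <- tibble::tibble(
    recurrence_time = c(20, 40, 72),
    recurrence_observed = c(TRUE, FALSE, FALSE),
    death_time = c(30, 40, 72),
    death_observed = c(TRUE, TRUE, FALSE),
    censor_time = c(80, 75, 72)
  )
  d <- derive_endpoints(df)
  # recurrence at 20, death at 30
  expect_equal(d$ttr_time[1], 20)
  expect_true(d$ttr_event[1])
  expect_equal(d$dfs_time[1], 20)
  expect_true(d$dfs_event[1])
  expect_equal(d$os_time[1], 30)
  expect_true(d$os_event[1])
  # no recurrence, death at 40: TTR censored at death
  expect_equal(d$ttr_time[2], 40)
  expect_false(d$ttr_event[2])
  expect_equal(d$dfs_time[2], 40)
  expect_true(d$dfs_event[2])
  expect_true(d$os_event[2])
  # neither event: all censored at 72
  expect_equal(d$ttr_time[3], 72)
  expect_equal(d$dfs_time[3], 72)
  expect_equal(d$os_time[3], 72)
  expect_false(any(d$ttr_event[3], d$dfs_event[3], d$os_event[3]))
})

test_that("contradictory outcome records are refused", {
  bad <- tibble::tibble(
    recurrence_time = 50, recurrence_observed = TRUE,
    death_time = 30, death_observed = TRUE, censor_time = 80
  )
  expect_error(derive_endpoints(bad), "recurrence after death")
  neg <- tibble::tibble(
    recurrence_time = -1, recurrence_observed = FALSE,
    death_time = 30, death_observed = TRUE, censor_time = 80
  )
  expect_error(derive_endpoints(neg), "negative")
})

test_that("endpoint ordering holds across a generated cohort", {
  ref <- default_reference()
  co <- derive_endpoints(
    generate_cohort(generator_config(n_patients = 3000, seed = 14), ref)
  )
  expect_true(all(co$dfs_time <= co$os_time + 1e-9))
  expect_gte(sum(co$dfs_event), sum(co$os_event))
})

test_that("exclusions remove preoperative treatment and QC failures with a log", {
  d <- tibble::tibble(
    patient_id = c("a", "b", "c", "d"),
    preoperative_treatment = c(TRUE, FALSE, FALSE, FALSE),
    qc_pass = c(TRUE, FALSE, TRUE, TRUE),
    qc_reasons = c("", "LOW_INTENSITY", "", "")
  )
  kept <- apply_exclusions(d)
  expect_equal(kept$patient_id, c("c", "d"))
  log <- exclusion_log(kept)
  expect_equal(log$n[log$reason == "assessed"], 4)
  expect_equal(log$n[log$reason == "PREOP"], 1)
  expect_equal(log$n[log$reason == "LOW_INTENSITY"], 1)
  expect_equal(log$n[log$reason == "analyzed"], 2)
})

test_that("risk-group definitions follow the clinical rules", {
  rows <- dplyr::bind_rows(
    clinical_row(t_stage = "T3", velipi = "positive", ln_examined = 20L), # high (VELIPI)
    clinical_row(t_stage = "T2", velipi = "negative", ln_examined = 15L), # low
    clinical_row(t_stage = "T4", velipi = "negative"), # high (T4), t4n0
    clinical_row(t_stage = "T4", velipi = "positive", chemotherapy = TRUE), # very high
    clinical_row(t_stage = "T3", ln_examined = 8L), # high (few LN)
    clinical_row(t_stage = "T3", differentiation = "unknown"), # incomplete
    clinical_row(stage = "I", t_stage = "T2") # stage I
  )
  rows$patient_id <- letters[seq_len(nrow(rows))]
  hi <- filter_subgroup(rows, "high_risk_stage2")
  lo <- filter_subgroup(rows, "low_risk_stage2")
  expect_setequal(hi$patient_id, c("a", "c", "d", "e"))
  expect_setequal(lo$patient_id, "b")
  vh <- filter_subgroup(rows, "very_high_risk_stage2")
  expect_setequal(vh$patient_id, "d")
  vh_or <- filter_subgroup(rows, "very_high_risk_stage2", very_high_rule = "or")
  expect_setequal(vh_or$patient_id, c("a", "c", "d"))
  t4 <- filter_subgroup(rows, "t4n0")
  expect_setequal(t4$patient_id, c("c", "d"))
  t4u <- filter_subgroup(rows, "t4n0_untreated")
  expect_setequal(t4u$patient_id, "c")
  expect_setequal(filter_subgroup(rows, "stage1")$patient_id, "g")
  expect_error(filter_subgroup(rows, "nonsense"), "unknown subgroup")
})

test_that("stage II patients with complete risk fields partition into high/low risk", {
  ref <- default_reference()
  co <- generate_cohort(generator_config(n_patients = 4000, seed = 18), ref)
  s2 <- filter_subgroup(co, "stage2")
  complete <- s2[s2$velipi != "unknown" & s2$differentiation != "unknown", ]
  hi <- filter_subgroup(co, "high_risk_stage2")
  lo <- filter_subgroup(co, "low_risk_stage2")
  expect_equal(nrow(hi) + nrow(lo), nrow(complete))
  expect_length(intersect(hi$patient_id, lo$patient_id), 0)
  vh <- filter_subgroup(co, "very_high_risk_stage2")
  expect_true(all(vh$patient_id %in% hi$patient_id))
  expect_true(all(filter_subgroup(co, "t4n0")$patient_id %in% s2$patient_id))
  mss <- filter_subgroup(co, "stage2_mss")
  expect_true(all(mss$msi == "MSS"))
})
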