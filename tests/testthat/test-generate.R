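test_that("5-year rates convert to exponential hazards and back", {
  expect_equal(hazard_from_rate5yr(1.0), 0)
  expect_equal(hazard_from_rate5yr(0.934), 0.001138, tolerance = 1e-6 / 0.001138)
  expect_lt(abs(hazard_from_rate5yr(0.934) - (-log(0.934) / 60)), 1e-15)
  expect_equal(hazard_from_rate5yr(exp(-60 * 0.01)), 0.01)
  expect_error(hazard_from_rate5yr(0), "\\(0, 1\\]")
  expect_error(hazard_from_rate5yr(1.2), "\\(0, 1\\]")
})

test_that("cohort generation is deterministic given the seed", {
  ref <- default_reference()
  cfg <- generator_config(n_patients = 300, seed = 42)
  c1 <- generate_cohort(cfg, ref)
  c2 <- generate_cohort(cfg, ref)
  expect_identical(c1, c2)
  c3 <- generate_cohort(generator_config(n_patients = 300, seed = 43), ref)
  expect_false(identical(c1$recurrence_time, c3$recurrence_time))
})

test_that("category sampling matches the configured proportions", {
  ref <- default_reference()
  cfg <- generator_config(
    n_patients = 100000,
    category_proportions = c(Lo = 0.238, Int = 0.472, Hi = 0.290),
    seed = 5
  )
  co <- generate_cohort(cfg, ref)
  frac <- 100 * as.numeric(table(co$true_category)) / nrow(co)
  expect_lt(max(abs(frac - c(23.8, 47.2, 29.0))), 0.5)

  only_lo <- generate_cohort(
    generator_config(
      n_patients = 500,
      category_proportions = c(Lo = 1, Int = 0, Hi = 0), seed = 2
    ),
    ref
  )
  expect_true(all(only_lo$true_mean_percentile <= 25))

  counts <- generate_cohort(
    generator_config(
      n_patients = 100,
      category_counts = c(Lo = 30, IntHi = 70), seed = 2
    ),
    ref
  )
  expect_equal(as.numeric(table(counts$true_category)), c(30, 70))
})

test_that("rescoring generated densities reproduces the sampled category exactly", {
  ref <- default_reference()
  cfg <- generator_config(n_patients = 2000, seed = 33)
  sc <- score_cohort(generate_cohort(cfg, ref), ref)
  expect_identical(as.character(sc$is3), as.character(sc$true_category))
  expect_equal(
    sc$mean_percentile,
    rowMeans(cbind(sc$pct_cd3_ct, sc$pct_cd3_im, sc$pct_cd8_ct, sc$pct_cd8_im)),
    tolerance = 1e-12
  )
})

test_that("per-category survival at 60 months matches the planted rates", {
  ref <- default_reference()
  cfg <- generator_config(n_patients = 50000, seed = 8)
  sc <- derive_endpoints(score_cohort(generate_cohort(cfg, ref), ref))
  planted <- c(Lo = 78.4, Int = 88.1, Hi = 93.4)
  for (cat in names(planted)) {
    idx <- sc$is3 == cat
    km <- km_curve(sc[idx, ], ttr_time, ttr_event)
    est <- 100 * km_rate_at(km, 60, side = "left")$estimate
    expect_lt(abs(est - planted[[cat]]), 1)
  }
})

test_that("censoring window calibration hits the target median follow-up", {
  ref <- default_reference()
  cfg <- generator_config(n_patients = 20000, seed = 12)
  co <- generate_cohort(cfg, ref)
  followup <- co$censor_time[!co$death_observed]
  expect_lt(abs(median(followup) - 69.5), 1.5)
  win <- censoring_window(cfg)
  expect_equal(diff(win), 48)
})

test_that("with equal hazards across categories, log-rank p-values are uniform", {
  ref <- default_reference()
  base <- generator_config(
    n_patients = 200,
    category_proportions = c(Lo = 0.5, Int = 0, Hi = 0.5),
    survival_spec = list(type = "rate5yr", values = c(Lo = 0.75, Int = 0.75, Hi = 0.75)),
    censoring_spec = list(family = "admin", time = 72),
    death_hazard = 0, seed = 1
  )
  pvals <- vapply(1:1000, function(i) {
    cfg <- base
    cfg$seed <- i
    co <- derive_endpoints(generate_cohort(cfg, ref))
    co$grp <- co$true_category
    logrank_test(co, ttr_time, ttr_event, grp)$p.value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("covariate prevalences and staging consistency hold", {
  ref <- default_reference()
  co <- generate_cohort(generator_config(n_patients = 20000, seed = 3), ref)
  expect_lt(abs(mean(co$gender == "male") - 0.526), 0.02)
  expect_lt(abs(mean(co$ln_examined) - 19), 0.5)
  expect_lt(abs(median(co$age) - 68), 2)
  expect_true(all(co$t_stage[co$stage == "I"] %in% c("T1", "T2")))
  expect_true(all(co$t_stage[co$stage == "II"] %in% c("T3", "T4")))
  expect_true(all(co$n_stage == 0))
  expect_true(all(
    co$recurrence_time[co$recurrence_observed & co$death_observed] <=
      co$death_time[co$recurrence_observed & co$death_observed] + 1e-9
  ))
})

test_that("invalid generator configurations are refused", {
  expect_error(generator_config(n_patients = 10, n_centers = 14), "n_centers")
  expect_error(
    generator_config(category_proportions = c(Lo = 0.5, Int = 0.4, Hi = 0.2)),
    "sum to 1"
  )
  expect_error(
    generator_config(n_patients = 100, category_counts = c(Lo = 10, Hi = 20)),
    "sum to n_patients"
  )
  expect_error(generator_config(death_hazard = -1), ">= 0")
})

test_that("cohort tables round-trip through the text format", {
  ref <- default_reference()
  co <- generate_cohort(generator_config(n_patients = 120, seed = 9), ref)
  path <- tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 120)
  expect_equal(back$density_cd3_ct, co$density_cd3_ct, tolerance = 1e-9)
  expect_identical(
    as.character(back$true_category),
    as.character(co$true_category)
  )
  expect_s3_class(back$stage, "factor")
})
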