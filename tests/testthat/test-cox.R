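test_that("symmetric groups give a zero coefficient and strata reduce correctly", {
  d <- tibble::tibble(
    t = rep(c(2, 5, 9, 14, 20), 2),
    e = rep(c(TRUE, TRUE, FALSE, TRUE, TRUE), 2),
    g = rep(c("a", "b"), each = 5)
  )
  fit <- cox_fit(d, t, e, terms = "g")
  expect_lt(abs(fit$coefficients[["gb"]]), 1e-8)
  expect_equal(exp(fit$coefficients[["gb"]]), 1, tolerance = 1e-6)

  # one stratum is the same as no strata
  d$s1 <- factor("only")
  f0 <- cox_fit(d, t, e, terms = "g")
  f1 <- cox_fit(d, t, e, terms = "g", strata = "s1")
  expect_equal(f0$coefficients, f1$coefficients, tolerance = 1e-12)
  expect_equal(f0$loglik, f1$loglik, tolerance = 1e-12)
})

test_that("coefficients, covariance and log-likelihood match coxph", {
  set.seed(77)
  for (i in 1:20) {
    d <- make_surv_data(sample(60:150, 1),
      groups = c("a", "b", "c"),
      round_digits = if (i %% 2 == 0) 0 else NULL
    )
    if (sum(d$e) < 10) next
    ties <- if (i %% 3 == 0) "breslow" else "efron"
    fit <- cox_fit(d, t, e, terms = c("g", "x"), strata = "s", ties = ties)
    oracle <- survival::coxph(
      survival::Surv(t, e) ~ g + x + survival::strata(s),
      data = d, ties = ties
    )
    expect_lt(max(abs(fit$coefficients - stats::coef(oracle))), 1e-6)
    expect_lt(max(abs(fit$vcov - stats::vcov(oracle))), 1e-6)
    expect_lt(max(abs(fit$loglik - oracle$loglik)), 1e-6)
  }
})

test_that("a planted hazard ratio of 0.5 is recovered at n = 5000", {
  set.seed(99)
  n <- 5000
  grp <- rep(c(0, 1), each = n / 2)
  t <- rexp(n, 0.01 * ifelse(grp == 1, 0.5, 1))
  cens <- runif(n, 40, 100)
  d <- tibble::tibble(
    t = pmin(t, cens), e = t < cens,
    g = factor(ifelse(grp == 1, "hi", "base"), levels = c("base", "hi"))
  )
  fit <- cox_fit(d, t, e, terms = "g")
  hr <- exp(fit$coefficients[["ghi"]])
  expect_gt(hr, 0.45)
  expect_lt(hr, 0.55)
})

test_that("coefficient bias is small over repeated proportional-hazards cohorts", {
  set.seed(123)
  true_beta <- log(0.5)
  est <- vapply(1:200, function(i) {
    n <- 2000
    grp <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.008 * exp(true_beta * grp))
    cens <- runif(n, 45, 95)
    d <- tibble::tibble(t = pmin(t, cens), e = t < cens, g = factor(grp))
    cox_fit(d, t, e, terms = "g")$coefficients[["g1"]]
  }, numeric(1))
  expect_lt(abs(mean(est) - true_beta) / abs(true_beta), 0.02)
})

test_that("the Wald test is the squared z for one parameter and blocks factors", {
  set.seed(15)
  d <- make_surv_data(150, groups = c("a", "b", "c"))
  fit <- cox_fit(d, t, e, terms = c("g", "x"))
  w_x <- wald_test(fit, "x")
  td <- tidy(fit)
  z <- td$statistic[td$term == "x"]
  expect_equal(w_x$statistic, z^2, tolerance = 1e-12)
  expect_equal(w_x$df, 1)
  w_g <- wald_test(fit, "g")
  expect_equal(w_g$df, 2)
  b <- fit$coefficients[1:2]
  v <- fit$vcov[1:2, 1:2]
  expect_equal(w_g$statistic, as.numeric(t(b) %*% solve(v, b)), tolerance = 1e-12)
  expect_error(wald_test(fit, "nope"), "not in fit")
})

test_that("complete separation is flagged, not silently returned", {
  d <- tibble::tibble(
    t = c(1, 2, 3, 4, 50, 60, 70, 80),
    e = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    g = factor(rep(c("bad", "good"), each = 4))
  )
  expect_warning(fit <- cox_fit(d, t, e, terms = "g"), "monotone|converge")
  expect_false(fit$converged)
})

test_that("constant-within-strata covariates are dropped with a message", {
  set.seed(3)
  d <- make_surv_data(120)
  d$const <- 1
  expect_message(
    fit <- cox_fit(d, t, e, terms = c("g", "const")),
    "dropping constant"
  )
  expect_false(any(grepl("const", names(fit$coefficients))))
})

test_that("the likelihood-ratio test separates nested models correctly", {
  set.seed(8)
  d <- make_surv_data(200)
  full <- cox_fit(d, t, e, terms = c("g", "x"))
  reduced <- cox_fit(d, t, e, terms = "g")
  lt <- lr_test(full, reduced)
  expect_equal(lt$df, 1)
  expect_gte(lt$statistic, 0)
  same <- lr_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  other <- cox_fit(d[1:150, ], t, e, terms = "g")
  expect_error(lr_test(full, other), "same data")
  unrelated <- cox_fit(d, t, e, terms = "x")
  expect_error(lr_test(reduced, unrelated), "nested")
})

test_that("null tests keep their nominal levels", {
  set.seed(202)
  n_rep <- 1000
  p_lr <- numeric(n_rep)
  p_logrank <- numeric(n_rep)
  p_wald <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    n <- 300
    d <- tibble::tibble(
      t = rexp(n, 0.02), e = runif(n) < 0.8,
      g = factor(rep(c("a", "b"), n / 2)), x = rnorm(n)
    )
    p_logrank[i] <- logrank_test(d, t, e, g)$p.value
    full <- cox_fit(d, t, e, terms = c("g", "x"))
    reduced <- cox_fit(d, t, e, terms = "g")
    p_lr[i] <- lr_test(full, reduced)$p.value # x is pure noise
    p_wald[i] <- wald_test(full, "g")$p.value
  }
  expect_lte(mean(p_logrank < 0.05), 0.06)
  expect_lte(mean(p_wald < 0.05), 0.06)
  ks <- suppressWarnings(stats::ks.test(p_lr, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("adding a strong covariate is detected with near-certain power", {
  set.seed(301)
  hits <- vapply(1:200, function(i) {
    n <- 300
    grp <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.01 * 0.3^grp)
    cens <- runif(n, 50, 120)
    d <- tibble::tibble(
      t = pmin(t, cens), e = t < cens, g = factor(grp), x = rnorm(n)
    )
    full <- cox_fit(d, t, e, terms = c("x", "g"))
    reduced <- cox_fit(d, t, e, terms = "x")
    lr_test(full, reduced)$p.value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(10)
  d <- make_surv_data(150)
  fit <- cox_fit(d, t, e, terms = c("g", "x"), strata = "s")
  td <- tidy(fit, exponentiate = TRUE)
  expect_named(
    td,
    c("term", "estimate", "std.error", "statistic", "p.value", "conf.low", "conf.high")
  )
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n, 150)
  expect_equal(gl$statistic, 2 * (gl$logLik - gl$null_logLik), tolerance = 1e-12)
  expect_gte(gl$concordance, 0)
})
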