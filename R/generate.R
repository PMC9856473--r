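#' Convert a 5-year event-free rate to an exponential hazard
#'
#' Under an exponential event-time model, a survival fraction `s5` at five
#' years (60 months) corresponds to the monthly hazard
#' `lambda = -log(s5) / 60`, i.e. `exp(-60 * lambda) = s5`.
#'
#' @param s5 Event-free fraction at 60 months, in (0, 1\].
#' @return Hazard per month (0 when `s5 == 1`).
#' @examples
#' hazard_from_rate5yr(0.934)
#' @export
hazard_from_rate5yr <- function(s5) {
  if (any(s5 <= 0 | s5 > 1)) abort("a 5-year event-free rate must lie in (0, 1]")
  -log(s5) / 60
}

#' Synthetic-cohort generator configuration
#'
#' Bundles every knob of the cohort simulator with defaults that reproduce
#' the study conditions of the multicenter early-stage colon cancer series
#' the package emulates: 1885 patients over 14 centers, three-level score
#' proportions 23.8 / 47.2 / 29.0 percent, per-category exponential
#' recurrence hazards calibrated to 5-year recurrence-free rates of
#' 78.4 / 88.1 / 93.4 percent, uniform administrative censoring tuned to a
#' 69.5-month median follow-up among censored patients, 52.6 percent male,
#' median age 68, and a mean of 19 lymph nodes examined.
#'
#' @param n_patients Cohort size.
#' @param n_centers Number of participating centers.
#' @param cohort_split Fraction of patients in cohort 1 (North America).
#' @param category_proportions Named numeric over `Lo`, `Int`, `Hi`,
#'   summing to 1. Ignored when `category_counts` is given.
#' @param category_counts Optional named integer counts (exact group sizes
#'   instead of multinomial sampling); must sum to `n_patients`.
#' @param survival_spec Per-category recurrence model. Either
#'   `list(type = "rate5yr", values = c(Lo=, Int=, Hi=))` with 5-year
#'   recurrence-free rates, or `list(type = "hr", lo_rate5yr =, hr = c(Lo=1,
#'   Int=, Hi=))` with true hazard ratios versus `Lo`. Categories absent
#'   from the proportions may be dropped (two-level designs use only
#'   `Lo` and `Hi`).
#' @param weibull_shape Shape of the Weibull event-time family; 1 (the
#'   default) is the exponential model, other values keep the same
#'   5-year survival while bending the hazard for sensitivity checks.
#' @param censoring_spec Either `list(family = "uniform", target_median =
#'   69.5, width = 48)` — an administrative window solved numerically so the
#'   median follow-up of censored patients hits the target — or
#'   `list(family = "admin", time = 60)` for a fixed cutoff.
#' @param covariates Named list of covariate prevalences; see
#'   [default_covariates()].
#' @param death_hazard Monthly hazard of death without prior recurrence.
#' @param post_recurrence_death_hazard Monthly death hazard after
#'   recurrence.
#' @param perturbation_sd Spread (percentile points) of the four channel
#'   percentiles around each patient's mean percentile.
#' @param intensity_mean,intensity_sd Staining-intensity distribution (AU)
#'   used for the QC columns.
#' @param preop_fraction Fraction flagged as preoperatively treated
#'   (default 0; the study excluded them by design — nonzero values exist
#'   to exercise the exclusion funnel).
#' @param seed Integer seed.
#' @return A list of class `til_config`.
#' @export
generator_config <- function(n_patients = 1885,
                             n_centers = 14,
                             cohort_split = 262 / 1885,
                             category_proportions = c(Lo = 0.238, Int = 0.472, Hi = 0.290),
                             category_counts = NULL,
                             survival_spec = list(
                               type = "rate5yr",
                               values = c(
                                 Lo = 0.784, Int = 0.881, Hi = 0.934,
                                 IntHi = 0.900
                               )
                             ),
                             weibull_shape = 1,
                             censoring_spec = list(
                               family = "uniform",
                               target_median = 69.5, width = 48
                             ),
                             covariates = default_covariates(),
                             death_hazard = 0.004,
                             post_recurrence_death_hazard = 0.025,
                             perturbation_sd = 10,
                             intensity_mean = 400,
                             intensity_sd = 60,
                             preop_fraction = 0,
                             seed = 1L) {
  if (n_patients < 1) abort("n_patients must be >= 1")
  if (n_centers > n_patients) abort("n_centers may not exceed n_patients")
  if (!is.null(category_counts)) {
    if (sum(category_counts) != n_patients) {
      abort("category_counts must sum to n_patients")
    }
  } else if (abs(sum(category_proportions) - 1) > 1e-9) {
    abort("category_proportions must sum to 1")
  }
  if (death_hazard < 0 || post_recurrence_death_hazard < 0) {
    abort("hazards must be >= 0")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), n_centers = as.integer(n_centers),
      cohort_split = cohort_split,
      category_proportions = category_proportions,
      category_counts = category_counts,
      survival_spec = survival_spec, weibull_shape = weibull_shape,
      censoring_spec = censoring_spec, covariates = covariates,
      death_hazard = death_hazard,
      post_recurrence_death_hazard = post_recurrence_death_hazard,
      perturbation_sd = perturbation_sd,
      intensity_mean = intensity_mean, intensity_sd = intensity_sd,
      preop_fraction = preop_fraction,
      seed = as.integer(seed)
    ),
    class = "til_config"
  )
}

#' @rdname generator_config
#' @details `default_covariates()` holds the marginal prevalences used for
#'   clinical covariates; covariates are drawn independently (the joint
#'   distribution of the source cohort is not public). T-stage is drawn
#'   within stage (stage I: T1/T2; stage II: T3/T4) so staging stays
#'   internally consistent, and chemotherapy is essentially a stage II
#'   treatment.
#' @export
default_covariates <- function() {
  list(
    male = 0.526,
    age_mean = 68, age_sd = 12.5,
    stage2 = 1434 / 1885,
    t_within_stage1 = c(T1 = 0.4, T2 = 0.6),
    t_within_stage2 = c(T3 = 0.85, T4 = 0.15),
    right_sided = 0.5,
    msi_known = 0.55, msi_of_known = 0.17,
    velipi = 0.20, velipi_unknown = 0.08,
    poor_differentiation = 0.15, differentiation_unknown = 0.05,
    perforation = 0.04,
    chemo_stage2 = 1 - 1130 / 1434, chemo_stage1 = 0.02,
    ln_mean = 19, ln_size = 12
  )
}

category_hazards <- function(config) {
  spec <- config$survival_spec
  cats <- if (!is.null(config$category_counts)) {
    names(config$category_counts)
  } else {
    names(config$category_proportions)
  }
  if (identical(spec$type, "rate5yr")) {
    vals <- spec$values[cats]
    if (anyNA(vals)) abort("survival_spec does not cover every category")
    lam <- hazard_from_rate5yr(vals)
  } else if (identical(spec$type, "hr")) {
    lam0 <- hazard_from_rate5yr(spec$lo_rate5yr)
    hrs <- spec$hr[cats]
    if (anyNA(hrs)) abort("survival_spec does not cover every category")
    lam <- lam0 * hrs
  } else {
    abort("survival_spec$type must be 'rate5yr' or 'hr'")
  }
  setNames(as.numeric(lam), cats)
}

# Weibull scale giving the same 5-year survival as exponential hazard lam
weibull_scale_for <- function(lam, shape) {
  ifelse(lam == 0, Inf, 60 / (60 * lam)^(1 / shape))
}

r_event_times <- function(n, lam, shape) {
  if (lam == 0) {
    return(rep(Inf, n))
  }
  b <- weibull_scale_for(lam, shape)
  b * (-log(runif(n)))^(1 / shape)
}

#' Solve the administrative censoring window
#'
#' For a uniform censoring time on `[center - width/2, center + width/2]`,
#' the follow-up of a censored (still alive) patient has density
#' proportional to the overall survival function of the death process on
#' that window. The window center is solved numerically so that the median
#' of this conditional distribution equals the configured target (default
#' 69.5 months). The death process used is the exponential-equivalent
#' approximation of the generator's mixture (non-recurrence death plus
#' recurrence followed by post-recurrence death).
#'
#' @param config A [generator_config()].
#' @return `c(L, U)` in months.
#' @export
censoring_window <- function(config) {
  spec <- config$censoring_spec
  if (identical(spec$family, "admin")) {
    return(c(spec$time, spec$time))
  }
  if (identical(spec$family, "window")) {
    return(c(spec$L, spec$U)) # pre-solved window, passed through
  }
  if (!identical(spec$family, "uniform")) {
    abort("censoring_spec$family must be 'uniform', 'window' or 'admin'")
  }
  target <- spec$target_median %||% 69.5
  w <- spec$width %||% 48
  lam <- category_hazards(config)
  pi_cat <- if (!is.null(config$category_counts)) {
    config$category_counts / sum(config$category_counts)
  } else {
    config$category_proportions[names(lam)]
  }
  mu0 <- config$death_hazard
  mup <- config$post_recurrence_death_hazard
  surv_death <- function(t) {
    a <- vapply(seq_along(lam), function(i) {
      l <- lam[[i]]
      if (l == 0) {
        rep(1, length(t))
      } else if (abs(l - mup) < 1e-12) {
        (1 + l * t) * exp(-l * t)
      } else {
        (mup * exp(-l * t) - l * exp(-mup * t)) / (mup - l)
      }
    }, numeric(length(t)))
    exp(-mu0 * t) * as.numeric(a %*% as.numeric(pi_cat))
  }
  cond_median <- function(center) {
    L <- max(0, center - w / 2)
    U <- center + w / 2
    total <- stats::integrate(surv_death, L, U)$value
    uniroot(
      function(m) stats::integrate(surv_death, L, m)$value - total / 2,
      interval = c(L, U), tol = 1e-8
    )$root
  }
  center <- uniroot(
    function(c) cond_median(c) - target,
    interval = c(w / 2 + 1e-6, target + w), tol = 1e-7
  )$root
  c(max(0, center - w / 2), center + w / 2)
}

#' Generate a synthetic patient cohort
#'
#' Draws a full cohort with the statistical structure the downstream
#' analysis assumes: a latent three-level score category per patient, a
#' mean percentile uniform within that category's band, four channel
#' percentiles that average exactly to the mean, densities obtained by
#' inverse-percentile lookup against the reference, recurrence and death
#' times from per-category (Weibull/exponential) hazards with independent
#' administrative censoring, and clinical covariates from the configured
#' marginal prevalences. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @param ref A [til_reference][simulate_reference]; defaults to the
#'   packaged reference.
#' @return A tibble, one row per patient. Density columns feed
#'   [score_cohort()]; outcome columns (`recurrence_time`,
#'   `recurrence_observed`, `death_time`, `death_observed`, `censor_time`)
#'   feed [derive_endpoints()].
#' @examples
#' cfg <- generator_config(n_patients = 200, seed = 7)
#' cohort <- generate_cohort(cfg)
#' dplyr::count(cohort, true_category)
#' @export
generate_cohort <- function(config, ref = default_reference()) {
  stopifnot(inherits(config, "til_config"))
  n <- config$n_patients
  withr_seed(config$seed, {
    # (a) latent category ("IntHi" allowed for two-level designs)
    if (!is.null(config$category_counts)) {
      cats_avail <- names(config$category_counts)
      cat_vec <- sample(rep(cats_avail, times = config$category_counts))
    } else {
      cats_avail <- names(config$category_proportions)
      cat_vec <- sample(cats_avail, n,
        replace = TRUE,
        prob = config$category_proportions
      )
    }
    bad <- setdiff(cats_avail, c("Lo", "Int", "Hi", "IntHi"))
    if (length(bad)) abort(paste0("unknown categories: ", paste(bad, collapse = ", ")))
    true_category <- factor(cat_vec, levels = intersect(
      c("Lo", "Int", "Hi", "IntHi"), cats_avail
    ))

    # (b) mean percentile uniform within the category band. Rescoring via
    # the inverse transform ceils percentiles to the reference grid (at
    # most 100/n_ref points up), so the draw stops one grid step short of
    # each closed upper band edge: the round trip then reproduces the
    # sampled category exactly.
    g <- 100 / length(ref[[1]])
    band_lo <- c(Lo = 0, Int = 25, Hi = 70, IntHi = 25)[cat_vec]
    band_hi <- c(Lo = 25 - g, Int = 70 - g, Hi = 100, IntHi = 100)[cat_vec]
    m <- runif(n, band_lo, band_hi)

    # (c) four percentiles with exact mean m: centered Gaussian
    # perturbations, shrunk just enough to stay inside [0, 100]
    e <- matrix(rnorm(4 * n, sd = config$perturbation_sd), ncol = 4)
    e <- e - rowMeans(e)
    pos <- pmax(apply(e, 1, max), 1e-12)
    neg <- pmax(-apply(e, 1, min), 1e-12)
    s <- pmin(1, (100 - m) / pos, m / neg)
    p <- pmin(pmax(m + s * e, 0), 100) # clamp float round-off at the edges
    colnames(p) <- c("pct_cd3_ct", "pct_cd3_im", "pct_cd8_ct", "pct_cd8_im")

    # (d) densities by inverse-percentile lookup
    d_cd3_ct <- inverse_percentile_density(p[, 1], "CD3", "CT", ref)
    d_cd3_im <- inverse_percentile_density(p[, 2], "CD3", "IM", ref)
    d_cd8_ct <- inverse_percentile_density(p[, 3], "CD8", "CT", ref)
    d_cd8_im <- inverse_percentile_density(p[, 4], "CD8", "IM", ref)

    # (e) outcome processes: recurrence, death, censoring
    lam <- category_hazards(config)
    r_time <- numeric(n)
    for (cname in names(lam)) {
      idx <- which(cat_vec == cname)
      r_time[idx] <- r_event_times(length(idx), lam[[cname]], config$weibull_shape)
    }
    d0 <- if (config$death_hazard > 0) rexp(n, config$death_hazard) else rep(Inf, n)
    post <- if (config$post_recurrence_death_hazard > 0) {
      rexp(n, config$post_recurrence_death_hazard)
    } else {
      rep(Inf, n)
    }
    win <- censoring_window(config)
    cens <- if (win[1] == win[2]) rep(win[1], n) else runif(n, win[1], win[2])

    death_latent <- pmin(d0, r_time + post)
    recurrence_observed <- r_time < pmin(d0, cens)
    recurrence_time <- pmin(r_time, d0, cens)
    death_observed <- death_latent < cens
    death_time <- pmin(death_latent, cens)

    # (f) covariates from marginal prevalences
    cv <- config$covariates
    stage <- ifelse(runif(n) < cv$stage2, "II", "I")
    t_stage <- character(n)
    i1 <- stage == "I"
    t_stage[i1] <- sample(names(cv$t_within_stage1), sum(i1),
      replace = TRUE, prob = cv$t_within_stage1
    )
    t_stage[!i1] <- sample(names(cv$t_within_stage2), sum(!i1),
      replace = TRUE, prob = cv$t_within_stage2
    )
    msi <- ifelse(runif(n) < cv$msi_known,
      ifelse(runif(n) < cv$msi_of_known, "MSI", "MSS"), "unknown"
    )
    velipi <- ifelse(runif(n) < cv$velipi_unknown, "unknown",
      ifelse(runif(n) < cv$velipi, "positive", "negative")
    )
    diff_grade <- ifelse(runif(n) < cv$differentiation_unknown, "unknown",
      ifelse(runif(n) < cv$poor_differentiation, "poor", "well/moderate")
    )
    chemo <- runif(n) < ifelse(stage == "II", cv$chemo_stage2, cv$chemo_stage1)

    tibble::tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      cohort = ifelse(runif(n) < config$cohort_split, 1L, 2L),
      center = factor(
        sample(sprintf("C%02d", seq_len(config$n_centers)), n, replace = TRUE)
      ),
      gender = ifelse(runif(n) < cv$male, "male", "female"),
      age = round(pmin(pmax(rnorm(n, cv$age_mean, cv$age_sd), 25), 99)),
      stage = factor(stage, levels = c("I", "II")),
      t_stage = factor(t_stage, levels = c("T1", "T2", "T3", "T4")),
      n_stage = 0L,
      sidedness = ifelse(runif(n) < cv$right_sided, "right", "left"),
      msi = factor(msi, levels = c("MSS", "MSI", "unknown")),
      velipi = factor(velipi, levels = c("negative", "positive", "unknown")),
      differentiation = factor(diff_grade,
        levels = c("well/moderate", "poor", "unknown")
      ),
      perforation = runif(n) < cv$perforation,
      ln_examined = pmax(1L, stats::rnbinom(n, size = cv$ln_size, mu = cv$ln_mean)),
      chemotherapy = chemo,
      preoperative_treatment = runif(n) < config$preop_fraction,
      true_category = true_category,
      true_mean_percentile = m,
      density_cd3_ct = d_cd3_ct,
      density_cd3_im = d_cd3_im,
      density_cd8_ct = d_cd8_ct,
      density_cd8_im = d_cd8_im,
      intensity_cd3 = pmax(0, rnorm(n, config$intensity_mean, config$intensity_sd)),
      intensity_cd8 = pmax(0, rnorm(n, config$intensity_mean, config$intensity_sd)),
      recurrence_time = recurrence_time,
      recurrence_observed = recurrence_observed,
      death_time = death_time,
      death_observed = death_observed,
      censor_time = cens
    )
  })
}

#' Read and write cohort tables
#'
#' Cohorts are exchanged as plain tab-separated text (UTF-8, `.` decimal
#' separator, fixed header), one row per patient.
#'
#' @param data A cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a tibble with factor columns restored.
#' @export
write_cohort <- function(data, path) {
  utils::write.table(data, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- tibble::as_tibble(utils::read.table(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, fileEncoding = "UTF-8"
  ))
  factor_specs <- list(
    stage = c("I", "II"), t_stage = c("T1", "T2", "T3", "T4"),
    msi = c("MSS", "MSI", "unknown"),
    velipi = c("negative", "positive", "unknown"),
    differentiation = c("well/moderate", "poor", "unknown"),
    true_category = c("Lo", "Int", "Hi", "IntHi"), is3 = c("Lo", "Int", "Hi"),
    is2 = c("Lo", "IntHi"), is5 = c("I0", "I1", "I2", "I3", "I4")
  )
  for (col in intersect(names(factor_specs), names(out))) {
    out[[col]] <- factor(out[[col]], levels = factor_specs[[col]])
  }
  if ("center" %in% names(out)) out$center <- factor(out$center)
  out
}
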