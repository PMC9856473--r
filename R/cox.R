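#' Cox proportional-hazards model, optionally stratified by center
#'
#' Maximizes the (stratified) Cox partial likelihood by Newton-Raphson with
#' step-halving. Tied event times are handled by the Efron approximation by
#' default (Breslow available for cross-checks). Stratification by the
#' participating center gives each stratum its own baseline hazard while
#' sharing the regression coefficients, the design used for all
#' between-center adjustment in the analysis.
#'
#' @param data A data frame, one row per patient.
#' @param time,event Unquoted outcome columns (months, logical/0-1).
#' @param terms Character vector of covariate column names. Factors are
#'   expanded to treatment-contrast dummies against their first level;
#'   columns constant within every stratum are dropped with a message.
#' @param strata Optional name of a stratification column (e.g.
#'   `"center"`), or `NULL` for an unstratified fit.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param max_iter,tol Newton iteration cap and convergence tolerance on
#'   the largest coefficient update.
#' @return An object of class `til_cox` with coefficients, the inverse
#'   observed information as `vcov`, partial log-likelihoods at the null
#'   and the optimum, the per-patient linear predictor, and bookkeeping for
#'   [wald_test()], [lr_test()] and [chi2_importance()]. Monotone
#'   likelihood (complete separation) is flagged via `converged = FALSE`
#'   with a warning, never returned silently.
#' @examples
#' cfg <- generator_config(n_patients = 300, seed = 2)
#' cohort <- derive_endpoints(score_cohort(generate_cohort(cfg), default_reference()))
#' fit <- cox_fit(cohort, ttr_time, ttr_event, terms = "is3", strata = "center")
#' tidy(fit, exponentiate = TRUE)
#' @export
cox_fit <- function(data, time, event, terms, strata = NULL,
                    ties = c("efron", "breslow"),
                    max_iter = 50, tol = 1e-9) {
  ties <- match.arg(ties)
  t <- dplyr::pull(data, {{ time }})
  e <- as.logical(dplyr::pull(data, {{ event }}))
  if (anyNA(t) || anyNA(e)) abort("missing outcome values")
  missing_terms <- setdiff(terms, names(data))
  if (length(missing_terms)) {
    abort(paste0("terms not in data: ", paste(missing_terms, collapse = ", ")))
  }
  md <- as.data.frame(data[terms])
  for (j in seq_along(md)) {
    if (is.character(md[[j]]) || is.logical(md[[j]])) md[[j]] <- factor(md[[j]])
    if (is.factor(md[[j]])) md[[j]] <- droplevels(md[[j]])
  }
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  mm <- stats::model.matrix(form, md)
  assign_map <- attr(mm, "assign")[-1]
  x <- mm[, -1, drop = FALSE]
  s <- if (is.null(strata)) {
    factor(rep(1L, length(t)))
  } else {
    factor(dplyr::pull(data, !!rlang::sym(strata)))
  }
  s <- droplevels(s)

  # drop columns without variation inside any stratum (no information)
  keep <- vapply(seq_len(ncol(x)), function(j) {
    any(tapply(x[, j], s, function(v) length(unique(v)) > 1))
  }, logical(1))
  if (!all(keep)) {
    inform(paste0(
      "dropping constant terms: ",
      paste(colnames(x)[!keep], collapse = ", ")
    ))
    assign_map <- assign_map[keep]
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0) abort("no usable covariates after dropping constants")
  if (sum(e) == 0) abort("no events")

  fit <- cox_newton(x, t, e, s, ties, max_iter, tol)
  structure(
    list(
      coefficients = setNames(fit$beta, colnames(x)),
      vcov = fit$vcov,
      loglik = fit$loglik, # c(null, final)
      n = length(t), n_events = sum(e),
      term_labels = terms, assign = assign_map,
      strata = strata, ties = ties,
      iter = fit$iter, converged = fit$converged,
      linear_predictor = as.numeric(x %*% fit$beta),
      time = t, event = e
    ),
    class = "til_cox"
  )
}

revcumsum <- function(m) {
  if (is.null(dim(m))) {
    return(rev(cumsum(rev(m))))
  }
  apply(m, 2, function(col) rev(cumsum(rev(col))))
}

# pre-sort each stratum once; returns list of per-stratum layouts
cox_layout <- function(x, t, e, s) {
  lapply(split(seq_along(t), s), function(idx) {
    o <- idx[order(t[idx])]
    ts <- t[o]
    es <- e[o]
    ev_times <- unique(ts[es])
    if (length(ev_times) == 0) {
      return(NULL)
    }
    # first position at risk for each event time (all with time >= tj)
    first_pos <- findInterval(ev_times, ts, left.open = TRUE) + 1
    death_sets <- lapply(ev_times, function(tt) which(ts == tt & es))
    list(
      x = x[o, , drop = FALSE], first_pos = first_pos,
      death_sets = death_sets
    )
  })
}

# log partial likelihood, score and information at beta
cox_eval <- function(layouts, beta, ties) {
  p <- length(beta)
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (lay in layouts) {
    if (is.null(lay)) next
    xs <- lay$x
    eta <- as.numeric(xs %*% beta)
    r <- exp(eta)
    xr <- xs * r
    rs <- revcumsum(r)
    rxs <- revcumsum(xr)
    if (is.null(dim(rxs))) rxs <- matrix(rxs, ncol = 1)
    # lower-triangular vectorization of x x^T r, reverse-cumulated
    lt <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
    xxr <- xs[, lt[, 1], drop = FALSE] * xs[, lt[, 2], drop = FALSE] * r
    rxxs <- revcumsum(xxr)
    if (is.null(dim(rxxs))) rxxs <- matrix(rxxs, ncol = 1)
    unpack <- function(v) {
      mat <- matrix(0, p, p)
      mat[cbind(lt[, 1], lt[, 2])] <- v
      mat[cbind(lt[, 2], lt[, 1])] <- v
      mat
    }
    for (gi in seq_along(lay$first_pos)) {
      fp <- lay$first_pos[[gi]]
      dset <- lay$death_sets[[gi]]
      d <- length(dset)
      rs0 <- rs[fp]
      rx0 <- rxs[fp, ]
      rxx0 <- unpack(rxxs[fp, ])
      ll <- ll + sum(eta[dset])
      grad <- grad + colSums(xs[dset, , drop = FALSE])
      if (ties == "breslow" || d == 1) {
        nterms <- d
        for (l in seq_len(nterms)) {
          f <- if (ties == "efron") (l - 1) / d else 0
          den <- rs0 - f * sum(r[dset])
          xb <- (rx0 - f * colSums(xr[dset, , drop = FALSE])) / den
          xxb <- (rxx0 - f * unpack_sum(xs, r, dset, lt, p)) / den
          ll <- ll - log(den)
          grad <- grad - xb
          info <- info + xxb - tcrossprod(xb)
        }
      } else {
        sr <- sum(r[dset])
        sxr <- colSums(xr[dset, , drop = FALSE])
        sxxr <- unpack_sum(xs, r, dset, lt, p)
        for (l in seq_len(d)) {
          f <- (l - 1) / d
          den <- rs0 - f * sr
          xb <- (rx0 - f * sxr) / den
          xxb <- (rxx0 - f * sxxr) / den
          ll <- ll - log(den)
          grad <- grad - xb
          info <- info + xxb - tcrossprod(xb)
        }
      }
    }
  }
  list(ll = ll, grad = grad, info = info)
}

unpack_sum <- function(xs, r, dset, lt, p) {
  v <- colSums(
    xs[dset, lt[, 1], drop = FALSE] * xs[dset, lt[, 2], drop = FALSE] *
      r[dset]
  )
  mat <- matrix(0, p, p)
  mat[cbind(lt[, 1], lt[, 2])] <- v
  mat[cbind(lt[, 2], lt[, 1])] <- v
  mat
}

cox_newton <- function(x, t, e, s, ties, max_iter, tol) {
  p <- ncol(x)
  layouts <- cox_layout(x, t, e, s)
  if (all(vapply(layouts, is.null, logical(1)))) {
    abort("no stratum contributes events to the partial likelihood")
  }
  beta <- numeric(p)
  ev <- cox_eval(layouts, beta, ties)
  ll_null <- ev$ll
  ll <- ev$ll
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(ev$info, ev$grad), error = function(err) {
      abort("singular information matrix; check for redundant covariates")
    })
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
    new_beta <- beta + step
    new_ev <- cox_eval(layouts, new_beta, ties)
    halvings <- 0
    while ((!is.finite(new_ev$ll) || new_ev$ll < ll - 1e-12) && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      new_ev <- cox_eval(layouts, new_beta, ties)
      halvings <- halvings + 1
    }
    beta <- new_beta
    ev <- new_ev
    ll <- ev$ll
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (max(abs(beta)) > 15) {
    converged <- FALSE
    warn("monotone partial likelihood (probable complete separation); estimates unreliable")
  } else if (!converged) {
    warn(paste0("Cox fit did not converge in ", iter, " iterations"))
  }
  list(
    beta = beta, vcov = solve(ev$info), loglik = c(ll_null, ll),
    iter = iter, converged = converged
  )
}

#' @export
print.til_cox <- function(x, ...) {
  cat(
    "<til_cox> n =", x$n, " events =", x$n_events,
    if (!is.null(x$strata)) paste0(" strata = ", x$strata), "\n"
  )
  print(tidy(x, exponentiate = TRUE), n = Inf)
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A [til_cox][cox_fit] object.
#' @param exponentiate Report hazard ratios instead of log-hazard ratios.
#' @param conf.level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic` (Wald z), `p.value`, `conf.low`, `conf.high`.
#' @method tidy til_cox
#' @export
tidy.til_cox <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  est <- unname(x$coefficients)
  se <- unname(sqrt(diag(x$vcov)))
  z <- est / se
  zq <- qnorm(1 - (1 - conf.level) / 2)
  lo <- est - zq * se
  hi <- est + zq * se
  if (exponentiate) {
    est <- exp(est)
    lo <- exp(lo)
    hi <- exp(hi)
  }
  tibble::tibble(
    term = names(x$coefficients), estimate = est, std.error = se,
    statistic = z, p.value = 2 * pnorm(-abs(z)),
    conf.low = lo, conf.high = hi
  )
}

#' @rdname tidy.til_cox
#' @return `glance()`: one-row tibble with sample sizes, the partial
#'   log-likelihoods, the model likelihood-ratio chi-square against the
#'   null, and Harrell's concordance of the model's linear predictor.
#' @method glance til_cox
#' @export
glance.til_cox <- function(x, ...) {
  lr <- 2 * (x$loglik[2] - x$loglik[1])
  df <- length(x$coefficients)
  cc <- concordance_core(x$time, x$event, x$linear_predictor)
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    logLik = x$loglik[2], null_logLik = x$loglik[1],
    statistic = lr, df = df,
    p.value = pchisq(lr, df, lower.tail = FALSE),
    concordance = cc$estimate
  )
}

# coefficient indices belonging to a model term
term_index <- function(fit, term) {
  ti <- match(term, fit$term_labels)
  if (is.na(ti)) abort(paste0("term '", term, "' not in fit"))
  which(fit$assign == ti)
}

#' Block Wald test of a model term
#'
#' Tests all coefficients belonging to one term (e.g. every dummy of a
#' factor) against zero using the Wald statistic
#' `b' V^{-1} b ~ chi-square(df)`.
#'
#' @param fit A [til_cox][cox_fit] object.
#' @param term Name of a term supplied to `cox_fit(terms = ...)`.
#' @return One-row tibble: `term`, `statistic`, `df`, `p.value`.
#' @export
wald_test <- function(fit, term) {
  idx <- term_index(fit, term)
  if (length(idx) == 0) abort(paste0("term '", term, "' has no coefficients in fit"))
  b <- fit$coefficients[idx]
  v <- fit$vcov[idx, idx, drop = FALSE]
  stat <- tryCatch(
    as.numeric(t(b) %*% solve(v, b)),
    error = function(err) abort("singular covariance block")
  )
  tibble::tibble(
    term = term, statistic = stat, df = length(idx),
    p.value = pchisq(stat, length(idx), lower.tail = FALSE)
  )
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' Twice the difference in maximized partial log-likelihood between a full
#' and a nested reduced model, referred to chi-square on the difference in
#' parameter count. Used to quantify how much the score adds to a model
#' already carrying the clinical covariates.
#'
#' @param full,reduced [til_cox][cox_fit] fits on the same data, endpoint
#'   and strata; `reduced`'s terms must be a subset of `full`'s.
#' @return One-row tibble: `statistic`, `df`, `p.value`.
#' @export
lr_test <- function(full, reduced) {
  if (!all(reduced$term_labels %in% full$term_labels)) {
    abort("models are not nested: reduced terms not a subset of full terms")
  }
  if (full$n != reduced$n || full$n_events != reduced$n_events ||
    !identical(full$strata, reduced$strata)) {
    abort("models must be fitted on the same data, endpoint and strata")
  }
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 0) abort("full model has fewer parameters than reduced model")
  stat <- max(0, 2 * (full$loglik[2] - reduced$loglik[2]))
  tibble::tibble(
    statistic = stat, df = df,
    p.value = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  )
}

#' Relative importance of model terms by chi-square decomposition
#'
#' Each term's block Wald chi-square is expressed as a percentage of the
#' sum over all terms, the "relative contribution to risk" display used
#' for multivariable models. By default the raw chi-square is used;
#' `subtract_df = TRUE` uses chi-square minus its degrees of freedom.
#'
#' @param fit A [til_cox][cox_fit] object.
#' @param subtract_df Use `chisq - df` instead of raw `chisq`.
#' @return A tibble of class `til_importance`: `term`, `statistic`, `df`,
#'   `importance` (percent, summing to 100).
#' @export
chi2_importance <- function(fit, subtract_df = FALSE) {
  rows <- dplyr::bind_rows(lapply(fit$term_labels, function(tm) {
    if (length(term_index(fit, tm)) == 0) {
      return(NULL)
    }
    wald_test(fit, tm)
  }))
  val <- rows$statistic - if (subtract_df) rows$df else 0
  val <- pmax(val, 0)
  total <- sum(val)
  if (total <= 0) abort("all term chi-squares are zero; importance undefined")
  out <- tibble::tibble(
    term = rows$term, statistic = rows$statistic, df = rows$df,
    importance = 100 * val / total
  )
  class(out) <- c("til_importance", class(out))
  out
}
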