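#' Kaplan-Meier estimate with Greenwood confidence intervals
#'
#' Product-limit estimator of the survival function with Greenwood's
#' variance; pointwise 95% confidence intervals are formed on the
#' log(-log) scale, which keeps them inside (0, 1).
#'
#' @param data A data frame.
#' @param time,event Unquoted column names: follow-up time (months) and
#'   event indicator (logical or 0/1).
#' @param conf.level Confidence level (default 0.95).
#' @return An object of class `til_km`: the step curve as a tibble
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`) plus `n` and `n_events`.
#' @examples
#' d <- tibble::tibble(t = c(5, 10, 15), e = c(TRUE, TRUE, TRUE))
#' km <- km_curve(d, t, e)
#' km_rate_at(km, 12)
#' @export
km_curve <- function(data, time, event, conf.level = 0.95) {
  t <- dplyr::pull(data, {{ time }})
  e <- as.logical(dplyr::pull(data, {{ event }}))
  km_compute(t, e, conf.level)
}

km_compute <- function(t, e, conf.level = 0.95) {
  if (length(t) == 0) abort("empty input: no observations")
  if (any(t < 0)) abort("negative times")
  if (anyNA(t) || anyNA(e)) abort("missing times or events")
  ut <- sort(unique(t))
  n_less <- findInterval(ut, sort(t), left.open = TRUE) # #{time < ut}
  n_risk <- length(t) - n_less
  et <- t[e]
  d <- tabulate(match(et, ut), nbins = length(ut))
  n_censor <- tabulate(match(t[!e], ut), nbins = length(ut))
  keep <- d > 0
  tj <- ut[keep]
  nj <- n_risk[keep]
  dj <- d[keep]
  surv <- cumprod(1 - dj / nj)
  # Greenwood: var(S) = S^2 * cumsum(d / (n (n - d)))
  gw_term <- ifelse(nj - dj > 0, dj / (nj * (nj - dj)), 0)
  var_s <- surv^2 * cumsum(gw_term)
  z <- qnorm(1 - (1 - conf.level) / 2)
  ci <- loglog_ci(surv, sqrt(var_s), z)
  curve <- tibble::tibble(
    time = tj, n_risk = nj, n_event = dj,
    n_censor = n_censor[keep],
    estimate = surv, std.error = sqrt(var_s),
    conf.low = ci$low, conf.high = ci$high
  )
  structure(
    list(
      curve = curve, n = length(t), n_events = sum(e),
      conf.level = conf.level,
      censor_times = tibble::tibble(time = ut, n_censor = n_censor)
    ),
    class = "til_km"
  )
}

# CI for S on the log(-log) scale; degenerate at S = 0 or 1
loglog_ci <- function(s, se, z) {
  low <- high <- s
  ok <- s > 0 & s < 1 & se > 0
  th <- z * se[ok] / (s[ok] * log(s[ok]))
  low[ok] <- s[ok]^exp(-th)
  high[ok] <- s[ok]^exp(th)
  lo <- pmin(low, high)
  hi <- pmax(low, high)
  list(low = lo, high = hi)
}

#' @rdname km_curve
#' @param km A `til_km` object.
#' @param at Evaluation time (months).
#' @param side `"left"` evaluates the curve just before `at` (events at
#'   exactly `at` excluded), `"right"` includes them. Event-free rates at
#'   five years use the left-continuous value at 60 months.
#' @return `km_rate_at()`: one-row tibble `estimate`, `std.error`,
#'   `conf.low`, `conf.high` (survival scale, 0-1).
#' @export
km_rate_at <- function(km, at, side = c("left", "right")) {
  side <- match.arg(side)
  cv <- km$curve
  idx <- if (side == "left") {
    findInterval(at, cv$time, left.open = TRUE)
  } else {
    findInterval(at, cv$time)
  }
  if (idx == 0) {
    return(tibble::tibble(
      estimate = 1, std.error = 0, conf.low = 1, conf.high = 1
    ))
  }
  cv[idx, c("estimate", "std.error", "conf.low", "conf.high")]
}

#' @export
print.til_km <- function(x, ...) {
  cat("<til_km> n =", x$n, " events =", x$n_events, "\n")
  print(x$curve, n = 6)
  invisible(x)
}

#' @method tidy til_km
#' @export
tidy.til_km <- function(x, ...) x$curve

#' Log-rank test
#'
#' The standard (unstratified) K-sample log-rank test: at each event time
#' the observed group-wise event counts are compared with their
#' hypergeometric expectations, and the accumulated observed-minus-expected
#' vector is referred to its covariance, giving a chi-square statistic on
#' K - 1 degrees of freedom.
#'
#' @inheritParams km_curve
#' @param group Unquoted grouping column (factor or character, >= 2
#'   non-empty groups).
#' @return One-row tibble: `statistic`, `df`, `p.value`.
#' @examples
#' d <- tibble::tibble(
#'   t = c(2, 4, 6, 8, 10, 12), e = TRUE,
#'   g = rep(c("a", "b"), 3)
#' )
#' logrank_test(d, t, e, g)
#' @export
logrank_test <- function(data, time, event, group) {
  t <- dplyr::pull(data, {{ time }})
  e <- as.logical(dplyr::pull(data, {{ event }}))
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  if (nlevels(g) < 2) abort("log-rank needs at least two non-empty groups")
  if (any(table(g) == 0)) abort("a group has zero observations")
  lr <- logrank_compute(t, e, g)
  tibble::tibble(
    statistic = lr$chisq, df = lr$df,
    p.value = pchisq(lr$chisq, lr$df, lower.tail = FALSE)
  )
}

logrank_compute <- function(t, e, g) {
  k <- nlevels(g)
  tj <- sort(unique(t[e]))
  m <- length(tj)
  # per-group numbers at risk and events at each event time
  n_kj <- matrix(0, m, k)
  d_kj <- matrix(0, m, k)
  for (i in seq_len(k)) {
    tk <- t[g == levels(g)[i]]
    n_kj[, i] <- length(tk) - findInterval(tj, sort(tk), left.open = TRUE)
    ek <- t[g == levels(g)[i] & e]
    d_kj[, i] <- tabulate(match(ek, tj), nbins = m)
  }
  nj <- rowSums(n_kj)
  dj <- rowSums(d_kj)
  obs <- colSums(d_kj)
  expd <- colSums((dj / nj) * n_kj)
  # covariance of the observed counts (hypergeometric)
  v <- matrix(0, k, k)
  mult <- ifelse(nj > 1, dj * (nj - dj) / (nj - 1), 0)
  for (a in seq_len(k)) {
    for (b in seq_len(a)) {
      if (a == b) {
        v[a, a] <- sum(mult * (n_kj[, a] / nj) * (1 - n_kj[, a] / nj))
      } else {
        v[a, b] <- v[b, a] <- -sum(mult * n_kj[, a] * n_kj[, b] / nj^2)
      }
    }
  }
  u <- (obs - expd)[-k]
  vk <- v[-k, -k, drop = FALSE]
  chisq <- tryCatch(
    as.numeric(t(u) %*% solve(vk, u)),
    error = function(err) {
      if (all(abs(u) < 1e-12)) 0 else abort("singular log-rank covariance")
    }
  )
  list(chisq = max(chisq, 0), df = k - 1)
}
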