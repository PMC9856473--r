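#' Restricted mean survival time
#'
#' The area under the Kaplan-Meier curve from 0 to the truncation time
#' `tau`: the average event-free time over the first `tau` months. The
#' variance is the standard nonparametric (Greenwood-type) expression
#' accumulating, at each event time before `tau`, the squared remaining
#' area times the Greenwood increment.
#'
#' @inheritParams km_curve
#' @param tau Truncation time (months); must not exceed the largest
#'   observed time (use [auto_tau()] across groups).
#' @return One-row tibble: `rmst`, `std.error`, `conf.low`, `conf.high`,
#'   `tau`.
#' @examples
#' d <- tibble::tibble(t = c(10, 20, 30, 40), e = c(TRUE, TRUE, FALSE, TRUE))
#' rmst(d, t, e, tau = 35)
#' @export
rmst <- function(data, time, event, tau, conf.level = 0.95) {
  t <- dplyr::pull(data, {{ time }})
  e <- as.logical(dplyr::pull(data, {{ event }}))
  rmst_compute(t, e, tau, conf.level)
}

rmst_compute <- function(t, e, tau, conf.level = 0.95) {
  if (tau > max(t)) {
    abort(paste0(
      "tau (", format(tau), ") exceeds the last observed time (",
      format(max(t)), "); use auto_tau() over the compared groups"
    ))
  }
  if (tau <= 0) abort("tau must be positive")
  km <- km_compute(t, e)
  cv <- km$curve[km$curve$time <= tau, , drop = FALSE]
  times <- c(0, cv$time, tau)
  surv <- c(1, cv$estimate, if (nrow(cv)) cv$estimate[nrow(cv)] else 1)
  widths <- diff(times)
  # left-continuous step integral: S just before each segment
  area <- sum(surv[-length(surv)] * widths)
  # remaining area beyond each event time, for the variance
  if (nrow(cv)) {
    seg_area <- surv[-length(surv)] * widths
    rem <- rev(cumsum(rev(seg_area)))[-1] # integral from each event time to tau
    gw <- ifelse(cv$n_risk - cv$n_event > 0,
      cv$n_event / (cv$n_risk * (cv$n_risk - cv$n_event)), 0
    )
    v <- sum(rem^2 * gw)
  } else {
    v <- 0
  }
  z <- qnorm(1 - (1 - conf.level) / 2)
  se <- sqrt(v)
  tibble::tibble(
    rmst = area, std.error = se,
    conf.low = area - z * se, conf.high = area + z * se, tau = tau
  )
}

#' @rdname rmst
#' @param group Unquoted grouping column.
#' @details `auto_tau()` implements the truncation rule used throughout:
#'   the minimum over groups of each group's largest observed time, so the
#'   restricted mean is evaluated where every group still has follow-up.
#' @return `auto_tau()`: a single time in months.
#' @export
auto_tau <- function(data, time, event, group = NULL) {
  t <- dplyr::pull(data, {{ time }})
  g <- rlang::enquo(group)
  if (rlang::quo_is_null(g)) {
    return(max(t))
  }
  gv <- factor(dplyr::pull(data, !!g))
  min(tapply(t, droplevels(gv), max))
}

#' Restricted-mean survival comparison between groups
#'
#' Per-group RMST at a common truncation time, plus each group's
#' difference versus the reference (first) level with a normal-theory
#' two-sided p-value (variances add across independent groups).
#'
#' @inheritParams rmst
#' @param group Unquoted grouping column (first factor level = reference).
#' @param tau Truncation time; `NULL` (default) applies the shortest
#'   group-maximum rule of [auto_tau()].
#' @return A tibble, one row per level: `level`, `n`, `rmst`,
#'   `std.error`, `conf.low`, `conf.high`, `rmst_diff`, `diff.low`,
#'   `diff.high`, `p.value` (difference columns `NA`/0 on the reference
#'   row), plus the `tau` used.
#' @export
rmst_difference <- function(data, time, event, group, tau = NULL,
                            conf.level = 0.95) {
  t <- dplyr::pull(data, {{ time }})
  e <- as.logical(dplyr::pull(data, {{ event }}))
  g <- droplevels(factor(dplyr::pull(data, {{ group }})))
  if (nlevels(g) < 2) abort("rmst_difference needs at least two groups")
  if (is.null(tau)) tau <- min(tapply(t, g, max))
  per <- lapply(levels(g), function(lv) {
    idx <- g == lv
    cbind(level = lv, n = sum(idx), rmst_compute(t[idx], e[idx], tau, conf.level))
  })
  per <- dplyr::bind_rows(per)
  z <- qnorm(1 - (1 - conf.level) / 2)
  ref <- per[1, ]
  diff <- per$rmst - ref$rmst
  sed <- sqrt(per$std.error^2 + ref$std.error^2)
  pval <- 2 * pnorm(-abs(diff / sed))
  per$rmst_diff <- diff
  per$diff.low <- diff - z * sed
  per$diff.high <- diff + z * sed
  per$p.value <- pval
  per$rmst_diff[1] <- 0
  per$diff.low[1] <- NA_real_
  per$diff.high[1] <- NA_real_
  per$p.value[1] <- NA_real_
  tibble::as_tibble(per)
}
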