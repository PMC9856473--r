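#' Harrell's concordance index
#'
#' The probability that, of two comparable patients, the one with the
#' higher risk score fails first. A pair is usable when the earlier time is
#' an event (or when an event and a censoring coincide, the event counts
#' as earlier); pairs of tied event times are not usable. Ties in the
#' score count 1/2. The standard error is the leave-one-subject-out
#' jackknife, with a normal-approximation confidence interval.
#'
#' @param data A data frame.
#' @param score Unquoted column: risk score (higher = fails earlier).
#' @param time,event Unquoted outcome columns.
#' @param conf.level Confidence level (default 0.95).
#' @return One-row tibble: `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `n_pairs` (usable pairs).
#' @examples
#' d <- tibble::tibble(s = c(3, 2, 1), t = c(1, 2, 3), e = c(TRUE, FALSE, TRUE))
#' c_index(d, s, t, e)
#' @export
c_index <- function(data, score, time, event, conf.level = 0.95) {
  sc <- dplyr::pull(data, {{ score }})
  t <- dplyr::pull(data, {{ time }})
  e <- as.logical(dplyr::pull(data, {{ event }}))
  concordance_core(t, e, sc, conf.level)
}

concordance_core <- function(t, e, sc, conf.level = 0.95) {
  n <- length(t)
  num_i <- numeric(n) # concordance score of pairs involving i
  den_i <- numeric(n) # usable pairs involving i
  total_num <- 0
  total_den <- 0
  for (i in which(e)) {
    later <- t > t[i] | (t == t[i] & !e)
    later[i] <- FALSE
    if (!any(later)) next
    scr <- (sc[i] > sc[later]) + 0.5 * (sc[i] == sc[later])
    w <- sum(later)
    s_sum <- sum(scr)
    total_num <- total_num + s_sum
    total_den <- total_den + w
    num_i[i] <- num_i[i] + s_sum
    den_i[i] <- den_i[i] + w
    num_i[later] <- num_i[later] + scr
    den_i[later] <- den_i[later] + 1
  }
  if (total_den == 0) abort("no usable pairs for concordance")
  cc <- total_num / total_den
  loo <- (total_num - num_i) / pmax(total_den - den_i, 1)
  se <- sqrt((n - 1) / n * sum((loo - cc)^2))
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    estimate = cc, std.error = se,
    conf.low = max(0, cc - z * se), conf.high = min(1, cc + z * se),
    n_pairs = total_den
  )
}
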