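#' Plot a Kaplan-Meier curve
#'
#' @param object A [til_km][km_curve] object.
#' @param ... Unused.
#' @return A ggplot: survival step curve with the Greenwood log(-log)
#'   confidence band.
#' @method autoplot til_km
#' @export
autoplot.til_km <- function(object, ...) {
  cv <- dplyr::bind_rows(
    tibble::tibble(
      time = 0, estimate = 1, conf.low = 1, conf.high = 1
    ),
    object$curve[, c("time", "estimate", "conf.low", "conf.high")]
  )
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf.low), linetype = "dashed") +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf.high), linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Event-free probability")
}

#' Plot per-group survival curves
#'
#' @param data Scored cohort with derived endpoints.
#' @param endpoint `"ttr"`, `"dfs"` or `"os"`.
#' @param group Grouping column name (e.g. `"is3"`).
#' @return A ggplot of grouped Kaplan-Meier step curves.
#' @export
plot_km <- function(data, endpoint = c("ttr", "dfs", "os"), group = "is3") {
  endpoint <- match.arg(endpoint)
  curves <- km_by_group(data, endpoint, group)
  starts <- tibble::tibble(
    group = unique(curves$group), time = 0, estimate = 1
  )
  ggplot2::ggplot(
    dplyr::bind_rows(curves[, c("group", "time", "estimate")], starts),
    ggplot2::aes(x = .data$time, y = .data$estimate, colour = .data$group)
  ) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Months", y = "Event-free probability",
      colour = group, title = toupper(endpoint)
    )
}

#' Plot a chi-square importance breakdown
#'
#' @param object A [til_importance][chi2_importance] tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of each term's relative contribution (%).
#' @method autoplot til_importance
#' @export
autoplot.til_importance <- function(object, ...) {
  d <- dplyr::arrange(tibble::as_tibble(object), .data$importance)
  d$term <- factor(d$term, levels = d$term)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance, y = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Relative contribution to risk (%)", y = NULL)
}
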