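#' Category bands of the consensus scoring system
#'
#' The mean of the four percentiles is binned with pre-defined cut-points:
#' three levels Lo \[0, 25\], Int (25, 70\], Hi (70, 100\]; five levels
#' I0 \[0, 10\], I1 (10, 25\], I2 (25, 70\], I3 (70, 95\], I4 (95, 100\];
#' and two levels Lo \[0, 25\] vs Int+Hi (25, 100\]. Interior boundaries are
#' closed on the left band (25.0 is Lo, 25.01 is Int), matching the
#' ">"-notation of the published band definitions; a mean of exactly 25 is
#' Lo under all three schemes.
#'
#' @param mean_percentile Numeric vector in \[0, 100\].
#' @param scheme One of `"IS2"`, `"IS3"`, `"IS5"`.
#' @return A factor with levels `Lo`/`IntHi` (IS2), `Lo`/`Int`/`Hi` (IS3)
#'   or `I0`..`I4` (IS5).
#' @examples
#' classify_immunoscore(c(10, 25, 25.01, 70, 70.01, 95.01), "IS3")
#' @export
classify_immunoscore <- function(mean_percentile, scheme = c("IS3", "IS2", "IS5")) {
  scheme <- match.arg(scheme)
  x <- mean_percentile
  if (any(x < 0 | x > 100, na.rm = TRUE)) abort("mean percentile outside [0, 100]")
  is5 <- cut(x,
    breaks = c(-Inf, 10, 25, 70, 95, 100),
    labels = c("I0", "I1", "I2", "I3", "I4"), right = TRUE
  )
  switch(scheme,
    IS5 = is5,
    IS3 = coarsen_is5(is5),
    IS2 = coarsen_is3(coarsen_is5(is5))
  )
}

# I0,I1 -> Lo; I2 -> Int; I3,I4 -> Hi
coarsen_is5 <- function(is5) {
  factor(
    c(I0 = "Lo", I1 = "Lo", I2 = "Int", I3 = "Hi", I4 = "Hi")[as.character(is5)],
    levels = c("Lo", "Int", "Hi")
  )
}

# Lo -> Lo; Int,Hi -> IntHi
coarsen_is3 <- function(is3) {
  factor(
    c(Lo = "Lo", Int = "IntHi", Hi = "IntHi")[as.character(is3)],
    levels = c("Lo", "IntHi")
  )
}

#' Mean of the four marker-region percentiles
#'
#' @param p Numeric vector or matrix: exactly four percentiles per patient
#'   (a length-4 vector, or a matrix/data frame with four columns), each in
#'   \[0, 100\]. Missing values are an error: a patient with a missing
#'   channel must have been excluded by QC upstream.
#' @return Numeric vector of means.
#' @examples
#' percentile_mean(c(74, 66, 58, 91))
#' @export
percentile_mean <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)
  if (ncol(p) != 4) abort("exactly four percentiles per patient are required")
  if (anyNA(p)) abort("missing percentile: patient should have been excluded by QC")
  if (any(p < 0 | p > 100)) abort("percentiles outside [0, 100]")
  rowMeans(p)
}

#' Score a cohort of quantified slides
#'
#' Applies the full determination chain to a cohort table: each of the four
#' densities is converted to a percentile of the reference distribution, the
#' four percentiles are averaged, and the mean is classified under the
#' two-, three- and five-level schemes. Rows failing QC (when a `qc_pass`
#' column is present) are refused: exclusion must happen before scoring.
#'
#' @param data A data frame with one row per patient carrying density
#'   columns `density_cd3_ct`, `density_cd3_im`, `density_cd8_ct`,
#'   `density_cd8_im` (cells/mm^2).
#' @param ref A [til_reference][simulate_reference] object.
#' @return The input as a tibble with appended columns `pct_cd3_ct`,
#'   `pct_cd3_im`, `pct_cd8_ct`, `pct_cd8_im`, `mean_percentile`, `is2`,
#'   `is3`, `is5`.
#' @examples
#' ref <- default_reference()
#' cohort <- tibble::tibble(
#'   density_cd3_ct = c(50, 2000), density_cd3_im = c(80, 3000),
#'   density_cd8_ct = c(20, 800), density_cd8_im = c(30, 1200)
#' )
#' score_cohort(cohort, ref)
#' @export
score_cohort <- function(data, ref) {
  dens_cols <- c(
    "density_cd3_ct", "density_cd3_im",
    "density_cd8_ct", "density_cd8_im"
  )
  missing_cols <- setdiff(dens_cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing density columns: ", paste(missing_cols, collapse = ", ")))
  }
  if ("qc_pass" %in% names(data) && !all(data$qc_pass)) {
    abort("cohort contains QC-failed rows; apply exclusions before scoring")
  }
  if (anyNA(data[dens_cols])) {
    abort("missing densities; apply QC exclusions before scoring")
  }
  out <- tibble::as_tibble(data)
  out$pct_cd3_ct <- density_to_percentile(out$density_cd3_ct, "CD3", "CT", ref)
  out$pct_cd3_im <- density_to_percentile(out$density_cd3_im, "CD3", "IM", ref)
  out$pct_cd8_ct <- density_to_percentile(out$density_cd8_ct, "CD8", "CT", ref)
  out$pct_cd8_im <- density_to_percentile(out$density_cd8_im, "CD8", "IM", ref)
  out$mean_percentile <- percentile_mean(
    cbind(out$pct_cd3_ct, out$pct_cd3_im, out$pct_cd8_ct, out$pct_cd8_im)
  )
  out$is5 <- classify_immunoscore(out$mean_percentile, "IS5")
  out$is3 <- coarsen_is5(out$is5)
  out$is2 <- coarsen_is3(out$is3)
  out
}
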