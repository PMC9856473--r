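# shared fixtures, built in code

# a reference object with known values in every channel
make_ref <- function(values) {
  entries <- lapply(
    stats::setNames(
      c("CD3_CT", "CD8_CT", "CD3_IM", "CD8_IM"),
      c("CD3_CT", "CD8_CT", "CD3_IM", "CD8_IM")
    ),
    function(ch) sort(values)
  )
  structure(entries, class = "til_reference", n = length(values), seed = NA)
}

# random censored survival data for oracle comparisons
make_surv_data <- function(n, rate = 0.02, censor_frac = 0.3, groups = NULL,
                           round_digits = NULL) {
  t <- rexp(n, rate)
  if (!is.null(round_digits)) t <- round(t, round_digits) + 0.001
  tibble::tibble(
    t = t,
    e = stats::runif(n) > censor_frac,
    g = if (is.null(groups)) {
      factor(sample(c("a", "b"), n, TRUE))
    } else {
      factor(sample(groups, n, TRUE))
    },
    x = stats::rnorm(n),
    s = factor(sample(1:3, n, TRUE))
  )
}

# a slide built from explicit coordinates (no simulation)
make_slide <- function(cells, regions = default_regions()) {
  structure(list(cells = cells, regions = regions), class = "til_slide")
}

# a minimal clinical record for subgroup tests
clinical_row <- function(stage = "II", t_stage = "T3", velipi = "negative",
                         differentiation = "well/moderate", perforation = FALSE,
                         ln_examined = 20L, chemotherapy = FALSE, msi = "MSS") {
  tibble::tibble(
    stage = factor(stage, levels = c("I", "II")),
    t_stage = factor(t_stage, levels = c("T1", "T2", "T3", "T4")),
    velipi = factor(velipi, levels = c("negative", "positive", "unknown")),
    differentiation = factor(differentiation,
      levels = c("well/moderate", "poor", "unknown")
    ),
    perforation = perforation,
    ln_examined = ln_examined,
    chemotherapy = chemotherapy,
    msi = factor(msi, levels = c("MSS", "MSI", "unknown"))
  )
}
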