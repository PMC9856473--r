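test_that("region density is count over area for known coordinates", {
  # 100 CD3 cells on a grid inside the 2x2 mm (4 mm^2)... use a 2 mm^2 CT
  regions <- list(
    CT = cbind(x = c(0, 2, 2, 0), y = c(0, 0, 1, 1)), # 2 mm^2
    IM = cbind(x = c(2, 3, 3, 2), y = c(0, 0, 2, 2))
  )
  grid <- expand.grid(x = seq(0.1, 1.9, length.out = 10), y = seq(0.1, 0.9, length.out = 10))
  sl <- make_slide(
    tibble::tibble(
      x = grid$x, y = grid$y, marker = "CD3", region = "CT", intensity = 300
    ),
    regions
  )
  expect_equal(region_density(sl, "CD3", "CT"), 100 / 2)
  expect_equal(region_density(sl, "CD8", "CT"), 0)
  expect_equal(region_density(sl, "CD3", "IM"), 0)
})

test_that("cells outside the polygon are excluded, edge points included", {
  square <- list(CT = cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)), IM = NA)
  pts <- tibble::tibble(
    x = c(0.5, 0.2, 1.5, -0.1, 1.0, 0.0, 0.5),
    y = c(0.5, 0.8, 0.5, 0.5, 0.5, 0.0, 1.0),
    marker = "CD8", region = "CT", intensity = 300
  )
  # brute-force expectation: 2 interior + 3 boundary (x=1 edge, origin
  # vertex, top edge) = 5 inside, 2 outside
  sl <- make_slide(pts, square)
  expect_equal(region_density(sl, "CD8", "CT"), 5 / 1)
  inside <- point_in_polygon(pts$x, pts$y, square$CT)
  expect_equal(inside, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("missing region gives NA density and zero-area polygons error", {
  sl <- make_slide(
    tibble::tibble(
      x = 0.5, y = 0.5, marker = "CD3", region = "CT", intensity = 300
    ),
    list(CT = cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)), IM = NA)
  )
  expect_true(is.na(region_density(sl, "CD3", "IM")))
  degenerate <- make_slide(sl$cells, list(
    CT = cbind(x = c(0, 1, 2), y = c(0, 0, 0)), IM = NA
  ))
  expect_error(region_density(degenerate, "CD3", "CT"), "zero area")
})

test_that("simulated slides are deterministic Poisson point patterns", {
  s1 <- simulate_slide(c(CD3_CT = 100, CD8_IM = 50), seed = 4)
  s2 <- simulate_slide(c(CD3_CT = 100, CD8_IM = 50), seed = 4)
  expect_identical(s1$cells, s2$cells)
  empty <- simulate_slide(c(CD3_CT = 0), seed = 4)
  expect_equal(nrow(empty$cells), 0)
  expect_error(simulate_slide(c(CD3_CT = -1)), ">= 0")

  # intensity 200/mm^2 over a 5 mm^2 CT: counts ~ Poisson(1000)
  big_ct <- list(CT = cbind(x = c(0, 5, 5, 0), y = c(0, 0, 1, 1)), IM = NA)
  counts <- vapply(1:30, function(i) {
    nrow(simulate_slide(c(CD3_CT = 200), regions = big_ct, seed = i)$cells)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 30))
  expect_gt(var(counts), 1000 * 0.5) # dispersion consistent with Poisson
})

test_that("density estimation through simulated slides is unbiased", {
  big_ct <- list(CT = cbind(x = c(0, 5, 5, 0), y = c(0, 0, 1, 1)), IM = NA)
  # 2000 cells/mm^2 over 5 mm^2 = 10,000 expected cells per slide
  est <- vapply(1:20, function(i) {
    region_density(
      simulate_slide(c(CD3_CT = 2000), regions = big_ct, seed = 100 + i),
      "CD3", "CT"
    )
  }, numeric(1))
  expect_lt(abs(mean(est) / 2000 - 1), 0.02)
})

test_that("QC excludes at 152 AU inclusive and on missing regions", {
  d <- tibble::tibble(
    density_cd3_ct = c(10, 10, NA, 10),
    density_cd3_im = 10, density_cd8_ct = 10, density_cd8_im = 10,
    intensity_cd3 = c(152, 153, 300, 152.0001),
    intensity_cd8 = c(300, 153, 300, 300)
  )
  q <- qc_cohort(d)
  expect_equal(q$qc_pass, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(q$qc_reasons[1], "LOW_INTENSITY")
  expect_equal(q$qc_reasons[3], "MISSING_REGION")
  expect_equal(q$qc_reasons[2], "")
})

test_that("raising the intensity threshold never re-includes a slide", {
  set.seed(6)
  d <- tibble::tibble(
    density_cd3_ct = 10, density_cd3_im = 10,
    density_cd8_ct = 10, density_cd8_im = 10,
    intensity_cd3 = runif(200, 100, 400),
    intensity_cd8 = runif(200, 100, 400)
  )
  thresholds <- c(100, 152, 200, 300)
  excluded <- lapply(thresholds, function(th) which(!qc_cohort(d, th)$qc_pass))
  for (i in seq_along(thresholds)[-1]) {
    expect_true(all(excluded[[i - 1]] %in% excluded[[i]]))
  }
})

test_that("slides round-trip through their text serialization", {
  sl <- simulate_slide(c(CD3_CT = 80, CD8_CT = 40, CD3_IM = 60), seed = 12)
  cp <- tempfile(fileext = ".tsv")
  rp <- tempfile(fileext = ".tsv")
  write_slide(sl, cp, rp)
  back <- read_slide(cp, rp)
  expect_equal(nrow(back$cells), nrow(sl$cells))
  expect_equal(back$cells$x, sl$cells$x, tolerance = 1e-12)
  expect_equal(
    region_density(back, "CD3", "CT"),
    region_density(sl, "CD3", "CT")
  )
  q <- quantify_slide(back, "pt1")
  expect_equal(q$density_cd3_ct, region_density(sl, "CD3", "CT"))
  expect_true(is.na(q$density_cd8_im) || q$density_cd8_im >= 0)
})
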