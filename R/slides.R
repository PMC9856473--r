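#' Simulate a stained slide as a marked point pattern
#'
#' A synthetic stand-in for a digitally analyzed immunostained section:
#' each region (center of tumor `CT`, invasive margin `IM`) is a simple
#' polygon, and each marker's positive cells form a homogeneous Poisson
#' point pattern of the requested intensity inside that polygon, carrying a
#' per-cell staining intensity in arbitrary units (AU).
#'
#' @param target_densities Named numeric, `cells/mm^2` per channel, e.g.
#'   `c(CD3_CT = 500, CD3_IM = 800, CD8_CT = 200, CD8_IM = 300)`. Channels
#'   may be omitted (no cells simulated for them).
#' @param regions Named list of polygons (`matrix` with columns `x`, `y`
#'   in mm, vertices of a simple polygon, no repeated closing vertex), or
#'   `NA` for a missing region. Defaults to a 2x2 mm square CT and a
#'   rectangular IM band beside it.
#' @param intensity_mean,intensity_sd Per-cell staining intensity
#'   distribution (AU, normal truncated at 0).
#' @param seed Integer seed; identical seeds give identical slides.
#' @return An object of class `til_slide`: `list(cells = tibble(x, y,
#'   marker, region, intensity), regions = <list>)`.
#' @examples
#' sl <- simulate_slide(c(CD3_CT = 100, CD8_CT = 40), seed = 3)
#' region_density(sl, "CD3", "CT")
#' @export
simulate_slide <- function(target_densities,
                           regions = default_regions(),
                           intensity_mean = 400, intensity_sd = 60,
                           seed = 1L) {
  if (any(target_densities < 0)) abort("target densities must be >= 0")
  withr_seed(seed, {
    rows <- list()
    for (ch in names(target_densities)) {
      parts <- strsplit(ch, "_", fixed = TRUE)[[1]]
      marker <- parts[[1]]
      region <- parts[[2]]
      check_marker_region(marker, region)
      poly <- regions[[region]]
      if (is.null(poly) || !is.matrix(poly)) next
      area <- polygon_area(poly)
      n_exp <- target_densities[[ch]] * area
      n_cells <- rpois(1, n_exp)
      if (n_cells == 0) next
      pts <- sample_in_polygon(n_cells, poly)
      rows[[ch]] <- tibble::tibble(
        x = pts[, 1], y = pts[, 2],
        marker = marker, region = region,
        intensity = pmax(0, rnorm(n_cells, intensity_mean, intensity_sd))
      )
    }
    cells <- if (length(rows)) {
      dplyr::bind_rows(rows)
    } else {
      tibble::tibble(
        x = numeric(), y = numeric(), marker = character(),
        region = character(), intensity = numeric()
      )
    }
    structure(list(cells = cells, regions = regions), class = "til_slide")
  })
}

#' @rdname simulate_slide
#' @export
default_regions <- function() {
  list(
    CT = cbind(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2)),
    IM = cbind(x = c(2, 3, 3, 2), y = c(0, 0, 2, 2))
  )
}

# shoelace area of a simple polygon (mm^2)
polygon_area <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("polygon coordinates must be finite")
  j <- c(seq_len(nrow(poly))[-1], 1)
  area <- abs(sum(x * y[j] - x[j] * y)) / 2
  if (area <= 0) abort("polygon has zero area")
  area
}

# rejection-sample n uniform points inside the polygon
sample_in_polygon <- function(n, poly) {
  bx <- range(poly[, 1])
  by <- range(poly[, 2])
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    cand <- cbind(runif(m, bx[1], bx[2]), runif(m, by[1], by[2]))
    keep <- point_in_polygon(cand[, 1], cand[, 2], poly)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Point-in-polygon test (closed boundary)
#'
#' Even-odd ray casting with an explicit on-edge test: points lying exactly
#' on a polygon edge or vertex count as inside. The closed-boundary
#' convention makes density counts deterministic and testable.
#'
#' @param x,y Coordinates (vectors).
#' @param poly Vertex matrix (columns x, y), simple polygon.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]
  py <- poly[, 2]
  nv <- length(px)
  jx <- px[c(2:nv, 1)]
  jy <- py[c(2:nv, 1)]
  vapply(seq_along(x), function(i) {
    xi <- x[[i]]
    yi <- y[[i]]
    # on an edge (including vertices)?
    dx <- jx - px
    dy <- jy - py
    cross <- (xi - px) * dy - (yi - py) * dx
    within <- (xi - px) * (xi - jx) + (yi - py) * (yi - jy) <= 1e-12
    if (any(abs(cross) <= 1e-12 & within)) {
      return(TRUE)
    }
    # even-odd ray cast to the right (horizontal edges never "cross")
    crossings <- (py > yi) != (jy > yi)
    xint <- px + (yi - py) / (jy - py) * (jx - px)
    hits <- crossings & (xi < xint)
    sum(hits) %% 2 == 1
  }, logical(1))
}

#' Cell density of a marker within a region
#'
#' Counts marker-positive cells whose coordinates fall inside the region
#' polygon (boundary inclusive) and divides by the polygon area. Returns
#' `NA` when the region polygon is missing, the condition that later
#' triggers a `MISSING_REGION` exclusion.
#'
#' @param slide A [til_slide][simulate_slide].
#' @inheritParams density_to_percentile
#' @return Density in cells/mm^2, or `NA_real_`.
#' @export
region_density <- function(slide, marker, region) {
  check_marker_region(marker, region)
  poly <- slide$regions[[region]]
  if (is.null(poly) || !is.matrix(poly)) {
    return(NA_real_)
  }
  area <- polygon_area(poly)
  cells <- slide$cells[slide$cells$marker == marker, , drop = FALSE]
  if (nrow(cells) == 0) {
    return(0)
  }
  inside <- point_in_polygon(cells$x, cells$y, poly)
  sum(inside) / area
}

#' Quantify a slide into a one-row cohort record
#'
#' @param slide A [til_slide][simulate_slide].
#' @param patient_id Identifier carried through.
#' @return One-row tibble with the four densities and per-marker mean
#'   staining intensities, ready for [qc_cohort()].
#' @export
quantify_slide <- function(slide, patient_id = NA_character_) {
  dens <- lapply(mr_channels(), function(ch) {
    parts <- strsplit(ch, "_", fixed = TRUE)[[1]]
    region_density(slide, parts[[1]], parts[[2]])
  })
  names(dens) <- tolower(paste0("density_", mr_channels()))
  mi <- vapply(.markers, function(m) {
    v <- slide$cells$intensity[slide$cells$marker == m]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  tibble::tibble(
    patient_id = patient_id,
    density_cd3_ct = dens$density_cd3_ct,
    density_cd3_im = dens$density_cd3_im,
    density_cd8_ct = dens$density_cd8_ct,
    density_cd8_im = dens$density_cd8_im,
    intensity_cd3 = mi[["CD3"]],
    intensity_cd8 = mi[["CD8"]]
  )
}

#' Slide-level quality control
#'
#' Applies the study's slide exclusion rules to a quantified cohort table:
#' a patient fails QC when any of the four densities is missing
#' (`MISSING_REGION`) or when either marker's mean staining intensity is at
#' or below the threshold (`LOW_INTENSITY`; default 152 AU, with the
#' boundary value itself excluded).
#'
#' @param data Data frame with the four `density_*` columns and
#'   `intensity_cd3`, `intensity_cd8` (AU).
#' @param intensity_threshold Exclusion threshold in AU (default 152).
#' @return The input as a tibble with `qc_pass` (logical) and `qc_reasons`
#'   (comma-separated codes, `""` when passing) appended.
#' @examples
#' df <- tibble::tibble(
#'   density_cd3_ct = c(100, NA), density_cd3_im = 1, density_cd8_ct = 1,
#'   density_cd8_im = 1, intensity_cd3 = c(152, 300), intensity_cd8 = 300
#' )
#' qc_cohort(df)
#' @export
qc_cohort <- function(data, intensity_threshold = 152) {
  if (intensity_threshold < 0) abort("intensity threshold must be >= 0")
  dens_cols <- c(
    "density_cd3_ct", "density_cd3_im",
    "density_cd8_ct", "density_cd8_im"
  )
  out <- tibble::as_tibble(data)
  missing_region <- rowSums(is.na(as.matrix(out[dens_cols]))) > 0
  low_intensity <- out$intensity_cd3 <= intensity_threshold |
    out$intensity_cd8 <= intensity_threshold
  reasons <- character(nrow(out))
  reasons[low_intensity] <- "LOW_INTENSITY"
  reasons[missing_region] <- ifelse(
    reasons[missing_region] == "", "MISSING_REGION",
    paste("MISSING_REGION", reasons[missing_region], sep = ",")
  )
  out$qc_pass <- !(missing_region | low_intensity)
  out$qc_reasons <- reasons
  out
}

#' Read and write slide files
#'
#' A slide is serialized as two delimited text files: a cell table
#' (`x`, `y`, `marker`, `region`, `intensity`) and a region-polygon table
#' (`region`, `vertex`, `x`, `y`).
#'
#' @param slide A [til_slide][simulate_slide].
#' @param cells_path,regions_path File paths.
#' @return `write_slide()` returns the paths invisibly; `read_slide()`
#'   returns a `til_slide`.
#' @export
write_slide <- function(slide, cells_path, regions_path) {
  utils::write.table(slide$cells, cells_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  reg <- dplyr::bind_rows(lapply(names(slide$regions), function(rn) {
    poly <- slide$regions[[rn]]
    if (!is.matrix(poly)) {
      return(NULL)
    }
    tibble::tibble(
      region = rn, vertex = seq_len(nrow(poly)),
      x = poly[, 1], y = poly[, 2]
    )
  }))
  utils::write.table(reg, regions_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(cells_path, regions_path))
}

#' @rdname write_slide
#' @export
read_slide <- function(cells_path, regions_path) {
  cells <- tibble::as_tibble(
    utils::read.table(cells_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  )
  reg_tab <- utils::read.table(regions_path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE
  )
  regions <- lapply(split(reg_tab, reg_tab$region), function(d) {
    d <- d[order(d$vertex), ]
    cbind(x = d$x, y = d$y)
  })
  structure(list(cells = cells, regions = regions), class = "til_slide")
}
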