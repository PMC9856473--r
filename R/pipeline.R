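#' Pipeline configuration
#'
#' A nested list controlling an end-to-end run: a `generator` section
#' (arguments to [generator_config()]), a `reference` section (size and
#' seed of the percentile reference), and an `analysis` section (which
#' subgroups, endpoints and scoring schemes to analyze, the adjustment
#' set for the multivariable model, and the stratification variable).
#' Serialized as YAML.
#'
#' @return A list of class `til_pipeline_config`.
#' @export
default_config <- function() {
  structure(
    list(
      generator = list(n_patients = 1885, seed = 1L),
      reference = list(n = 1000L, seed = 20230108L),
      analysis = list(
        subgroups = subgroup_names(),
        endpoints = c("ttr", "dfs", "os"),
        groupings = c("is2", "is3"),
        strata = "center",
        adjust = c("gender", "t_stage", "n_stage", "msi"),
        very_high_rule = "and",
        rate_at = 60,
        intensity_threshold = 152
      )
    ),
    class = "til_pipeline_config"
  )
}

#' @rdname default_config
#' @param path YAML file path.
#' @param config A pipeline configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (sec in intersect(names(raw), names(cfg))) {
    for (key in names(raw[[sec]])) cfg[[sec]][[key]] <- raw[[sec]][[key]]
  }
  cfg
}

#' @rdname default_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a cohort, applies slide QC and the study
#' exclusions, scores every patient, derives the three endpoints and then,
#' for each requested subgroup x endpoint x scheme, writes the univariate
#' comparison block, a multivariable Cox summary with its chi-square
#' importance breakdown, and the per-group survival-curve export. A JSON
#' run manifest (seed, configuration hash, exclusion funnel, subgroup
#' sizes) and a plain-text log complete the output directory. Failures are
#' isolated per analysis block: the run continues and the failed blocks
#' are listed in the manifest.
#'
#' @param config A [default_config()]-shaped list.
#' @param outdir Output directory; must not exist unless `force = TRUE`.
#' @param seed Optional integer overriding `config$generator$seed`.
#' @param cohort_file Optional path to a cohort table ([write_cohort()]
#'   dialect) used instead of the synthetic generator.
#' @param force Allow writing into an existing directory.
#' @return Invisibly, a list with the scored cohort, the result tibbles
#'   and the manifest.
#' @export
run_pipeline <- function(config = default_config(), outdir, seed = NULL,
                         cohort_file = NULL, force = FALSE) {
  if (dir.exists(outdir) && !force) {
    abort(paste0("output directory exists: ", outdir, " (use force = TRUE)"))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  logline <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), paste0(...), "\n",
      file = log_path, append = TRUE
    )
  }
  if (!is.null(seed)) config$generator$seed <- as.integer(seed)
  an <- config$analysis

  ref <- simulate_reference(
    n = config$reference$n %||% 1000,
    seed = config$reference$seed %||% 20230108L
  )
  cohort <- if (!is.null(cohort_file)) {
    logline("loading cohort from ", cohort_file)
    read_cohort(cohort_file)
  } else {
    gen_cfg <- do.call(generator_config, config$generator)
    logline(
      "generating cohort: n = ", gen_cfg$n_patients,
      ", seed = ", gen_cfg$seed
    )
    generate_cohort(gen_cfg, ref)
  }

  cohort <- qc_cohort(cohort, an$intensity_threshold %||% 152)
  kept <- apply_exclusions(cohort)
  excl <- exclusion_log(kept)
  for (i in seq_len(nrow(excl))) {
    logline("exclusion funnel: ", excl$reason[i], " = ", excl$n[i])
  }
  scored <- derive_endpoints(score_cohort(kept, ref))
  write_cohort(scored, file.path(outdir, "scored_cohort.tsv"))

  results <- list()
  failures <- character()
  subgroup_sizes <- list()
  for (sg in an$subgroups) {
    sub <- filter_subgroup(scored, sg, very_high_rule = an$very_high_rule %||% "and")
    subgroup_sizes[[sg]] <- nrow(sub)
    logline("subgroup ", sg, ": n = ", nrow(sub))
    for (ep in an$endpoints) {
      for (gr in an$groupings) {
        block <- paste(sg, ep, gr, sep = "_")
        res <- tryCatch(
          {
            cmp <- compare_groups(sub, ep, gr,
              strata = an$strata,
              rate_at = an$rate_at %||% 60
            )
            utils::write.table(
              tibble::as_tibble(cmp),
              file.path(outdir, paste0("comparison_", block, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE
            )
            curves <- km_by_group(sub, ep, gr)
            utils::write.table(
              curves, file.path(outdir, paste0("km_", block, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE
            )
            mv <- cox_fit(sub, paste0(ep, "_time"), paste0(ep, "_event"),
              terms = c(gr, an$adjust), strata = an$strata
            )
            imp <- chi2_importance(mv)
            utils::write.table(
              tidy(mv, exponentiate = TRUE),
              file.path(outdir, paste0("multivariable_", block, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE
            )
            utils::write.table(
              tibble::as_tibble(imp),
              file.path(outdir, paste0("importance_", block, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE
            )
            list(comparison = cmp, multivariable = mv, importance = imp)
          },
          error = function(err) {
            logline("FAILED ", block, ": ", conditionMessage(err))
            NULL
          }
        )
        if (is.null(res)) {
          failures <- c(failures, block)
        } else {
          results[[block]] <- res
        }
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tilscore")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$generator$seed,
    config_hash = rlang::hash(config),
    cohort_file = cohort_file,
    exclusions = as.list(setNames(excl$n, excl$reason)),
    subgroup_sizes = subgroup_sizes,
    n_scored = nrow(scored),
    failed_blocks = failures
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  logline("done: ", length(results), " blocks, ", length(failures), " failures")
  invisible(list(
    cohort = scored, results = results, manifest = manifest,
    failures = failures
  ))
}
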