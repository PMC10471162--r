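#' Default pipeline configuration
#'
#' All defaults mirror the analysis settings the package implements:
#' 3 mm within-mask smoothing, windows of 20 subjects slid in steps of 5,
#' one consumed gradient component, 1000 bootstrap iterations.
#'
#' @param ... overrides for any config field. Fields: `bold` (vector of
#'   paths), `mask`, `atlas`, `atlas_labels` (TSV path with label/name
#'   columns), `covariates` (TSV path), `simulate` (list passed to
#'   [simulate_cohort()]: n_subjects, seed, ...), `fwhm_mm`,
#'   `window_length`, `step`, `behavior_scores`, `behavior_parameters`,
#'   `n_components`, `bootstrap_iterations`, `bootstrap_draw`, `seed`,
#'   `out`.
#' @return list of class `lc_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(bold = NULL, mask = NULL, atlas = NULL, atlas_labels = NULL,
              covariates = NULL, simulate = NULL,
              fwhm_mm = 3, window_length = 20L, step = 5L,
              behavior_scores = c("em_recognition", "er_reactivity"),
              behavior_parameters = NULL,
              n_components = 1L, bootstrap_iterations = 1000L,
              bootstrap_draw = 20L, seed = 1L, out = "lcgrad-out")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("Unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "lc_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @return `lc_config`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

pipeline_log <- function(dir, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  cat(line, "\n", sep = "", file = file.path(dir, "pipeline.log"), append = TRUE)
  message(line)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the gradient analysis pipeline
#'
#' Ties the stages together with fixed seeds and on-disk artifacts:
#' `simulate` (phantom cohort written as NIfTI volumes + covariate TSV +
#' truth JSON), `gradient` (per-subject and whole-group gradient NIfTIs
#' with JSON sidecars), `tsm` (bilateral trend-surface table),
#' `age`, `behavior`, `clusterability`, `groups` (statistics tables), or
#' `all`. Each run writes the resolved configuration and a log beside the
#' outputs; a stage failure leaves a `FAILED` marker naming the stage.
#'
#' @param config an [pipeline_config()], a list of fields, or a YAML path.
#' @param stages character vector of stage names, or `"all"`.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "lc_config")) config <- do.call(pipeline_config, config)
  all_stages <- c("simulate", "gradient", "tsm", "age", "behavior",
                  "clusterability", "groups")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) stopf("Unknown stage(s): %s", paste(unknown, collapse = ", "))

  # validate inputs before any compute
  if (is.null(config$simulate)) {
    for (f in c("mask", "atlas", "covariates")) {
      if (is.null(config[[f]])) stopf("Config field `%s` is required when not simulating", f)
      if (!file.exists(config[[f]])) stopf("Input file for `%s` not found: %s", f, config[[f]])
    }
    missing_bold <- config$bold[!file.exists(config$bold)]
    if (length(missing_bold)) stopf("BOLD file(s) not found: %s", paste(missing_bold, collapse = ", "))
  }

  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(config$out, "config.yaml"))
  cat("", file = file.path(config$out, "pipeline.log"))
  pipeline_log(config$out, "lcgrad %s, seed %d",
               as.character(utils::packageVersion("lcgrad")), config$seed)

  current_stage <- NULL
  result <- tryCatch({
    cohort <- NULL
    if (!is.null(config$simulate)) {
      current_stage <- "simulate"
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% config$seed
      sim_args$fwhm_mm <- config$fwhm_mm
      cohort <- do.call(simulate_cohort, sim_args)
      if ("simulate" %in% stages) {
        write_tsv(cohort$covariates, file.path(config$out, "covariates.tsv"))
        write_volume(cohort$mask, file.path(config$out, "mask.nii.gz"))
        atlas <- make_phantom_atlas(cohort$config)
        write_volume(atlas, file.path(config$out, "atlas.nii.gz"))
        write_tsv(atlas$labels, file.path(config$out, "atlas_labels.tsv"))
        jsonlite::write_json(
          list(seed = cohort$seed,
               rostral_extent = cohort$truth$rostral_extent,
               sharpness = cohort$truth$sharpness,
               effects = unclass(cohort$effects)),
          file.path(config$out, "truth.json"), auto_unbox = TRUE, digits = NA)
        pipeline_log(config$out, "simulate: %d subjects", nrow(cohort$covariates))
      }
    } else {
      current_stage <- "load"
      mask <- load_mask(config$mask)
      labels <- utils::read.delim(config$atlas_labels)
      atlas <- load_atlas(config$atlas, labels)
      covariates <- tibble::as_tibble(utils::read.delim(config$covariates))
      cohort <- cohort_from_volumes(as.list(config$bold), mask, atlas,
                                    covariates, fwhm_mm = config$fwhm_mm)
      pipeline_log(config$out, "load: %d subjects", nrow(covariates))
    }

    if ("gradient" %in% stages) {
      current_stage <- "gradient"
      grad_dir <- file.path(config$out, "gradients")
      dir.create(grad_dir, showWarnings = FALSE)
      group <- group_gradient(cohort$sims, cohort$coords)
      write_volume(group, file.path(grad_dir, "group_gradient.nii.gz"), cohort$mask)
      for (s in seq_along(cohort$sims)) {
        g <- roi_gradient(cohort$sims[[s]], cohort$coords)
        write_volume(g, file.path(grad_dir, sprintf("%s_gradient.nii.gz",
                                                    cohort$covariates$id[s])),
                     cohort$mask)
      }
      pipeline_log(config$out, "gradient: group thresholds L=%.3f R=%.3f",
                   group$thresholds["left"], group$thresholds["right"])
    }

    if ("tsm" %in% stages) {
      current_stage <- "tsm"
      fits <- lapply(cohort$sims, function(S) {
        fit_bilateral(roi_gradient(S, cohort$coords))
      })
      write_tsv(tsm_table(fits, cohort$covariates$id),
                file.path(config$out, "tsm_parameters.tsv"))
      pipeline_log(config$out, "tsm: %d subjects x 2 hemispheres", length(fits))
    }

    summary_json <- list(seed = config$seed)
    if ("age" %in% stages) {
      current_stage <- "age"
      age_res <- per_year_age_analysis(cohort, parameters = config$behavior_parameters)
      write_tsv(age_res$f_test, file.path(config$out, "age_f_test.tsv"))
      write_tsv(age_res$correlations, file.path(config$out, "age_correlations.tsv"))
      summary_json$age <- as.list(age_res$f_test)
      pipeline_log(config$out, "age: F = %.3f, p = %.4g",
                   age_res$f_test$statistic, age_res$f_test$p_value)
    }
    if ("behavior" %in% stages) {
      current_stage <- "behavior"
      for (sc in config$behavior_scores) {
        res <- window_behavior_analysis(cohort, sc,
                                        window_length = config$window_length,
                                        step = config$step,
                                        parameters = config$behavior_parameters)
        write_tsv(res$f_test, file.path(config$out, sprintf("behavior_%s_f_test.tsv", sc)))
        write_tsv(res$correlations,
                  file.path(config$out, sprintf("behavior_%s_correlations.tsv", sc)))
        summary_json[[paste0("behavior_", sc)]] <- as.list(res$f_test)
        pipeline_log(config$out, "behavior %s: F = %.3f, p = %.4g", sc,
                     res$f_test$statistic, res$f_test$p_value)
      }
    }
    if ("clusterability" %in% stages) {
      current_stage <- "clusterability"
      cl <- clusterability_vs_age(cohort)
      write_tsv(cl$subjects, file.path(config$out, "clusterability.tsv"))
      summary_json$clusterability <- list(rho = cl$rho, p_value = cl$p_value)
      pipeline_log(config$out, "clusterability: rho = %.3f, p = %.4g", cl$rho, cl$p_value)
    }
    if ("groups" %in% stages) {
      current_stage <- "groups"
      gc_res <- bootstrap_group_comparison(cohort,
                                           draw = config$bootstrap_draw,
                                           iterations = config$bootstrap_iterations,
                                           seed = config$seed)
      write_tsv(gc_res$manova, file.path(config$out, "groups_manova.tsv"))
      write_tsv(gc_res$posthoc, file.path(config$out, "groups_posthoc.tsv"))
      summary_json$groups <- as.list(gc_res$manova)
      pipeline_log(config$out, "groups: Pillai = %.3f, p = %.4g",
                   gc_res$manova$pillai, gc_res$manova$p_value)
    }
    jsonlite::write_json(summary_json, file.path(config$out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    pipeline_log(config$out, "done")
    config$out
  }, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", current_stage %||% "setup",
                       conditionMessage(e)),
               file.path(config$out, "FAILED"))
    stopf("Pipeline stage `%s` failed: %s", current_stage %||% "setup",
          conditionMessage(e))
  })
  invisible(result)
}
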