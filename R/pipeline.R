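#' Configuration for the end-to-end LAD pipeline
#'
#' Nested sections mirror the stage parameters: `simulate` (a
#' [seldi_config()] or `NULL` when `input` is given), `binning`
#' (low/high/width), `standard` (mz/window), `filter`, `patterns`,
#' `risk` (group count), `cv` (k/repeats) and a master `seed` from which
#' each stage derives its own seed (stage i uses `seed * 131 + i`).
#' Unknown keys are rejected.
#'
#' @param ... overrides of the default sections, e.g.
#'   `cv = list(k = 5, repeats = 2)`.
#' @param seed master seed.
#' @param input optional path to an existing cohort TSV or feature-matrix
#'   CSV; when given, the simulate stage is skipped.
#' @return a validated list of class `"lad_pipeline_config"`.
#' @export
lad_pipeline_config <- function(..., seed = 1L, input = NULL) {
  defaults <- list(
    simulate = seldi_config(),
    binning = list(low = 500, high = 12000, width = 2),
    standard = list(mz = 5734.5, window = 10),
    filter = list(homogeneity = 0.8, prevalence = 0.8),
    patterns = list(homogeneity = 0.75, prevalence = 0.3, max_degree = 2L),
    risk = list(groups = 5L),
    cv = list(k = 10L, repeats = 10L, stratified = TRUE),
    seed = seed,
    input = input
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown pipeline config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !inherits(overrides[[nm]], "seldi_config")) {
      bad <- setdiff(names(overrides[[nm]]), names(defaults[[nm]]))
      if (length(bad)) {
        stop(sprintf("unknown key(s) in section '%s': %s", nm,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      defaults[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults$seed <- as.integer(defaults$seed)
  structure(defaults, class = "lad_pipeline_config")
}

#' Run the LAD pipeline end to end
#'
#' Executes the stages in order — simulate (or load), preprocess
#' (bin/normalize/aggregate), discretize, support set, pattern
#' enumeration, model selection, prediction + risk stratification + ROC,
#' and repeated k-fold cross-validation — writing every intermediate
#' artifact to `out_dir` plus a manifest with the configuration, stage
#' seeds and artifact checksums. Reruns with the same configuration
#' produce identical checksums.
#'
#' @param config a [lad_pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @param run_cv set `FALSE` to skip the (slowest) CV stage.
#' @return the manifest, invisibly (list with `config_hash`, `seeds`,
#'   `artifacts` incl. md5 checksums, `model_summary`, `cv_summary`).
#' @export
run_lad_pipeline <- function(config = lad_pipeline_config(), out_dir,
                             run_cv = TRUE) {
  stopifnot(inherits(config, "lad_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- vapply(1:9, function(i) derive_seed(config$seed, i), integer(1))
  art <- function(name) file.path(out_dir, name)
  artifacts <- character(0)
  stage <- function(name, file, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s\nartifacts so far: %s",
                   name, conditionMessage(e),
                   paste(artifacts, collapse = ", ")), call. = FALSE)
    })
    if (!is.null(file)) artifacts <<- c(artifacts, file)
    res
  }

  # 1. cohort
  cohort <- stage("simulate", art("cohort.tsv"), function() {
    if (!is.null(config$input)) {
      co <- read_cohort(config$input)
      write_cohort(co, art("cohort.tsv"))
      co
    } else {
      sim_cfg <- config$simulate
      sim_cfg$seed <- seeds[1]
      co <- simulate_cohort(sim_cfg)
      write_cohort(co, art("cohort.tsv"), manifest = art("cohort_manifest.json"))
      co
    }
  })

  # 2. preprocess
  spec <- binning_spec(config$binning$low, config$binning$high,
                       config$binning$width)
  fm <- stage("preprocess", art("matrix.csv"), function() {
    fm <- build_feature_matrix(cohort, spec, config$standard$mz,
                               config$standard$window)
    write_feature_matrix(fm, art("matrix.csv"))
    jsonlite::write_json(fm$qc, art("qc.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    fm
  })

  # 3-6. discretize, support set, patterns, model (via the fitting front end)
  fit <- stage("train", art("model.json"), function() {
    fit <- lad(fm, positive = "rapid",
               filter_homogeneity = config$filter$homogeneity,
               filter_prevalence = config$filter$prevalence,
               pattern_homogeneity = config$patterns$homogeneity,
               pattern_prevalence = config$patterns$prevalence,
               max_degree = config$patterns$max_degree)
    write_cutpoints(fit$cutpoints, art("cuts.json"))
    write_support_set(fit$support_set, art("support.json"))
    write_patterns(c(fit$positive_patterns, fit$negative_patterns),
                   art("patterns.json"))
    write_model(fit, art("model.json"))
    artifacts <<- c(artifacts, art("cuts.json"), art("support.json"),
                    art("patterns.json"))
    fit
  })

  # 7. predictions, risk groups, ROC
  preds <- stage("predict", art("predictions.csv"), function() {
    d <- predict(fit, fm, type = "detail")
    d <- cbind(patient_id = fm$patient_ids, d, label = fm$labels)
    utils::write.csv(d, art("predictions.csv"), row.names = FALSE,
                     quote = FALSE)
    d
  })
  risk_tab <- stage("riskgroups", art("risk_groups.csv"), function() {
    tab <- risk_groups(preds$risk, fm$labels, g = config$risk$groups,
                       ids = fm$patient_ids, positive = "rapid")
    utils::write.csv(as.data.frame(tab), art("risk_groups.csv"),
                     row.names = FALSE, quote = FALSE)
    tab
  })
  roc <- stage("roc", art("roc.json"), function() {
    a <- lad_auc(preds$risk, fm$labels, positive = "rapid")
    jsonlite::write_json(list(auc = a$auc, ci = a$ci, se = a$se,
                              ci_method = a$ci_method),
                         art("roc.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    a
  })

  # 8. cross-validation
  cv <- NULL
  if (run_cv) {
    cv <- stage("crossvalidate", art("cv_report.json"), function() {
      cv <- lad_cv(fm, k = config$cv$k, repeats = config$cv$repeats,
                   seed = seeds[8], stratified = config$cv$stratified,
                   positive = "rapid",
                   filter_homogeneity = config$filter$homogeneity,
                   filter_prevalence = config$filter$prevalence,
                   pattern_homogeneity = config$patterns$homogeneity,
                   pattern_prevalence = config$patterns$prevalence,
                   max_degree = config$patterns$max_degree)
      write_cv_report(cv, art("cv_report.json"))
      utils::write.csv(cv$records, art("cv_records.csv"), row.names = FALSE,
                       quote = FALSE)
      artifacts <<- c(artifacts, art("cv_records.csv"))
      cv
    })
  }

  cfg_json <- jsonlite::toJSON(config_for_json(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_file <- tempfile(); writeLines(cfg_json, cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seeds = seeds,
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(f) list(path = basename(f),
                                        md5 = unname(tools::md5sum(f)))),
    model_summary = list(P = fit$P, N = fit$N,
                         support_masses = fit$support_set$features),
    auc = roc$auc,
    cv_summary = if (!is.null(cv)) as.data.frame(cv$summary) else NULL
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_for_json <- function(config) {
  cfg <- unclass(config)
  if (inherits(cfg$simulate, "seldi_config")) {
    cfg$simulate <- unclass(cfg$simulate)
    cfg$simulate$planted_masses <- as.list(cfg$simulate$planted_masses)
  }
  cfg
}
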