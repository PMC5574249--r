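#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the end-to-end analysis. Unknown
#' keys in any block are rejected. The global `seed` drives a named
#' sub-stream per generator, so the discovery and trial simulations are
#' independently reproducible.
#'
#' @param seed Integer global seed.
#' @param out_dir Output directory for [run_pipeline()].
#' @param discovery A [discovery_sim_config()] describing the simulated
#'   discovery cohort.
#' @param trial A [trial_sim_config()] describing the simulated trial, or
#'   `NULL` to skip trial evaluation.
#' @param preprocess Named list: `offset`, `low_signal`, `k`, `min_corr`.
#' @param build Named list: `max_size`, `min_var`.
#' @param classify Named list: `target_specificity` (threshold calibration
#'   target, default 0.73 — the published operating point; see the
#'   vignette) and `calibrate` (logical; `FALSE` keeps the fixed -0.3).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("brcaness_run_"),
                            discovery = discovery_sim_config(),
                            trial = trial_sim_config(),
                            preprocess = list(),
                            build = list(),
                            classify = list()) {
  check_block <- function(block, defaults, name) {
    unknown <- setdiff(names(block), names(defaults))
    if (length(unknown) > 0) {
      abort(paste0("Unknown key in `", name, "`: ", unknown[1]),
            class = "brcaness_config_error")
    }
    utils::modifyList(defaults, block)
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.",
          class = "brcaness_config_error")
  }
  if (!inherits(discovery, "discovery_sim_config")) {
    abort("`discovery` must come from discovery_sim_config().",
          class = "brcaness_config_error")
  }
  if (!is.null(trial) && !inherits(trial, "trial_sim_config")) {
    abort("`trial` must come from trial_sim_config() or be NULL.",
          class = "brcaness_config_error")
  }
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    discovery = discovery,
    trial = trial,
    preprocess = check_block(preprocess,
                             list(offset = 10, low_signal = 1, k = 10,
                                  min_corr = 0.5), "preprocess"),
    build = check_block(build, list(max_size = 100, min_var = 1),
                        "build"),
    classify = check_block(classify,
                           list(target_specificity = 0.73,
                                calibrate = TRUE), "classify")
  ), class = "pipeline_config")
}

#' Run the end-to-end analysis
#'
#' Executes simulate, preprocess, build (LOOCV gene-set search + DLDA),
#' classify (median centroids, threshold calibration, scoring) and, when a
#' trial configuration is present, the trial evaluation; writes every
#' result plus a manifest to `config$out_dir`. Identical configuration and
#' seed produce byte-identical outputs.
#'
#' Files written: `expression.tsv` (preprocessed cohort),
#' `annotation.tsv`, `cv_search.tsv`, `model.json`, `calls.tsv`,
#' `trial.tsv`, `evaluation.json`, `config.json`, `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param write Write outputs to disk (default TRUE).
#' @return Invisibly, a `pipeline_run` list: `cohort`, `expr`
#'   (preprocessed), `cv`, `dlda`, `dlda_confusion`, `model`, `calls`,
#'   `centroid_confusion`, `trial`, `evaluation`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), write = TRUE) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().",
          class = "brcaness_config_error")
  }
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(paste0("Pipeline stage `", name, "` failed: ",
                   conditionMessage(e)),
            class = "brcaness_pipeline_error", parent = e)
    })
  }

  # simulate
  dcfg <- config$discovery
  dcfg$seed <- dcfg$seed %||% config$seed
  cohort <- stage("simulate", simulate_discovery(dcfg))
  label <- setNames(cohort$samples$label, cohort$samples$sample_id)

  # preprocess
  pp <- config$preprocess
  expr <- stage("preprocess",
                preprocess_expression(cohort$expr, offset = pp$offset,
                                      low_signal = pp$low_signal,
                                      k = pp$k, min_corr = pp$min_corr))

  # build: variance filter, LOOCV size search, DLDA on the selection
  bd <- config$build
  cv <- stage("build", {
    keep <- variance_filter(expr, min_var = bd$min_var)
    loocv_search(expr, label, max_size = bd$max_size, genes = keep)
  })
  dlda <- stage("build", fit_dlda(expr, label, cv$selected_genes))
  dlda_calls <- dlda_posterior(dlda, expr)
  dlda_confusion <- confusion_counts(dlda_calls$call, label)

  # classify: portable centroid diagnostic (needs >= 2 genes for Pearson
  # correlation; widen a size-1 selection to the top 2 ranked genes)
  cl <- config$classify
  sig_genes <- cv$selected_genes
  if (length(sig_genes) < 2) sig_genes <- cv$ranking$gene_id[1:2]
  model <- stage("classify", {
    m <- fit_centroids(expr, label, sig_genes)
    if (isTRUE(cl$calibrate)) {
      sc <- score_samples(m, expr)
      m$threshold <- calibrate_threshold(
        sc$score, label, target_specificity = cl$target_specificity)
    }
    m
  })
  calls <- stage("classify", score_samples(model, expr))
  centroid_confusion <- confusion_counts(calls$call, label)

  # evaluate the simulated trial
  trial <- NULL
  evaluation <- NULL
  if (!is.null(config$trial)) {
    tcfg <- config$trial
    tcfg$seed <- tcfg$seed %||% config$seed
    trial <- stage("simulate", simulate_trial(tcfg))
    evaluation <- stage("evaluate", suppressMessages(evaluate_trial(trial)))
  }

  run <- structure(list(cohort = cohort, expr = expr, cv = cv,
                        dlda = dlda, dlda_confusion = dlda_confusion,
                        model = model, calls = calls,
                        centroid_confusion = centroid_confusion,
                        trial = trial, evaluation = evaluation,
                        config = config, out_dir = config$out_dir),
                   class = "pipeline_run")
  if (write) write_run(run)
  invisible(run)
}

# serialise a trial_evaluation to plain lists for JSON
evaluation_to_list <- function(ev) {
  glance_it <- function(it) {
    if (is.null(it)) return(NULL)
    list(lr_stat = it$lr_stat, df = it$df, p_value = it$p_value,
         n_used = it$n_used, n_dropped = it$n_dropped,
         covariates = as.list(it$covariates),
         coefficients = as.data.frame(it$coefficients))
  }
  out <- list(arms = as.data.frame(ev$arms),
              interaction = purrr::compact(map(ev$interaction, glance_it)),
              characteristics = as.data.frame(ev$characteristics))
  if (!is.null(ev$subset_or)) {
    out$subset_or <- list(rules = as.data.frame(ev$subset_or$rules),
                          prevalence_gain_pct =
                            ev$subset_or$prevalence_gain_pct)
  }
  out
}

write_run <- function(run) {
  dir.create(run$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(run$out_dir, f)
  write_expression_tsv(run$expr, p("expression.tsv"))
  write_annotation_tsv(run$cohort$samples, p("annotation.tsv"))
  write_tsv_full(run$cv$results, p("cv_search.tsv"))
  write_signature_model(run$model, p("model.json"))
  write_tsv_full(run$calls, p("calls.tsv"))
  if (!is.null(run$trial)) {
    write_trial_tsv(run$trial, p("trial.tsv"))
    jsonlite::write_json(evaluation_to_list(run$evaluation),
                         p("evaluation.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  strip_class <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip_class) else x
  }
  cfg <- strip_class(run$config)
  cfg$out_dir <- NULL  # location-dependent, not part of the run identity
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  manifest <- list(
    package = "brcaness",
    version = as.character(packageVersion("brcaness")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = run$config$seed,
    config_hash = rlang::hash(cfg),
    selected_size = run$cv$selected_size,
    threshold = run$model$threshold)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(run$out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$cv)
  cm <- confusion_metrics(x$centroid_confusion)
  cat(sprintf(
    "centroid diagnostic (threshold %.3f): sensitivity %.1f%%, specificity %.1f%%\n",
    x$model$threshold, 100 * cm$sensitivity, 100 * cm$specificity))
  if (!is.null(x$evaluation)) {
    fmt_p <- function(it) {
      if (is.null(it)) "not estimable" else format(it$p_value, digits = 3)
    }
    cat(sprintf(
      "trial: OR %.2f (experimental) / %.2f (control), interaction p = %s (HR-adjusted %s)\n",
      x$evaluation$arms$or[1], x$evaluation$arms$or[2],
      fmt_p(x$evaluation$interaction$unadjusted),
      fmt_p(x$evaluation$interaction$hr_adjusted)))
  }
  cat("outputs:", x$out_dir, "\n")
  invisible(x)
}
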