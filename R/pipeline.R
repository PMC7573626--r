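# End-to-end pipeline: simulate -> classify -> clones -> survival -> fit ->
# predict -> evaluate, with versioned outputs and a hash manifest.
# Each stage draws its randomness from a sub-seed derived by hashing the
# stage name together with the global seed, so adding or removing a stage
# never perturbs the random streams of the others.

PIPELINE_STAGES <- c("simulate", "classify", "clones", "survival", "fit",
                     "predict", "evaluate")

#' Default pipeline configuration
#'
#' @param seed global seed; every stage derives its own sub-seed from it.
#' @param n_train,n_validate sizes of the simulated training and validation
#'   cohorts.
#' @param stages subset of
#'   `simulate, classify, clones, survival, fit, predict, evaluate`,
#'   run in that order.
#' @param family baseline hazard family for the multistate fit.
#' @param endpoint endpoint for the survival and evaluation stages.
#' @param group_by classification column for group-wise survival curves.
#' @param n_boot bootstrap resamples in the evaluation stage.
#' @param horizons prediction horizons (months) for the strategy table.
#' @param rel_threshold dominant-tier cut for the clonality stage.
#' @param generator_overrides named list merged into
#'   [default_generator_config()].
#' @param profiles list of patient profiles for the predict stage; defaults
#'   to two contrasting hypothetical patients (25-year-old women with white
#'   cell counts 10 and 100 x 1e9/L, genotype categories 1 and 5).
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, n_train = 500, n_validate = 200,
                               stages = PIPELINE_STAGES,
                               family = "exponential", endpoint = "LFS",
                               group_by = "eln_dnmt3a", n_boot = 200,
                               horizons = c(24, 60), rel_threshold = 0.67,
                               generator_overrides = list(),
                               profiles = NULL) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  if (is.null(profiles)) {
    profiles <- list(
      list(label = "category1_low_wcc", age = 25, sex = "female",
           wcc = 10, category = 1),
      list(label = "category5_high_wcc", age = 25, sex = "female",
           wcc = 100, category = 5)
    )
  }
  structure(list(seed = as.integer(seed), n_train = n_train,
                 n_validate = n_validate,
                 stages = PIPELINE_STAGES[PIPELINE_STAGES %in% stages],
                 family = family, endpoint = endpoint, group_by = group_by,
                 n_boot = n_boot, horizons = horizons,
                 rel_threshold = rel_threshold,
                 generator_overrides = generator_overrides,
                 profiles = profiles),
            class = "run_config")
}

pipeline_log <- function(log_path, stage, msg) {
  line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order inside `output_dir`,
#' logging to console and `pipeline.log`, and writes `manifest.json` listing
#' every produced file with its md5 hash plus a config snapshot. A rerun
#' with the same config and seed reproduces byte-identical outputs. A stage
#' failure halts the run with the failing stage named; the manifest then
#' carries a `FAILED` marker for that stage.
#'
#' @param config a [default_run_config()] list.
#' @param output_dir writable output directory (created if absent).
#' @return Invisibly, the manifest (also written as JSON).
#' @export
run_pipeline <- function(config = default_run_config(), output_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(output_dir)) {
    ok <- tryCatch(dir.create(output_dir, recursive = TRUE),
                   warning = function(w) FALSE)
    if (!isTRUE(ok)) stop("cannot create output directory: ", output_dir,
                          call. = FALSE)
  }
  if (file.access(output_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", output_dir, call. = FALSE)
  }
  log_path <- file.path(output_dir, "pipeline.log")
  cat("", file = log_path)
  manifest <- list(config = unclass(config),
                   config_hash = config_hash(unclass(config)),
                   stages = list(), files = list())
  produced <- character(0)
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(invisible(NULL))
    pipeline_log(log_path, stage, "starting")
    res <- tryCatch(fun(derive_seed(config$seed, stage)), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[stage]] <<- "FAILED"
      manifest$files <<- manifest_files(produced)
      jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           force = TRUE)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    produced <<- c(produced, res)
    manifest$stages[[stage]] <<- "ok"
    pipeline_log(log_path, stage, "done")
  }
  manifest_files <- function(paths) {
    lapply(unique(paths), function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  }
  need_cohort <- function() {
    if (is.null(state$train)) {
      cp <- file.path(output_dir, "train_clinical.tsv")
      mp <- file.path(output_dir, "train_mutations.tsv")
      if (!file.exists(cp)) {
        stop("no simulated cohort available; include the 'simulate' stage ",
             "or place cohort tables in the output directory")
      }
      state$train <- read_cohort(cp, mp)
    }
    state$train
  }

  run_stage("simulate", function(seed) {
    gc_train <- do.call(default_generator_config,
                        c(list(n_patients = config$n_train, seed = seed),
                          config$generator_overrides))
    state$train <- generate_cohort(gc_train)
    gc_val <- do.call(default_generator_config,
                      c(list(n_patients = config$n_validate,
                             seed = derive_seed(seed, "validation")),
                        config$generator_overrides))
    state$validate <- generate_cohort(gc_val)
    c(write_cohort(state$train,
                   file.path(output_dir, "train_clinical.tsv"),
                   file.path(output_dir, "train_mutations.tsv")),
      write_cohort(state$validate,
                   file.path(output_dir, "validate_clinical.tsv"),
                   file.path(output_dir, "validate_mutations.tsv")))
  })

  run_stage("classify", function(seed) {
    state$classification <- classify_cohort(need_cohort())
    write_tsv(state$classification,
              file.path(output_dir, "classification.tsv"))
  })

  run_stage("clones", function(seed) {
    cohort <- need_cohort()
    out1 <- write_tsv(call_clonality_cohort(cohort, config$rel_threshold),
                      file.path(output_dir, "clonality.tsv"))
    out2 <- write_tsv(enumerate_subtypes(cohort, config$rel_threshold),
                      file.path(output_dir, "clonal_subtypes.tsv"))
    bubble <- bubble_diagram_data(cohort, config$rel_threshold)
    out3 <- file.path(output_dir, "bubble_diagram.json")
    jsonlite::write_json(bubble, out3, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    c(out1, out2, out3)
  })

  run_stage("survival", function(seed) {
    cohort <- need_cohort()
    if (is.null(state$classification)) {
      state$classification <- classify_cohort(cohort)
    }
    rec <- derive_endpoints(cohort, endpoints = config$endpoint)
    grp <- state$classification[[config$group_by]][
      match(rec$patient_id, state$classification$patient_id)]
    paths <- character(0)
    for (g in unique(grp)) {
      km <- km_estimate(rec[grp == g, , drop = FALSE])
      paths <- c(paths, write_tsv(
        as.data.frame(km),
        file.path(output_dir, sprintf("km_%s_%s.tsv", config$endpoint, g))))
    }
    lr <- logrank_test(rec, group = grp)
    out <- file.path(output_dir, "logrank.json")
    jsonlite::write_json(list(endpoint = config$endpoint,
                              group_by = config$group_by,
                              statistic = lr$statistic, df = lr$df,
                              p_value = lr$p_value),
                         out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    c(paths, out)
  })

  run_stage("fit", function(seed) {
    state$model <- fit_multistate(need_cohort(), family = config$family)
    out <- file.path(output_dir, "multistate_model.json")
    jsonlite::write_json(
      list(family = state$model$family,
           transitions = lapply(state$model$transitions, function(f) {
             list(lambda0 = f$lambda0, gamma = f$gamma, beta = as.list(f$beta),
                  events = f$events, n = f$n, loglik = f$loglik,
                  iterations = f$iterations, grad_norm = f$grad_norm,
                  zero_events = f$zero_events)
           })),
      out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out
  })

  run_stage("predict", function(seed) {
    if (is.null(state$model)) stop("the 'fit' stage must run before 'predict'")
    paths <- character(0)
    for (prof in config$profiles) {
      for (strat in c("hsct_cr1", "no_hsct")) {
        occ <- predict_occupancy(state$model, prof, strategy = strat)
        paths <- c(paths, write_tsv(
          as.data.frame(occ),
          file.path(output_dir,
                    sprintf("occupancy_%s_%s.tsv", prof$label, strat))))
      }
      cmp <- compare_strategies(state$model, prof, horizons = config$horizons)
      paths <- c(paths, write_tsv(
        cmp, file.path(output_dir,
                       sprintf("strategies_%s.tsv", prof$label))))
    }
    paths
  })

  run_stage("evaluate", function(seed) {
    if (is.null(state$validate)) {
      stop("the 'simulate' stage must run before 'evaluate'")
    }
    tv <- train_validate(need_cohort(), state$validate,
                         family = config$family, endpoint = config$endpoint,
                         n_boot = config$n_boot, seed = seed)
    out <- file.path(output_dir, "evaluation.json")
    as_rep <- function(cmp) {
      list(c_model = cmp$c_model, c_baseline = cmp$c_baseline,
           delta = cmp$delta, delta_relative = cmp$delta_relative,
           delta_se = cmp$delta_se, p_value = cmp$p_value,
           n_boot = cmp$n_boot)
    }
    jsonlite::write_json(list(train = as_rep(tv$train),
                              validation = as_rep(tv$validation)),
                         out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    txt <- file.path(output_dir, "evaluation_summary.txt")
    lines <- c(
      "Concordance comparison (multistate model vs ELN 2017 baseline)",
      sprintf("  training:   C_model = %.4f  C_ELN = %.4f  delta = %+.4f  p = %s",
              tv$train$c_model, tv$train$c_baseline, tv$train$delta,
              format(tv$train$p_value)),
      sprintf("  validation: C_model = %.4f  C_ELN = %.4f  delta = %+.4f  p = %s",
              tv$validation$c_model, tv$validation$c_baseline,
              tv$validation$delta, format(tv$validation$p_value))
    )
    writeLines(lines, txt)
    c(out, txt)
  })

  manifest$files <- manifest_files(produced)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
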