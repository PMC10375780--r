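#' Pipeline configuration
#'
#' One config that drives the whole workflow: generate a synthetic cohort,
#' pre-process, impute, benchmark AAO models, and train/evaluate the
#' driving-capability GRU. Each stage can be toggled; a single global seed
#' fans out deterministically to every stage through a documented
#' stage-name hash, so stages can be re-run in isolation.
#'
#' @param generator An [generator_config()].
#' @param stages Character vector of enabled stages, in order, among
#'   `generate`, `preprocess`, `impute`, `aao`, `driving`.
#' @param seed Global seed.
#' @param out_dir Output directory (`NULL` keeps everything in memory).
#' @param missing_threshold,cap_params Passed to [preprocess()].
#' @param cascade Passed to [run_cascade()] as control.
#' @param aao_k CV folds for the AAO benchmark.
#' @param gru An [gru_config()] template for the driving stage.
#' @param train_frac Holdout training fraction.
#' @return A list of class `hd_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            stages = c("generate", "preprocess", "impute",
                                       "aao", "driving"),
                            seed = 1L, out_dir = NULL,
                            missing_threshold = 0.69,
                            cap_params = cap_parameters(),
                            cascade = cascade_control(),
                            aao_k = 10, gru = gru_config(),
                            train_frac = 0.8) {
  known <- c("generate", "preprocess", "impute", "aao", "driving")
  if (!all(stages %in% known)) abort("unknown stage name")
  structure(list(generator = generator, stages = stages, seed = as.integer(seed),
                 out_dir = out_dir, missing_threshold = missing_threshold,
                 cap_params = cap_params, cascade = cascade, aao_k = aao_k,
                 gru = gru, train_frac = train_frac),
            class = "hd_pipeline_config")
}

#' Deterministic per-stage seed derivation
#'
#' `(seed * 31 + sum of the stage name's character codes) mod 2^28`, so the
#' derived seeds stay well inside the 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 31 + sum(utf8ToInt(stage))) %% 2^28)
}

#' Run the end-to-end workflow
#'
#' Executes the enabled stages in order and returns a manifest (stage
#' status, seeds, wall time, output summaries) plus all stage results. A
#' stage failure is recorded and downstream stages are skipped.
#'
#' @param config An [pipeline_config()].
#' @return A list of class `hd_run` with `manifest` (tibble) and `results`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  res <- list()
  rows <- list()
  failed <- FALSE
  run_stage <- function(name, fun) {
    if (failed || !(name %in% config$stages)) {
      status <- if (failed) "skipped" else "disabled"
      rows[[length(rows) + 1L]] <<- tibble(
        stage = name, status = status, seed = stage_seed(config$seed, name),
        seconds = NA_real_)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(stage_seed(config$seed, name)), error = identity)
    secs <- proc.time()[["elapsed"]] - t0
    if (inherits(out, "error")) {
      failed <<- TRUE
      rows[[length(rows) + 1L]] <<- tibble(
        stage = name, status = paste("failed:", conditionMessage(out)),
        seed = stage_seed(config$seed, name), seconds = secs)
    } else {
      res[[name]] <<- out
      rows[[length(rows) + 1L]] <<- tibble(
        stage = name, status = "ok", seed = stage_seed(config$seed, name),
        seconds = secs)
    }
  }
  run_stage("generate", function(s) {
    gen <- config$generator
    gen$seed <- s
    sim <- generate_cohort(gen)
    if (!is.null(config$out_dir)) write_cohort(sim, file.path(config$out_dir, "cohort"))
    sim
  })
  run_stage("preprocess", function(s) {
    preprocess(as_cohort_table(res$generate),
               missing_threshold = config$missing_threshold,
               cap_params = config$cap_params)
  })
  run_stage("impute", function(s) {
    run_cascade(res$preprocess, seed = s, control = config$cascade)
  })
  run_stage("aao", function(s) {
    purrr::map(c(narrow = "narrow_41_56", wide = "wide_36_59"), function(tag) {
      ds <- make_aao_dataset(res$impute$table, tag)
      evaluate_registry_cv(ds, k = config$aao_k, seed = s)
    })
  })
  run_stage("driving", function(s) {
    tensor <- build_tensor(res$impute$table)
    split <- split_holdout(tensor, config$train_frac, seed = s)
    parts <- apply_split(tensor, split)
    scaled <- scale_features(parts$train, parts$test)
    cfg <- config$gru
    cfg$seed <- s
    fit <- train_gru(scaled$train, cfg)
    ev <- evaluate_driving(fit, scaled$test)
    bands <- band_accuracy(ev$scores$score, ev$scores$label)
    list(fit = fit, evaluation = ev, bands = bands, split = split,
         scaled = scaled)
  })
  run <- structure(list(manifest = bind_rows(rows), results = res,
                        config = config), class = "hd_run")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(run$manifest, file.path(config$out_dir, "manifest.csv"),
              row.names = FALSE)
    if (!is.null(res$preprocess)) {
      log <- cohort_log(res$preprocess)
      writeLines(vapply(seq_len(nrow(log)), function(i)
        jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE),
        character(1)),
        file.path(config$out_dir, "preprocess_log.jsonl"))
      rep <- attr(res$preprocess, "reports")
      jsonlite::write_json(
        list(before = as.numeric(rep$completeness_before),
             after = as.numeric(rep$completeness_after),
             per_form = attr(rep$completeness_after, "per_form")),
        file.path(config$out_dir, "completeness_report.json"),
        auto_unbox = TRUE, digits = NA)
    }
  }
  run
}

#' Render report tables from a pipeline run
#'
#' Shapes the stage outputs into the figure/table layouts of the workflow:
#' completeness per form before/after pre-processing, imputation score
#' scatter data, the AAO comparison table, and the driving confusion / ROC /
#' calibration-band tables. Missing stage outputs yield a partial bundle
#' with notes.
#'
#' @param run An [run_pipeline()] result.
#' @param dir Optional directory to write the bundle as CSV files.
#' @return A named list of tibbles plus `notes`.
#' @export
render_reports <- function(run, dir = NULL) {
  out <- list()
  notes <- character(0)
  res <- run$results
  if (!is.null(res$preprocess)) {
    rep <- attr(res$preprocess, "reports")
    out$completeness <- tibble(
      stage = c("before", "after"),
      completeness = c(as.numeric(rep$completeness_before),
                       as.numeric(rep$completeness_after)))
    pf <- attr(rep$completeness_after, "per_form")
    if (!is.null(pf)) out$completeness_by_form <- pf
  } else notes <- c(notes, "preprocess outputs missing")
  if (!is.null(res$impute)) {
    out$imputation_scores <- as_tibble(res$impute$report)
  } else notes <- c(notes, "imputation outputs missing")
  if (!is.null(res$aao)) {
    out$aao_table <- bind_rows(lapply(res$aao, function(ev) {
      r <- rank_models(ev)
      r$cag_range_tag <- attr(ev, "cag_range_tag")
      r
    }))
  } else notes <- c(notes, "aao outputs missing")
  if (!is.null(res$driving)) {
    ev <- res$driving$evaluation
    out$driving_metrics <- ev$metrics
    out$driving_confusion <- ev$confusion
    out$driving_roc <- roc_points(ev$scores$label, ev$scores$score)
    out$driving_bands <- as_tibble(res$driving$bands)
    test_tensor <- res$driving$scaled$test
    shown <- head(test_tensor$subjid, 3)
    out$driving_trajectories <- bind_rows(lapply(shown, function(s)
      mutate(predict_trajectory(res$driving$fit, test_tensor, s,
                                res$driving$bands), subjid = s)))
  } else notes <- c(notes, "driving outputs missing")
  if (length(out) == 0) notes <- c(notes, "empty run")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
  }
  c(out, list(notes = notes))
}
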