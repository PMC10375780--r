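#' Langbehn formula parameters
#'
#' The exponential expected-AAO curve `AAO = a + exp(b - c * CAG)` with the
#' published coefficients as defaults. `c > 0` so the prediction decreases
#' in CAG length.
#'
#' @param a Offset (years).
#' @param b Exponent intercept.
#' @param c Exponent slope per repeat.
#' @return A list of class `hd_langbehn_parameters`.
#' @export
langbehn_parameters <- function(a = 21.54, b = 9.556, c = 0.146) {
  if (c <= 0) abort("c must be > 0 (prediction decreasing in CAG)")
  structure(list(a = a, b = b, c = c), class = "hd_langbehn_parameters")
}

#' Predict AAO with the Langbehn formula
#'
#' @param cag CAG repeat lengths (> 0).
#' @param params An [langbehn_parameters()] object.
#' @return Expected AAO in years.
#' @export
#' @examples
#' langbehn_predict(41)  # about 57.06 years
langbehn_predict <- function(cag, params = langbehn_parameters()) {
  if (any(cag <= 0)) abort("cag must be positive")
  params$a + exp(params$b - params$c * cag)
}

#' Refit the Langbehn formula by nonlinear least squares
#'
#' Minimises `sum((aao - a - exp(b - c * cag))^2)` starting from the
#' published coefficients, via Levenberg-Marquardt. Non-convergence is an
#' error carrying the optimiser diagnostics, never a silent fallback to the
#' initial values.
#'
#' @param cag CAG repeat lengths.
#' @param aao Observed ages at onset (years), same length, at least 10.
#' @param init Starting [langbehn_parameters()].
#' @return An object of class `hd_langbehn_fit` with elements `params`,
#'   `fit` (the `nls` object) and `convergence`.
#' @export
refit_langbehn <- function(cag, aao, init = langbehn_parameters()) {
  if (length(cag) != length(aao) || length(cag) < 10)
    abort("need at least 10 paired observations")
  df <- data.frame(cag = cag, aao = aao)
  fit <- tryCatch(
    minpack.lm::nlsLM(aao ~ a + exp(b - c * cag), data = df,
                      start = list(a = init$a, b = init$b, c = init$c),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste("Langbehn refit failed to converge:",
                                    conditionMessage(e))))
  info <- fit$convInfo
  if (!is.null(info$isConv) && !info$isConv)
    abort(paste("Langbehn refit did not converge:", info$stopMessage))
  est <- stats::coef(fit)
  structure(list(
    params = langbehn_parameters(est[["a"]], est[["b"]], est[["c"]]),
    fit = fit,
    convergence = list(iterations = info$finIter %||% NA_integer_,
                       tolerance = info$finTol %||% NA_real_,
                       converged = TRUE)),
    class = "hd_langbehn_fit")
}

#' @export
tidy.hd_langbehn_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "Estimate"],
         std.error = s[, "Std. Error"], statistic = s[, "t value"],
         p.value = s[, "Pr(>|t|)"])
}

#' @export
glance.hd_langbehn_fit <- function(x, ...) {
  tibble(sigma = summary(x$fit)$sigma,
         iterations = x$convergence$iterations,
         converged = x$convergence$converged,
         nobs = length(stats::resid(x$fit)))
}

#' @export
print.hd_langbehn_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("Langbehn fit: AAO = %.4f + exp(%.4f - %.5f * CAG)\n",
              p$a, p$b, p$c))
  invisible(x)
}

#' Assemble the AAO modelling dataset
#'
#' One row per participant with a clinically diagnosed AAO: rows whose
#' `hddiagn` came from rater substitution (provenance `inferred_rater`) are
#' discarded, `caghigh` is filtered to the tagged inclusive range (narrow
#' 41-56 or wide 36-59), and the feature set is the CAG allele lengths,
#' encoded gender, parent AAO and family history. Rows with a missing
#' feature are dropped (logged in the `n_dropped_incomplete` attribute).
#'
#' @param table An imputed `hd_cohort`.
#' @param range_tag `"narrow_41_56"` or `"wide_36_59"`.
#' @return A tibble of class `hd_aao_dataset` with attribute
#'   `cag_range_tag`; target column `hddiagn`.
#' @export
make_aao_dataset <- function(table, range_tag = c("wide_36_59", "narrow_41_56")) {
  range_tag <- match.arg(range_tag)
  rng <- if (range_tag == "narrow_41_56") c(41, 56) else c(36, 59)
  prov <- cohort_provenance(table)
  sex_cols <- grep("^sex_", names(table), value = TRUE)
  feats <- c("caglow", "caghigh", sex_cols, "parentagesx", "fhx")
  feats <- intersect(feats, names(table))
  keep <- !is.na(prov$hddiagn) & prov$hddiagn != "inferred_rater" &
    !is.na(table$caghigh) & table$caghigh >= rng[1] & table$caghigh <= rng[2]
  df <- as_tibble(table[keep, c("subjid", feats, "hddiagn")]) %>%
    distinct(.data$subjid, .keep_all = TRUE)
  n0 <- nrow(df)
  df <- df[complete.cases(df), ]
  if (nrow(df) == 0) abort("empty AAO dataset after filtering")
  attr(df, "cag_range_tag") <- range_tag
  attr(df, "features") <- feats
  attr(df, "n_dropped_incomplete") <- n0 - nrow(df)
  class(df) <- c("hd_aao_dataset", class(df))
  df
}

# -- model registry ----------------------------------------------------------

aao_feature_matrix <- function(data) {
  as.matrix(data[, attr(data, "features") %||%
                   setdiff(names(data), c("subjid", "hddiagn"))])
}

#' Default AAO model registry
#'
#' Multivariate learners compared against the Langbehn baselines: linear
#' regression, a linear support-vector regressor, a random forest,
#' k-nearest-neighbours, a single-hidden-layer perceptron, and three
#' gradient-boosted tree configurations (depth-6 and depth-3 tree boosters
#' and a DART booster).
#'
#' @return A named list of model definitions (`fit(data, seed)` /
#'   `predict(fit, data)` closures).
#' @export
default_aao_registry <- function() {
  xgb_fit <- function(...) function(data, seed) {
    xgboost::xgboost(x = aao_feature_matrix(data), y = data$hddiagn,
                     objective = "reg:squarederror", nrounds = 150,
                     learning_rate = 0.1, nthreads = 1, seed = seed,
                     verbosity = 0, ...)
  }
  xgb_pred <- function(fit, data) predict(fit, aao_feature_matrix(data))
  list(
    linear_regression = list(
      # one-hot gender columns are collinear with the intercept; lm pivots
      fit = function(data, seed) lm(hddiagn ~ ., data = data[, -1]),
      predict = function(fit, data)
        as.numeric(suppressWarnings(predict(fit, data[, -1])))),
    linear_svm = list(
      # manual standardization so constant dummies cannot trip the scaler
      fit = function(data, seed) {
        std <- standardize_train(as.data.frame(aao_feature_matrix(data)))
        list(model = e1071::svm(x = as.matrix(std$X), y = data$hddiagn,
                                kernel = "linear", type = "eps-regression",
                                scale = FALSE),
             mu = std$mu, sig = std$sig)
      },
      predict = function(fit, data) {
        X <- scale(aao_feature_matrix(data), fit$mu, fit$sig)
        as.numeric(predict(fit$model, as.matrix(X)))
      }),
    random_forest = list(
      fit = function(data, seed) {
        fit <- ranger::ranger(
          x = as.data.frame(aao_feature_matrix(data)), y = data$hddiagn,
          num.trees = 300, seed = seed, num.threads = 1)
        attr(fit, "hd_seed") <- seed
        fit
      },
      predict = function(fit, data) predict(
        fit, data = as.data.frame(aao_feature_matrix(data)),
        num.threads = 1, seed = attr(fit, "hd_seed"))$predictions),
    knn = list(
      fit = function(data, seed) {
        std <- standardize_train(as.data.frame(aao_feature_matrix(data)))
        list(model = caret::knnreg(as.matrix(std$X), data$hddiagn, k = 5),
             mu = std$mu, sig = std$sig)
      },
      predict = function(fit, data) {
        X <- scale(aao_feature_matrix(data), fit$mu, fit$sig)
        as.numeric(predict(fit$model, as.matrix(X)))
      }),
    mlp = list(
      fit = function(data, seed) {
        std <- standardize_train(as.data.frame(aao_feature_matrix(data)))
        fit <- with_local_seed(seed, nnet::nnet(
          as.matrix(std$X), data$hddiagn, size = 8, linout = TRUE,
          decay = 0.01, maxit = 500, trace = FALSE))
        list(model = fit, mu = std$mu, sig = std$sig)
      },
      predict = function(fit, data) {
        X <- scale(aao_feature_matrix(data), fit$mu, fit$sig)
        as.numeric(predict(fit$model, as.matrix(X)))
      }),
    gboost_depth6 = list(fit = xgb_fit(max_depth = 6), predict = xgb_pred),
    gboost_depth3 = list(fit = xgb_fit(max_depth = 3), predict = xgb_pred),
    gboost_dart = list(fit = xgb_fit(booster = "dart", max_depth = 6,
                                     rate_drop = 0.1),
                       predict = xgb_pred)
  )
}

#' Cross-validated evaluation of the AAO registry
#'
#' Evaluates every registry model and the two fixed-formula baselines (the
#' original Langbehn coefficients and a Langbehn curve refit on each
#' training fold) under one shared, seeded 10-fold partition, so paired
#' comparisons are meaningful. A model that fails to fit is recorded as
#' failed; the others are unaffected.
#'
#' @param dataset An [make_aao_dataset()] result.
#' @param registry Named list of model definitions.
#' @param k Number of folds.
#' @param seed Integer seed for the fold partition.
#' @return A tibble of class `hd_model_evaluation`: one row per model and
#'   fold with `mae`, `rmse`, `r2` (`NA` metrics and `failed = TRUE` for
#'   failed fits), attribute `cag_range_tag`.
#' @export
evaluate_registry_cv <- function(dataset, registry = default_aao_registry(),
                                 k = 10, seed = 1L) {
  if (length(registry) == 0) abort("registry is empty")
  n <- nrow(dataset)
  folds <- with_local_seed(seed, sample(rep_len(seq_len(k), n)))
  baselines <- list(
    langbehn_original = list(
      fit = function(data, seed) langbehn_parameters(),
      predict = function(fit, data) langbehn_predict(data$caghigh, fit)),
    langbehn_refit = list(
      fit = function(data, seed) refit_langbehn(data$caghigh, data$hddiagn),
      predict = function(fit, data)
        langbehn_predict(data$caghigh, fit$params))
  )
  all_models <- c(baselines, registry)
  res <- purrr::map_dfr(names(all_models), function(nm) {
    def <- all_models[[nm]]
    purrr::map_dfr(seq_len(k), function(f) {
      te <- folds == f
      tr_data <- dataset[!te, , drop = FALSE]
      te_data <- dataset[te, , drop = FALSE]
      attr(tr_data, "features") <- attr(dataset, "features")
      attr(te_data, "features") <- attr(dataset, "features")
      out <- tryCatch({
        fit <- def$fit(tr_data, seed + f)
        pred <- def$predict(fit, te_data)
        m <- regression_metrics(te_data$hddiagn, pred)
        tibble(model = nm, fold = f, mae = m$mae, rmse = m$rmse, r2 = m$r2,
               failed = FALSE)
      }, error = function(e) {
        tibble(model = nm, fold = f, mae = NA_real_, rmse = NA_real_,
               r2 = NA_real_, failed = TRUE)
      })
      out
    })
  })
  attr(res, "cag_range_tag") <- attr(dataset, "cag_range_tag")
  class(res) <- c("hd_model_evaluation", class(res))
  res
}

#' Rank evaluated models
#'
#' Fold-level evaluations are averaged per model and sorted by descending
#' mean R2 with mean MAE as tiebreak, rendering the benchmark-table shape
#' (model, range, MAE, RMSE, R2 with fold SDs).
#'
#' @param evals An [evaluate_registry_cv()] result (rows from several
#'   ranges can be bound together if each carries a `cag_range_tag` column).
#' @return A tibble sorted by rank.
#' @export
rank_models <- function(evals) {
  if (nrow(evals) == 0) abort("no evaluations to rank")
  tag <- attr(evals, "cag_range_tag") %||% NA_character_
  if (!"cag_range_tag" %in% names(evals)) evals$cag_range_tag <- tag
  evals %>%
    filter(!.data$failed) %>%
    group_by(.data$model, .data$cag_range_tag) %>%
    summarise(folds = dplyr::n(),
              mae = mean(.data$mae), mae_sd = sd(.data$mae),
              rmse = mean(.data$rmse), rmse_sd = sd(.data$rmse),
              r2 = mean(.data$r2), r2_sd = sd(.data$r2),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$r2), .data$mae) %>%
    mutate(rank = row_number())
}
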