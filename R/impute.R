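#' Build a cohort table directly from a data frame
#'
#' Convenience constructor for analysis tables that did not come from the
#' generator (toy examples, external data). Cells present in `data` are
#' tagged `observed`.
#'
#' @param data A data frame with `subjid` (and optionally `visit`, `visdy`)
#'   plus variable columns.
#' @param catalog An [catalog_spec()] catalog covering the variable columns.
#' @return An `hd_cohort`.
#' @export
cohort_from_table <- function(data, catalog) {
  data <- as_tibble(data)
  if (!"subjid" %in% names(data)) abort("data must contain a subjid column")
  new_cohort(data, make_provenance(data), catalog)
}

#' Cascade hyperparameters
#'
#' Model-family hyperparameters for the imputation cascade. The candidate
#' families are a random forest, a linear (continuous/ordinal) or logistic
#' (boolean/nominal) regression, and k-nearest-neighbours on standardized
#' predictors.
#'
#' @param num_trees Random-forest trees.
#' @param knn_k Neighbours for the kNN family.
#' @param k_folds Cross-validation folds for model scoring.
#' @return A list of class `hd_cascade_control`.
#' @export
cascade_control <- function(num_trees = 100, knn_k = 5, k_folds = 10) {
  structure(list(num_trees = num_trees, knn_k = knn_k, k_folds = k_folds),
            class = "hd_cascade_control")
}

FAMILY_ORDER <- c("random_forest", "linear_or_logistic", "knn")

is_classification <- function(dtype) dtype %in% c("boolean", "nominal")

# predictors usable for imputing `target`: numeric catalog variables with no
# missing values anywhere in the current table (imputed cells count as
# observed in later rounds, which is how refitting gains data)
cascade_predictors <- function(table, catalog, target) {
  vars <- setdiff(analysis_vars(table, catalog), target)
  vars[vapply(vars, function(v)
    is.numeric(table[[v]]) && !anyNA(table[[v]]), logical(1))]
}

standardize_train <- function(X) {
  mu <- vapply(X, mean, numeric(1))
  sig <- vapply(X, sd, numeric(1))
  sig[!is.finite(sig) | sig == 0] <- 1
  list(mu = mu, sig = sig,
       X = as.data.frame(scale(X, center = mu, scale = sig)))
}

fit_family <- function(family, X, y, dtype, control, seed) {
  classification <- is_classification(dtype)
  if (classification) y <- factor(y)
  df <- data.frame(X, .y = y)
  if (family == "random_forest") {
    fit <- ranger::ranger(.y ~ ., data = df, num.trees = control$num_trees,
                          seed = seed, num.threads = 1,
                          classification = classification)
    list(family = family, fit = fit, classification = classification,
         seed = seed)
  } else if (family == "linear_or_logistic") {
    fit <- if (!classification) {
      lm(.y ~ ., data = df)
    } else if (nlevels(y) == 2) {
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    } else {
      nnet::multinom(.y ~ ., data = df, trace = FALSE)
    }
    list(family = family, fit = fit, classification = classification,
         levels = if (classification) levels(y))
  } else if (family == "knn") {
    std <- standardize_train(X)
    fit <- if (classification)
      caret::knn3(as.matrix(std$X), y, k = min(control$knn_k, nrow(X)))
    else
      caret::knnreg(as.matrix(std$X), y, k = min(control$knn_k, nrow(X)))
    list(family = family, fit = fit, classification = classification,
         mu = std$mu, sig = std$sig)
  } else abort(paste("unknown model family:", family))
}

predict_family <- function(model, X) {
  if (model$family == "random_forest") {
    # an explicit seed keeps vote tie-breaking off the global RNG stream
    p <- predict(model$fit, data = data.frame(X), num.threads = 1,
                 seed = model$seed)$predictions
    if (model$classification) as.character(p) else as.numeric(p)
  } else if (model$family == "linear_or_logistic") {
    # full one-hot blocks are collinear with the intercept by design;
    # lm/glm pivot the redundant columns, so the rank warnings are noise
    if (!model$classification) {
      as.numeric(suppressWarnings(predict(model$fit, newdata = data.frame(X))))
    } else if (length(model$levels) == 2) {
      p <- suppressWarnings(predict(model$fit, newdata = data.frame(X),
                                    type = "response"))
      model$levels[1 + as.integer(p >= 0.5)]
    } else {
      as.character(predict(model$fit, newdata = data.frame(X), type = "class"))
    }
  } else {
    Xs <- as.matrix(scale(X, center = model$mu, scale = model$sig))
    if (model$classification) {
      # deterministic argmax over vote fractions (first level wins ties)
      votes <- predict(model$fit, Xs, type = "prob")
      colnames(votes)[max.col(votes, ties.method = "first")]
    } else as.numeric(predict(model$fit, Xs))
  }
}

family_cv_score <- function(family, X, y, dtype, spec, control, seed) {
  n <- nrow(X)
  k <- min(control$k_folds, n)
  if (k < control$k_folds)
    warn(sprintf("only %d rows; folds reduced to %d", n, k))
  folds <- with_local_seed(seed, sample(rep_len(seq_len(k), n)))
  scores <- vapply(seq_len(k), function(f) {
    tr <- folds != f; te <- !tr
    model <- fit_family(family, X[tr, , drop = FALSE], y[tr], dtype,
                        control, seed + f)
    pred <- predict_family(model, X[te, , drop = FALSE])
    if (is_classification(dtype)) {
      weighted_f1(y[te], pred)
    } else if (dtype == "ordinal") {
      weighted_f1(y[te], clip_round_predictions(pred, spec))
    } else {
      regression_metrics(y[te], pred)$r2
    }
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Score candidate imputation models for one variable
#'
#' Fits the three candidate families on rows where the variable is observed
#' (10-fold cross-validation, shared seeded folds) and scores them by mean
#' fold R2 (continuous) or weighted F1 (ordinal / boolean / nominal;
#' regression predictions for ordinal targets are clipped and rounded before
#' scoring). Predictors are the variables with no missing values in the
#' current table. Ties prefer random forest, then linear, then kNN.
#'
#' @param table An `hd_cohort`.
#' @param variable Target variable name.
#' @param catalog Variable catalog.
#' @param seed Integer seed (folds and forests).
#' @param control A [cascade_control()].
#' @return One-row tibble: variable, dtype, one score column per family,
#'   `chosen_family`, `score`; or zero rows if the variable is unscorable
#'   (single class or too few rows).
#' @export
score_models_for_variable <- function(table, variable,
                                      catalog = active_catalog(table),
                                      seed = 1L, control = cascade_control()) {
  spec <- catalog[catalog$name == variable, ]
  if (nrow(spec) == 0) abort(paste("variable not in catalog:", variable))
  dtype <- spec$dtype
  rows <- which(!is.na(table[[variable]]))
  preds <- cascade_predictors(table, catalog, variable)
  if (length(preds) == 0) abort("no complete predictor variables available")
  y <- table[[variable]][rows]
  if (is_classification(dtype) && length(unique(y)) < 2) {
    warn(sprintf("variable '%s' has a single observed class; skipped", variable))
    return(tibble())
  }
  X <- table[rows, preds, drop = FALSE]
  class(X) <- class(tibble())
  scores <- vapply(FAMILY_ORDER, function(fam)
    family_cv_score(fam, X, y, dtype, spec, control, seed), numeric(1))
  best <- FAMILY_ORDER[which.max(scores)]  # which.max keeps family order on ties
  out <- tibble(variable = variable, dtype = dtype)
  for (fam in FAMILY_ORDER) out[[paste0("score_", fam)]] <- scores[[fam]]
  out$chosen_family <- best
  out$score <- max(scores)
  out
}

#' Clip and round model predictions to a variable's valid domain
#'
#' Continuous predictions are clipped to the valid range; ordinal
#' predictions are rounded to the nearest level (round-half-to-even) and
#' clipped; nominal/boolean predictions are mapped to the nearest valid
#' category label (classification output is already categorical).
#'
#' @param values Raw predictions.
#' @param spec One catalog row for the variable.
#' @return Predictions inside the valid domain.
#' @export
clip_round_predictions <- function(values, spec) {
  if (spec$dtype %in% c("continuous", "ordinal", "boolean")) {
    if (is.na(spec$valid_min) && is.na(spec$valid_max))
      abort(paste("schema error: empty valid range for", spec$name))
    v <- as.numeric(values)
    if (spec$dtype != "continuous") v <- round(v)
    clamp(v, spec$valid_min %||% -Inf, spec$valid_max %||% Inf)
  } else {
    lvls <- cat_levels(spec, spec$name)
    if (length(lvls) == 0) abort("schema error: empty category set")
    ifelse(values %in% lvls, values, lvls[1])
  }
}

#' Run the score-ordered imputation cascade
#'
#' Every non-composite variable with imputation-eligible missing cells is
#' scored ([score_models_for_variable()]), then variables are imputed
#' sequentially in descending initial-score order (lexicographic name
#' tiebreak). At each variable's turn its models are re-scored on the
#' augmented table (previously imputed cells count as observed, widening the
#' predictor set); the initial-round model is kept if it outperformed the
#' refit. Only missing eligible cells receive values (provenance
#' `imputed_ml`); cells marked `onset_not_applicable` are never imputed.
#' Composite scores are recomputed from their components afterwards.
#'
#' @param table A pre-processed `hd_cohort`.
#' @param catalog Variable catalog.
#' @param seed Integer seed controlling folds and forests.
#' @param control A [cascade_control()].
#' @return A list with `table` (fully imputed `hd_cohort`) and `report`
#'   (tibble of class `hd_imputation_report`: per-variable candidate scores,
#'   chosen family and round, and imputation order rank).
#' @export
run_cascade <- function(table, catalog = active_catalog(table), seed = 1L,
                        control = cascade_control()) {
  if (!inherits(table, "hd_cohort"))
    abort("table must be an hd_cohort (run preprocess first)")
  prov <- cohort_provenance(table)
  eligible_missing <- function(tab, v) {
    p <- cohort_provenance(tab)
    which(is.na(tab[[v]]) &
            (is.na(p[[v]]) | p[[v]] != "onset_not_applicable"))
  }
  composites <- catalog$name[!is.na(catalog$composite_of)]
  targets <- setdiff(analysis_vars(table, catalog), composites)
  targets <- targets[vapply(targets, function(v)
    length(eligible_missing(table, v)) > 0, logical(1))]
  empty_report <- tibble(variable = character(), dtype = character(),
                         rank = integer(), chosen_family = character(),
                         chosen_round = character(),
                         initial_score = numeric(), refit_score = numeric(),
                         final_score = numeric(), n_imputed = integer())
  if (length(targets) == 0) {
    return(list(table = recompute_composites(table, catalog),
                report = structure(empty_report,
                                   class = c("hd_imputation_report",
                                             class(empty_report)))))
  }
  initial_table <- table
  initial <- purrr::map_dfr(seq_along(targets), function(i)
    score_models_for_variable(initial_table, targets[i], catalog,
                              seed = seed + i, control = control))
  if (nrow(initial) == 0) abort("no scorable variables with missing cells")
  initial <- initial %>%
    arrange(dplyr::desc(.data$score), .data$variable) %>%
    mutate(rank = row_number())

  out <- table
  report <- vector("list", nrow(initial))
  for (i in seq_len(nrow(initial))) {
    v <- initial$variable[i]
    seed_v <- seed + match(v, targets)
    refit <- score_models_for_variable(out, v, catalog,
                                       seed = seed_v, control = control)
    refit_score <- if (nrow(refit)) refit$score else -Inf
    use_initial <- initial$score[i] >= refit_score
    fit_table <- if (use_initial) initial_table else out
    fam <- if (use_initial) initial$chosen_family[i] else refit$chosen_family
    spec <- catalog[catalog$name == v, ]
    preds <- cascade_predictors(fit_table, catalog, v)
    rows_tr <- which(!is.na(fit_table[[v]]))
    model <- fit_family(fam, fit_table[rows_tr, preds, drop = FALSE],
                        fit_table[[v]][rows_tr], spec$dtype, control, seed_v)
    rows_mis <- eligible_missing(out, v)
    pred <- predict_family(model, out[rows_mis, preds, drop = FALSE])
    pred <- clip_round_predictions(pred, spec)
    if (is.numeric(out[[v]])) pred <- as.numeric(pred)
    out <- set_cells(out, rows_mis, v, pred, "imputed_ml")
    report[[i]] <- tibble(
      variable = v, dtype = spec$dtype, rank = i,
      chosen_family = fam,
      chosen_round = if (use_initial) "initial" else "refit",
      initial_score = initial$score[i], refit_score = refit_score,
      final_score = max(initial$score[i], refit_score),
      n_imputed = length(rows_mis))
  }
  report <- bind_rows(report) %>%
    left_join(select(initial, "variable", dplyr::starts_with("score_")),
              by = "variable")
  out <- recompute_composites(out, catalog)
  list(table = out,
       report = structure(report, class = c("hd_imputation_report",
                                            class(report))))
}

#' Recompute composite scores from their components
#'
#' Each composite cell is overwritten with the sum of its component cells
#' (provenance `recomputed_composite`); composites never enter the cascade
#' as targets. A composite with a still-missing component is left missing
#' and logged.
#'
#' @param table An `hd_cohort`.
#' @param catalog Variable catalog declaring `composite_of`.
#' @return The `hd_cohort` with composites recomputed.
#' @export
recompute_composites <- function(table, catalog = active_catalog(table)) {
  defs <- catalog[!is.na(catalog$composite_of) & catalog$name %in% names(table), ]
  out <- table
  for (i in seq_len(nrow(defs))) {
    v <- defs$name[i]
    comps <- intersect(cat_split(defs$composite_of[i]), names(out))
    if (length(comps) == 0) next
    sums <- Reduce(`+`, lapply(comps, function(cc) out[[cc]]))
    ok <- which(!is.na(sums))
    bad <- which(is.na(sums))
    out <- set_cells(out, ok, v, sums[ok], "recomputed_composite",
                     overwrite = TRUE)
    if (length(bad)) {
      out[[v]][bad] <- NA
      prov <- attr(out, "provenance")
      prov[[v]][bad] <- NA_character_
      attr(out, "provenance") <- prov
      out <- log_event(out, "recompute_composites", "component_missing",
                       unique(out$subjid[bad]), v)
    }
  }
  out
}
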