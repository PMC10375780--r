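#' Assign visits to one-year slots
#'
#' Slot index of each visit: `round((d - d0) / t)` with the first visit
#' defining the baseline `d0`, round-to-nearest with half away from zero.
#' The first visit always lands in slot 0.
#'
#' @param days_from_baseline Days-from-baseline (`visdy`) of one
#'   participant's visits, first element the baseline visit.
#' @param t Target days between slots (365 for annual).
#' @return Integer slot indices (0-based).
#' @export
assign_visit_index <- function(days_from_baseline, t = 365) {
  d <- days_from_baseline - days_from_baseline[1]
  if (any(d < 0)) abort("data error: negative days from baseline")
  as.integer(floor(d / t + 0.5))
}

#' GRU training configuration
#'
#' @param layers Stacked GRU layers (the tuning grid uses 3 and 5).
#' @param hidden Hidden units per layer (grid: 128, 256, 512).
#' @param l2 L2 penalty on kernel/recurrent/head weights
#'   (grid: 1e-7, 1e-5, 1e-3).
#' @param learning_rate Adam learning rate (1e-5).
#' @param epochs Training epochs.
#' @param batch Minibatch size.
#' @param seed Integer seed (weight init and shuffling).
#' @return A list of class `hd_gru_config`.
#' @export
gru_config <- function(layers = 3L, hidden = 128L, l2 = 1e-5,
                       learning_rate = 1e-5, epochs = 250L, batch = 32L,
                       seed = 1L) {
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 l2 = l2, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 seed = as.integer(seed)),
            class = "hd_gru_config")
}

#' Build the longitudinal tensor
#'
#' Reshapes a fully imputed cohort into participants x slots x features with
#' an explicit mask: visits are assigned to at most `max_visits` annual
#' slots ([assign_visit_index()]); unoccupied slots are filled with the mask
#' sentinel everywhere; when two visits collide on a slot the later-dated
#' one is kept (`collapsed_collision`); slot indices beyond the window are
#' dropped and counted. Current labels come from `label_var`; next-year
#' labels are the following slot's current label. Labels that are missing or
#' were ML-imputed get sample weight 0; the next-year label at a
#' participant's final observed slot is unobservable and also gets weight 0.
#' Class weights follow `w_c = n / (C * n_c)` over the weight-eligible
#' current labels.
#'
#' @param table An imputed `hd_cohort`.
#' @param catalog Variable catalog.
#' @param label_var Binary status variable (default `driving`).
#' @param max_visits Slot count (default 5).
#' @param t Days per slot.
#' @param mask_value Sentinel for masked cells; must not collide with any
#'   observed feature value.
#' @return A list of class `hd_tensor`: `values` (N x T x F array), `mask`,
#'   `y_cur`, `y_next`, `w_cur`, `w_next`, `slot_provenance`,
#'   `feature_names`, `subjid`, `class_weights`, `mask_value`, `t`.
#' @export
build_tensor <- function(table, catalog = active_catalog(table),
                         label_var = "driving", max_visits = 5L, t = 365,
                         mask_value = -999) {
  feats <- setdiff(analysis_vars(table, catalog), label_var)
  feats <- feats[vapply(feats, function(v) is.numeric(table[[v]]), logical(1))]
  for (v in feats) {
    if (any(!is.na(table[[v]]) & table[[v]] == mask_value))
      abort(sprintf("configuration error: mask_value %s collides with observed values of '%s'",
                    mask_value, v))
  }
  prov <- cohort_provenance(table)
  subj <- unique(table$subjid)
  N <- length(subj); T_ <- as.integer(max_visits); F_ <- length(feats)
  values <- array(mask_value, dim = c(N, T_, F_),
                  dimnames = list(NULL, NULL, feats))
  mask <- matrix(0L, N, T_)
  y_cur <- matrix(NA_real_, N, T_)
  w_elig <- matrix(FALSE, N, T_)   # label observed and not imputed
  slot_prov <- matrix("masked_missing", N, T_)
  dropped <- 0L
  for (i in seq_len(N)) {
    rows <- which(table$subjid == subj[i])
    rows <- rows[order(table$visdy[rows])]
    slot <- assign_visit_index(table$visdy[rows], t)
    keep <- slot < T_
    dropped <- dropped + sum(!keep)
    rows <- rows[keep]; slot <- slot[keep]
    for (k in seq_along(rows)) {
      s <- slot[k] + 1L
      if (mask[i, s] == 1L) slot_prov[i, s] <- "collapsed_collision"
      else slot_prov[i, s] <- "observed"
      mask[i, s] <- 1L
      # later-dated visit wins a collision (rows are in date order)
      vals <- as.numeric(unlist(table[rows[k], feats]))
      vals[is.na(vals)] <- 0  # known-not-applicable onset cells
      values[i, s, ] <- vals
      lab <- table[[label_var]][rows[k]]
      y_cur[i, s] <- if (is.na(lab)) NA_real_ else as.numeric(lab)
      ptag <- prov[[label_var]][rows[k]]
      w_elig[i, s] <- !is.na(lab) && !is.na(ptag) && ptag == "observed"
    }
  }
  y_next <- cbind(y_cur[, -1, drop = FALSE], NA_real_)
  next_elig <- cbind(w_elig[, -1, drop = FALSE], FALSE) &
    cbind(mask[, -1, drop = FALSE] == 1L, FALSE) & (mask == 1L)
  cw <- compute_weights(y_cur, w_elig & (mask == 1L))
  w_cur <- matrix(0, N, T_)
  idx <- which(w_elig & (mask == 1L) & !is.na(y_cur))
  w_cur[idx] <- cw$class_weights[as.character(y_cur[idx])]
  w_next <- matrix(0, N, T_)
  idxn <- which(next_elig & !is.na(y_next))
  w_next[idxn] <- cw$class_weights[as.character(y_next[idxn])]
  y_cur[is.na(y_cur)] <- 0
  y_next[is.na(y_next)] <- 0
  structure(list(values = values, mask = mask, y_cur = y_cur, y_next = y_next,
                 w_cur = w_cur, w_next = w_next,
                 slot_provenance = slot_prov, feature_names = feats,
                 subjid = subj, class_weights = cw, mask_value = mask_value,
                 t = t, dropped_visits = dropped),
            class = "hd_tensor")
}

#' Class and sample weights for masked sequence labels
#'
#' Class weights `w_c = n / (C * n_c)` computed over eligible (observed,
#' non-imputed) labels; when all classes are present the weights satisfy
#' `sum_c w_c * n_c = n` exactly. Missing or imputed labels get sample
#' weight 0.
#'
#' @param labels Matrix (or vector) of binary labels.
#' @param eligible Logical mask of the labels that count.
#' @return A list with `class_weights` (named by class), `n`, `n_c`, `C`.
#' @export
compute_weights <- function(labels, eligible) {
  y <- labels[eligible]
  y <- y[!is.na(y)]
  classes <- c(0, 1)
  n_c <- vapply(classes, function(cl) sum(y == cl), numeric(1))
  if (any(n_c == 0))
    abort(sprintf("class %s absent among eligible labels; weight undefined",
                  classes[n_c == 0][1]))
  n <- length(y); C <- length(classes)
  w <- n / (C * n_c)
  names(w) <- as.character(classes)
  list(class_weights = w, n = n, n_c = setNames(n_c, classes), C = C)
}

#' Participant holdout split stratified by missing visits
#'
#' Splits whole participants 80/20 (by default) within groups sharing the
#' same number of missing visit slots, so train and test have matching
#' visit-count distributions. Groups smaller than 2 are pooled with the
#' nearest group (logged in the `pooled` attribute).
#'
#' @param tensor An `hd_tensor`.
#' @param train_frac Training fraction.
#' @param seed Integer seed.
#' @return A tibble (`subjid`, `missing_slots`, `group`, `split`), with
#'   attribute `pooled`.
#' @export
split_holdout <- function(tensor, train_frac = 0.8, seed = 1L) {
  miss <- rowSums(tensor$mask == 0L)
  groups <- tibble(subjid = tensor$subjid, missing_slots = miss)
  tab <- table(miss)
  pooled <- character(0)
  grp <- as.character(miss)
  small <- names(tab)[tab < 2]
  for (g in small) {
    others <- setdiff(unique(grp), g)
    if (length(others) == 0) break
    nearest <- others[which.min(abs(as.numeric(others) - as.numeric(g)))]
    pooled <- c(pooled, sprintf("%s->%s", g, nearest))
    grp[grp == g] <- nearest
  }
  groups$group <- grp
  assign <- with_local_seed(seed, {
    groups %>%
      group_by(.data$group) %>%
      mutate(.ord = sample(dplyr::n()),
             split = ifelse(.data$.ord <= round(train_frac * dplyr::n()),
                            "train", "test")) %>%
      ungroup() %>%
      select(-".ord")
  })
  attr(assign, "pooled") <- pooled
  assign
}

subset_tensor <- function(tensor, keep) {
  out <- tensor
  out$values <- tensor$values[keep, , , drop = FALSE]
  for (f in c("mask", "y_cur", "y_next", "w_cur", "w_next", "slot_provenance"))
    out[[f]] <- tensor[[f]][keep, , drop = FALSE]
  out$subjid <- tensor$subjid[keep]
  out
}

#' Split a tensor by a holdout assignment
#'
#' @param tensor An `hd_tensor`.
#' @param assignment A [split_holdout()] result.
#' @return A list with `train` and `test` tensors.
#' @export
apply_split <- function(tensor, assignment) {
  tr <- tensor$subjid %in% assignment$subjid[assignment$split == "train"]
  list(train = subset_tensor(tensor, tr),
       test = subset_tensor(tensor, !tr))
}

#' Scale tensor features to \[-1, 1\]
#'
#' Per-feature affine map fitted on the training tensor's observed slots
#' only (train min to -1, train max to +1); the mask sentinel is untouched
#' and test values outside the training range are preserved, not clipped.
#' Constant training features map to 0 with a warning.
#'
#' @param train_tensor,test_tensor `hd_tensor` objects.
#' @return A list with scaled `train`, `test` and the `scaler` tibble.
#' @export
scale_features <- function(train_tensor, test_tensor = NULL) {
  feats <- train_tensor$feature_names
  obs <- train_tensor$mask == 1L
  scaler <- purrr::map_dfr(seq_along(feats), function(f) {
    x <- train_tensor$values[, , f][obs]
    tibble(feature = feats[f], min = min(x), max = max(x))
  })
  if (any(scaler$min == scaler$max))
    warn(paste("constant training features mapped to 0:",
               paste(scaler$feature[scaler$min == scaler$max], collapse = ", ")))
  rescale <- function(tensor) {
    out <- tensor
    obs_t <- tensor$mask == 1L
    for (f in seq_along(feats)) {
      lo <- scaler$min[f]; hi <- scaler$max[f]
      x <- tensor$values[, , f]
      x[obs_t] <- if (hi > lo) 2 * (x[obs_t] - lo) / (hi - lo) - 1 else 0
      out$values[, , f] <- x
    }
    out$scaled <- TRUE
    out
  }
  if (train_tensor$mask_value >= -1 && train_tensor$mask_value <= 1)
    abort("configuration error: mask_value lies inside the scaled feature range")
  tr <- rescale(train_tensor)
  list(train = tr,
       test = if (!is.null(test_tensor)) rescale(test_tensor),
       scaler = scaler)
}

tensor_to_cube <- function(tensor) {
  # (N x T x F) -> (F x T x N) for the compiled trainer
  aperm(tensor$values, c(3, 2, 1))
}

#' Train the masked two-head GRU
#'
#' Stacked GRU layers with a masking rule that skips sentinel slots (the
#' hidden state is carried through missing visits unchanged), two sigmoid
#' output heads (current and next-year status), weighted binary
#' cross-entropy with the tensor's class/sample weights, an L2 penalty, and
#' Adam updates. Fully deterministic given the config seed.
#'
#' @param tensor A scaled training `hd_tensor`.
#' @param config An [gru_config()].
#' @return An object of class `hd_gru_fit` (`params`, `config`,
#'   `loss_history`, `feature_names`).
#' @export
train_gru <- function(tensor, config = gru_config()) {
  if (is.null(tensor$scaled))
    warn("training on an unscaled tensor")
  res <- gru_train_cpp(tensor_to_cube(tensor),
                       tensor$mask, tensor$y_cur, tensor$y_next,
                       tensor$w_cur, tensor$w_next,
                       config$layers, config$hidden, config$l2,
                       config$learning_rate, config$epochs, config$batch,
                       config$seed)
  structure(list(params = res$params, config = config,
                 loss_history = as.numeric(res$loss_history),
                 feature_names = tensor$feature_names),
            class = "hd_gru_fit")
}

#' Per-slot probabilities from a fitted GRU
#'
#' @param object An `hd_gru_fit`.
#' @param tensor An `hd_tensor` scaled with the training scaler.
#' @param ... Unused.
#' @return An N x T x 2 array of probabilities (heads: current, next-year).
#'   Probabilities at masked slots are computed from the carried hidden
#'   state and depend only on observed slots.
#' @export
predict.hd_gru_fit <- function(object, tensor, ...) {
  stopifnot(identical(object$feature_names, tensor$feature_names))
  gru_predict_cpp(object$params, tensor_to_cube(tensor), tensor$mask,
                  object$config$layers, object$config$hidden)
}

#' Training-set loss of a fitted GRU on a tensor
#'
#' @param fit An `hd_gru_fit`.
#' @param tensor An `hd_tensor`.
#' @return Scalar weighted BCE + L2 loss.
#' @export
gru_loss <- function(fit, tensor) {
  gru_loss_cpp(fit$params, tensor_to_cube(tensor), tensor$mask,
               tensor$y_cur, tensor$y_next, tensor$w_cur, tensor$w_next,
               fit$config$layers, fit$config$hidden, fit$config$l2)
}

pooled_scores <- function(pred, tensor) {
  use_c <- tensor$w_cur > 0
  use_n <- tensor$w_next > 0
  tibble(
    head = c(rep("current", sum(use_c)), rep("next_year", sum(use_n))),
    label = c(tensor$y_cur[use_c], tensor$y_next[use_n]),
    score = c(pred[, , 1][use_c], pred[, , 2][use_n]))
}

#' Evaluate driving-capability predictions
#'
#' AUC, accuracy and F1 per head and pooled over both heads, operating
#' points (TPR/TNR) at 0.5 and any requested thresholds, and the confusion
#' percentages per class. Slots with weight 0 are excluded from every
#' metric. Single-class labels make the AUC undefined (flagged `NaN`).
#'
#' @param fit An `hd_gru_fit` (or a precomputed prediction array via
#'   `predictions`).
#' @param tensor The evaluation `hd_tensor` (scaled).
#' @param thresholds Decision thresholds to report.
#' @param predictions Optional N x T x 2 probability array.
#' @return A list of class `hd_driving_evaluation`: `metrics` (per head +
#'   pooled), `operating_points`, `confusion`, `scores`.
#' @export
evaluate_driving <- function(fit, tensor, thresholds = c(0.5),
                             predictions = NULL) {
  pred <- predictions %||% predict(fit, tensor)
  sc <- pooled_scores(pred, tensor)
  eval_one <- function(df, label) {
    thr <- threshold_metrics(df$label, df$score, 0.5)
    tibble(head = label, n = nrow(df),
           auc = if (length(unique(df$label)) < 2) NaN
                 else auc_score(df$label, df$score),
           accuracy = thr$accuracy, f1 = thr$f1)
  }
  metrics <- bind_rows(
    eval_one(sc, "pooled"),
    eval_one(filter(sc, .data$head == "current"), "current"),
    eval_one(filter(sc, .data$head == "next_year"), "next_year"))
  ops <- purrr::map_dfr(thresholds, function(th)
    threshold_metrics(sc$label, sc$score, th))
  cm <- tibble(
    class = c("positive", "negative"),
    n = c(sum(sc$label == 1), sum(sc$label == 0)),
    correct_pct = c(100 * ops$tpr[ops$threshold == 0.5][1],
                    100 * ops$tnr[ops$threshold == 0.5][1]))
  structure(list(metrics = metrics, operating_points = ops,
                 confusion = cm, scores = sc),
            class = "hd_driving_evaluation")
}

#' @export
tidy.hd_driving_evaluation <- function(x, ...) x$metrics

#' @export
glance.hd_driving_evaluation <- function(x, ...) {
  m <- x$metrics[x$metrics$head == "pooled", ]
  tibble(auc = m$auc, accuracy = m$accuracy, f1 = m$f1, n = m$n)
}

#' Enumerate the GRU tuning grid
#'
#' Cross-product of the tuned hyperparameter axes; the full grid (layers
#' {3, 5} x hidden {128, 256, 512} x L2 {1e-7, 1e-5, 1e-3}) has 18
#' configurations.
#'
#' @param layers,hidden,l2 Grid axes.
#' @return A tibble with one row per configuration.
#' @export
gru_grid <- function(layers = c(3L, 5L), hidden = c(128L, 256L, 512L),
                     l2 = c(1e-7, 1e-5, 1e-3)) {
  tidyr::expand_grid(layers = layers, hidden = hidden, l2 = l2)
}

#' Enumerate and run the GRU tuning grid
#'
#' The full grid crosses layers {3, 5}, hidden size {128, 256, 512} and L2
#' {1e-7, 1e-5, 1e-3} (18 configurations) at a fixed learning rate; the
#' best configuration is the one with the highest test AUC (pooled heads),
#' F1 as tiebreak. A failing run is recorded and the grid continues.
#'
#' @param train_tensor,test_tensor Scaled `hd_tensor` objects.
#' @param layers,hidden,l2 Grid axes.
#' @param base_config An [gru_config()] supplying the non-grid settings.
#' @return A list: `leaderboard` (sorted tibble), `best_config`, `best_fit`.
#' @export
tune_grid <- function(train_tensor, test_tensor,
                      layers = c(3L, 5L), hidden = c(128L, 256L, 512L),
                      l2 = c(1e-7, 1e-5, 1e-3),
                      base_config = gru_config()) {
  grid <- gru_grid(layers, hidden, l2)
  rows <- vector("list", nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- gru_config(layers = grid$layers[i], hidden = grid$hidden[i],
                      l2 = grid$l2[i],
                      learning_rate = base_config$learning_rate,
                      epochs = base_config$epochs, batch = base_config$batch,
                      seed = base_config$seed)
    rows[[i]] <- tryCatch({
      fit <- train_gru(train_tensor, cfg)
      ev <- evaluate_driving(fit, test_tensor)
      fits[[i]] <- fit
      m <- ev$metrics[ev$metrics$head == "pooled", ]
      tibble(layers = cfg$layers, hidden = cfg$hidden, l2 = cfg$l2,
             auc = m$auc, accuracy = m$accuracy, f1 = m$f1, failed = FALSE)
    }, error = function(e)
      tibble(layers = cfg$layers, hidden = cfg$hidden, l2 = cfg$l2,
             auc = NA_real_, accuracy = NA_real_, f1 = NA_real_,
             failed = TRUE))
  }
  lb <- bind_rows(rows) %>%
    arrange(dplyr::desc(.data$auc), dplyr::desc(.data$f1))
  best_i <- which(!bind_rows(rows)$failed &
                    bind_rows(rows)$auc == lb$auc[1] &
                    bind_rows(rows)$f1 == lb$f1[1])[1]
  list(leaderboard = lb,
       best_config = if (!is.na(best_i))
         gru_config(layers = grid$layers[best_i], hidden = grid$hidden[best_i],
                    l2 = grid$l2[best_i],
                    learning_rate = base_config$learning_rate,
                    epochs = base_config$epochs, batch = base_config$batch,
                    seed = base_config$seed),
       best_fit = if (!is.na(best_i)) fits[[best_i]])
}

#' Calibration-band accuracies
#'
#' Splits predicted probabilities into ten equal bins (`[0,0.1)` ...
#' `[0.9,1.0]`, closed top edge) and reports the empirical accuracy (at
#' threshold 0.5) of the predictions falling in each bin. Empty bins are
#' flagged with `NA` accuracy.
#'
#' @param predictions Predicted probabilities (weight-eligible slots).
#' @param labels Matching binary labels.
#' @param bins Number of bins.
#' @param threshold Decision threshold for counting a prediction correct.
#' @return A tibble of class `hd_calibration_bands`.
#' @export
band_accuracy <- function(predictions, labels, bins = 10, threshold = 0.5) {
  edges <- seq(0, 1, length.out = bins + 1)
  bin <- pmin(findInterval(predictions, edges, rightmost.closed = TRUE), bins)
  out <- purrr::map_dfr(seq_len(bins), function(b) {
    in_b <- bin == b
    tibble(bin_lo = edges[b], bin_hi = edges[b + 1], n = sum(in_b),
           accuracy = if (any(in_b))
             mean((predictions[in_b] >= threshold) == (labels[in_b] == 1))
           else NA_real_)
  })
  class(out) <- c("hd_calibration_bands", class(out))
  out
}

#' Personalised driving trajectory
#'
#' For one participant: the recorded status and current-head probability at
#' each observed slot, plus a one-step-ahead probability (the next-year head
#' at the last observed slot) appended as a future slot. Each probability is
#' annotated with its calibration-band accuracy and the advice at the
#' threshold (positive when probability >= threshold).
#'
#' @param fit An `hd_gru_fit`.
#' @param tensor A scaled `hd_tensor`.
#' @param subjid Participant identifier inside the tensor.
#' @param bands An [band_accuracy()] table (test-set calibration).
#' @param threshold Advice threshold.
#' @return A tibble of class `hd_trajectory` (`slot`, `type`, `recorded`,
#'   `probability`, `band_accuracy`, `advice`).
#' @export
predict_trajectory <- function(fit, tensor, subjid, bands = NULL,
                               threshold = 0.5) {
  i <- match(subjid, tensor$subjid)
  if (is.na(i)) abort("participant not in tensor")
  obs <- which(tensor$mask[i, ] == 1L)
  if (length(obs) == 0) abort("all slots masked for this participant")
  pred <- predict(fit, subset_tensor(tensor, i))
  band_of <- function(p) {
    if (is.null(bands)) return(NA_real_)
    b <- pmin(findInterval(p, seq(0, 1, length.out = nrow(bands) + 1),
                           rightmost.closed = TRUE), nrow(bands))
    bands$accuracy[b]
  }
  cur <- tibble(slot = obs, type = "current",
                recorded = tensor$y_cur[i, obs],
                probability = pred[1, obs, 1])
  last <- max(obs)
  fut <- tibble(slot = last + 1L, type = "next_year", recorded = NA_real_,
                probability = pred[1, last, 2])
  out <- bind_rows(cur, fut) %>%
    mutate(band_accuracy = band_of(.data$probability),
           advice = .data$probability >= threshold)
  class(out) <- c("hd_trajectory", class(out))
  out
}
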