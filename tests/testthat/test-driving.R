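# Tensor construction, holdout stratification, scaling contracts, weights,
# calibration bands and trajectories.

test_that("visit indices round to the nearest annual slot", {
  expect_identical(assign_visit_index(c(0, 365, 548)), c(0L, 1L, 2L))
  expect_identical(assign_visit_index(c(100, 465)), c(0L, 1L))  # first visit is slot 0
  expect_identical(assign_visit_index(c(0, 182.5)), c(0L, 1L))  # half away from zero
  expect_identical(assign_visit_index(c(0, 182.49)), c(0L, 0L))
  expect_error(assign_visit_index(c(100, 50)), "negative")
})

test_that("the tensor masks unobserved slots and shifts next-year labels", {
  tensor <- cached_tensor()
  N <- length(tensor$subjid)
  expect_identical(dim(tensor$values)[1:2], c(N, 5L))
  # masked slots are sentinel-filled and weight-0
  masked <- tensor$mask == 0L
  for (f in seq_along(tensor$feature_names)) {
    expect_true(all(tensor$values[, , f][masked] == tensor$mask_value))
  }
  expect_true(all(tensor$w_cur[masked] == 0))
  expect_true(all(tensor$w_next[masked] == 0))
  # single-visit participants: slots 2..5 masked
  solo <- which(rowSums(tensor$mask) == 1L)
  if (length(solo)) expect_true(all(tensor$mask[solo, 2:5] == 0L))
  # next-year label of slot t equals current label of slot t+1 when eligible
  el <- which(tensor$w_next[, 1:4] > 0, arr.ind = TRUE)
  expect_true(all(tensor$y_next[, 1:4][el] ==
                    tensor$y_cur[, 2:5][el]))
  # next-year weight at each participant's final observed slot is 0
  last <- apply(tensor$mask, 1, function(m) max(which(m == 1L)))
  expect_true(all(tensor$w_next[cbind(seq_len(N), last)] == 0))
})

test_that("slot collisions keep the later-dated visit", {
  imp <- cached_imputed()$table
  one <- imp[imp$subjid == imp$subjid[1], ]
  # days 0 and 100 collide on slot 0; day 400 lands in slot 1
  three <- one[c(1, 1, 1), ]
  three$visdy <- c(0, 100, 400)
  three$visit <- 1:3
  three$sdmt <- c(11, 22, 33)
  three$driving <- c(1, 0, 1)
  co <- new_cohort_for_test(three, imp)
  tensor <- build_tensor(co)
  expect_identical(tensor$slot_provenance[1, 1], "collapsed_collision")
  expect_identical(tensor$slot_provenance[1, 2], "observed")
  f <- match("sdmt", tensor$feature_names)
  expect_equal(unname(tensor$values[1, 1, f]), 22)  # later-dated visit wins
  expect_equal(unname(tensor$values[1, 2, f]), 33)
  expect_equal(tensor$y_cur[1, 1], 0)
})

test_that("a mask sentinel colliding with data is a configuration error", {
  imp <- cached_imputed()$table
  expect_error(build_tensor(imp, mask_value = 0), "collides")
})

test_that("the holdout is stratified by missing-visit count", {
  tensor <- cached_tensor()
  split <- split_holdout(tensor, 0.8, seed = 7)
  expect_identical(split, split_holdout(tensor, 0.8, seed = 7))
  by_grp <- split %>%
    dplyr::count(group, split) %>%
    tidyr::pivot_wider(names_from = split, values_from = n, values_fill = 0)
  for (i in seq_len(nrow(by_grp))) {
    n_g <- by_grp$train[i] + by_grp$test[i]
    expect_lte(abs(by_grp$train[i] - 0.8 * n_g), 1)
  }
  # whole participants assigned exactly once
  expect_identical(sort(split$subjid), sort(tensor$subjid))
})

test_that("an exactly divisible cohort splits 16/4 per group", {
  # 5 groups of 20 participants, missing-slot counts 0..4
  mask <- do.call(rbind, lapply(0:4, function(m) {
    row <- c(rep(1L, 5 - m), rep(0L, m))
    matrix(rep(row, 20), nrow = 20, byrow = TRUE)
  }))
  tensor <- list(subjid = sprintf("P%03d", 1:100), mask = mask)
  class(tensor) <- "hd_tensor"
  split <- split_holdout(tensor, 0.8, seed = 1)
  counts <- split %>% dplyr::count(group, split)
  expect_true(all(counts$n[counts$split == "train"] == 16))
  expect_true(all(counts$n[counts$split == "test"] == 4))
})

test_that("feature scaling is train-fitted, unclipped and sentinel-safe", {
  tensor <- cached_tensor()
  parts <- apply_split(tensor, split_holdout(tensor, 0.8, seed = 3))
  sc <- scale_features(parts$train, parts$test)
  obs <- sc$train$mask == 1L
  for (f in seq_along(tensor$feature_names)) {
    x <- sc$train$values[, , f][obs]
    if (sc$scaler$min[f] < sc$scaler$max[f]) {
      expect_equal(min(x), -1)
      expect_equal(max(x), 1)
    }
  }
  # masked cells keep the sentinel
  expect_true(all(sc$train$values[, , 1][sc$train$mask == 0L] ==
                    tensor$mask_value))
  # the scaler is recomputable from the raw training tensor alone (no leakage)
  f1 <- 1
  raw <- parts$train$values[, , f1][parts$train$mask == 1L]
  expect_equal(sc$scaler$min[f1], min(raw))
  expect_equal(sc$scaler$max[f1], max(raw))
  # test values may leave [-1, 1]
  te <- sc$test$values[, , f1][sc$test$mask == 1L]
  raw_te <- parts$test$values[, , f1][parts$test$mask == 1L]
  expect_equal(te, 2 * (raw_te - min(raw)) / (max(raw) - min(raw)) - 1)
})

test_that("constant training features scale to zero with a warning", {
  tensor <- cached_tensor()
  tensor$values[, , 1][tensor$mask == 1L] <- 7
  expect_warning(sc <- scale_features(tensor), "constant")
  expect_true(all(sc$train$values[, , 1][tensor$mask == 1L] == 0))
})

test_that("class weights follow w_c = n / (C n_c) and conserve mass", {
  lab <- matrix(c(rep(0, 50), rep(1, 50)), 10, 10)
  el <- matrix(TRUE, 10, 10)
  w <- compute_weights(lab, el)
  expect_equal(unname(w$class_weights), c(1, 1))
  lab2 <- matrix(c(rep(1, 25), rep(0, 75)), 10, 10)
  w2 <- compute_weights(lab2, el)
  expect_equal(unname(w2$class_weights["1"]), 2.0)
  expect_equal(unname(w2$class_weights["0"]), 100 / (2 * 75))
  expect_equal(sum(w2$class_weights * w2$n_c), w2$n)
  # imputed slots are excluded from the counts and weighted 0 downstream
  el3 <- el; el3[1, ] <- FALSE
  w3 <- compute_weights(lab2, el3)
  expect_equal(w3$n, 90)
  expect_error(compute_weights(matrix(1, 5, 2), matrix(TRUE, 5, 2)),
               "absent")
})

test_that("imputed labels carry zero sample weight in the tensor", {
  imp <- cached_imputed()$table
  prov <- cohort_provenance(imp)
  tensor <- cached_tensor()
  imputed <- which(!is.na(prov$driving) & prov$driving == "imputed_ml")
  if (length(imputed)) {
    i <- imputed[1]
    subj <- imp$subjid[i]
    slot <- assign_visit_index(imp$visdy[imp$subjid == subj])[
      which(which(imp$subjid == subj) == i)] + 1L
    row <- match(subj, tensor$subjid)
    if (slot <= 5) expect_equal(tensor$w_cur[row, slot], 0)
  } else skip("no imputed driving labels in fixture")
})

test_that("calibration bands use half-open bins with a closed top edge", {
  p <- c(0.05, 0.55, 0.95, 1.0, 0.1)
  y <- c(0, 1, 1, 1, 0)
  b <- band_accuracy(p, y)
  expect_identical(nrow(b), 10L)
  expect_equal(b$n[6], 1)            # 0.55 in [0.5, 0.6)
  expect_equal(b$n[10], 2)           # 0.95 and 1.0 both in the top bin
  expect_equal(b$n[2], 1)            # 0.1 in [0.1, 0.2)
  all_right <- band_accuracy(c(0.2, 0.8, 0.9), c(0, 1, 1))
  expect_true(all(all_right$accuracy[!is.na(all_right$accuracy)] == 1))
})

test_that("driving evaluation handles perfect and inverted predictions", {
  tensor <- cached_tensor()
  N <- length(tensor$subjid)
  perfect <- array(0, dim = c(N, 5, 2))
  perfect[, , 1] <- tensor$y_cur
  perfect[, , 2] <- tensor$y_next
  ev <- evaluate_driving(NULL, tensor, predictions = perfect)
  expect_equal(ev$metrics$auc[ev$metrics$head == "pooled"], 1)
  expect_equal(ev$metrics$accuracy[ev$metrics$head == "pooled"], 1)
  expect_equal(ev$metrics$f1[ev$metrics$head == "pooled"], 1)
  inverted <- perfect
  inverted[, , 1] <- 1 - tensor$y_cur
  inverted[, , 2] <- 1 - tensor$y_next
  ev2 <- evaluate_driving(NULL, tensor, predictions = inverted)
  expect_equal(ev2$metrics$auc[1], 0)
  expect_equal(ev2$metrics$accuracy[1], 0)
  expect_equal(glance(ev)$auc, 1)
})
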