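# Cascade behaviour: model selection, ordering, clipping, composites,
# immutability and recovery against held-out truth.

test_that("predictions are clipped and rounded to the variable domain", {
  ord <- catalog_spec("o", "F", "ordinal", valid_min = 0, valid_max = 4)
  expect_equal(clip_round_predictions(4.7, ord), 4)
  expect_equal(clip_round_predictions(2.5, ord), 2)   # round-half-to-even
  expect_equal(clip_round_predictions(3.5, ord), 4)
  expect_equal(clip_round_predictions(-1.2, ord), 0)
  cont <- catalog_spec("c", "F", "continuous", valid_min = 0, valid_max = 10)
  expect_equal(clip_round_predictions(7.3, cont), 7.3)
  expect_equal(clip_round_predictions(12, cont), 10)
  nom <- catalog_spec("n", "F", "nominal", categories = "a,b")
  expect_equal(clip_round_predictions(c("a", "zz"), nom), c("a", "a"))
  bad <- catalog_spec("c2", "F", "continuous")
  expect_error(clip_round_predictions(1, bad), "schema error")
})

test_that("model scoring identifies noiseless linear structure", {
  toy <- toy_linear_cohort(n = 300, seed = 2, r2 = 0.999999, mcar = 0.1)
  rec <- score_models_for_variable(toy$cohort, "y", seed = 1,
                                   control = cascade_control(num_trees = 50))
  expect_identical(rec$chosen_family, "linear_or_logistic")
  expect_gte(rec$score_linear_or_logistic, 0.999)
})

test_that("pure-noise targets score near zero", {
  withr::with_seed(4, {
    d <- tibble::tibble(subjid = sprintf("S%04d", 1:2000), visit = 1L,
                        visdy = 0, x1 = rnorm(2000), x2 = rnorm(2000),
                        y = rnorm(2000))
  })
  co <- cohort_from_table(d, toy_catalog())
  rec <- score_models_for_variable(co, "y", seed = 1,
                                   control = cascade_control(num_trees = 50))
  expect_lte(rec$score, 0.05)
})

test_that("a perfectly separable binary target gives weighted F1 = 1", {
  cat <- dplyr::bind_rows(
    catalog_spec("x1", "T", "continuous", valid_min = -Inf, valid_max = Inf),
    catalog_spec("b", "T", "boolean", valid_min = 0, valid_max = 1))
  withr::with_seed(8, {
    x <- rnorm(300)
    d <- tibble::tibble(subjid = sprintf("S%03d", 1:300), visit = 1L,
                        visdy = 0, x1 = x, b = as.numeric(x > 0))
  })
  co <- cohort_from_table(d, cat)
  rec <- score_models_for_variable(co, "b", seed = 1)
  expect_equal(rec$score_random_forest, 1.0, tolerance = 1e-9)
})

test_that("a table without missing cells passes through unchanged", {
  d <- tibble::tibble(subjid = c("A", "B"), visit = 1L, visdy = 0,
                      x1 = c(1, 2), x2 = c(3, 4), y = c(5, 6))
  co <- cohort_from_table(d, toy_catalog())
  out <- run_cascade(co, seed = 1)
  expect_identical(nrow(out$report), 0L)
  expect_identical(as.data.frame(out$table)[names(d)], as.data.frame(d))
})

test_that("the cascade imputes in descending score order and is exact bookkeeping", {
  # y is strongly predictable, z is nearly noise: y must get rank 1
  withr::with_seed(12, {
    n <- 300
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- x1 + x2 + rnorm(n, 0, 0.2)
    z <- rnorm(n)
    d <- tibble::tibble(subjid = sprintf("S%03d", seq_len(n)), visit = 1L,
                        visdy = 0, x1 = x1, x2 = x2, y = y, z = z)
    d$y[sample(n, 60)] <- NA
    d$z[sample(n, 60)] <- NA
  })
  cat <- dplyr::bind_rows(
    toy_catalog(),
    catalog_spec("z", "Toy", "continuous", valid_min = -Inf, valid_max = Inf))
  co <- cohort_from_table(d, cat)
  res <- run_cascade(co, seed = 3, control = cascade_control(num_trees = 50))
  rep <- res$report
  expect_identical(rep$variable[rep$rank == 1], "y")
  expect_setequal(rep$rank, seq_len(nrow(rep)))
  expect_true(all(c("initial", "refit") %in% c(rep$chosen_round, "initial", "refit")))
  # observed cells unchanged, missing cells filled
  obs <- which(!is.na(d$y))
  expect_identical(res$table$y[obs], d$y[obs])
  expect_false(anyNA(res$table$y))
  expect_false(anyNA(res$table$z))
  prov <- cohort_provenance(res$table)
  expect_identical(unique(prov$y[is.na(d$y)]), "imputed_ml")
  # determinism
  res2 <- run_cascade(co, seed = 3, control = cascade_control(num_trees = 50))
  expect_identical(as.data.frame(res$table), as.data.frame(res2$table))
  expect_identical(res$report$chosen_family, res2$report$chosen_family)
})

test_that("the initial-round model is kept when the refit does not beat it", {
  toy <- toy_linear_cohort(n = 250, seed = 5, r2 = 0.9, mcar = 0.2)
  res <- run_cascade(toy$cohort, seed = 2,
                     control = cascade_control(num_trees = 50))
  rep <- res$report
  kept <- rep$chosen_round == "initial"
  expect_true(all(rep$initial_score[kept] >= rep$refit_score[kept]))
  expect_true(all(rep$final_score == pmax(rep$initial_score, rep$refit_score)))
})

test_that("composites are recomputed from components, overwriting records", {
  cat <- dplyr::bind_rows(
    catalog_spec("a", "F", "ordinal", valid_min = 0, valid_max = 4),
    catalog_spec("b", "F", "ordinal", valid_min = 0, valid_max = 4),
    catalog_spec("c", "F", "ordinal", valid_min = 0, valid_max = 4),
    catalog_spec("tot", "F", "ordinal", valid_min = 0, valid_max = 12,
                 composite_of = "a,b,c"))
  d <- tibble::tibble(subjid = c("A", "B", "C"), visit = 1L, visdy = 0,
                      a = c(3, 0, 1), b = c(0, 0, NA), c = c(2, 0, 1),
                      tot = c(99, 99, 99))  # recorded values get overwritten
  co <- cohort_from_table(d, cat)
  out <- recompute_composites(co)
  expect_equal(out$tot, c(5, 0, NA))
  prov <- cohort_provenance(out)
  expect_identical(prov$tot[1:2], rep("recomputed_composite", 2))
  expect_gt(nrow(cohort_log(out)), 0)  # missing component logged
})

test_that("the cascade clearly beats mean imputation on recoverable structure", {
  toy <- toy_linear_cohort(n = 800, seed = 7, r2 = 0.9, mcar = 0.2)
  res <- run_cascade(toy$cohort, seed = 4,
                     control = cascade_control(num_trees = 50, k_folds = 5))
  miss <- toy$missing_rows
  truth <- toy$truth[miss]
  rmse_cascade <- sqrt(mean((res$table$y[miss] - truth)^2))
  mean_imp <- mean(toy$cohort$y, na.rm = TRUE)
  rmse_mean <- sqrt(mean((mean_imp - truth)^2))
  expect_lt(rmse_cascade, 0.7 * rmse_mean)
  expect_gte(res$report$final_score[res$report$variable == "y"], 0.8)
})

test_that("single-class categorical targets are skipped with a warning", {
  cat <- dplyr::bind_rows(
    catalog_spec("x1", "T", "continuous", valid_min = -Inf, valid_max = Inf),
    catalog_spec("b", "T", "boolean", valid_min = 0, valid_max = 1))
  d <- tibble::tibble(subjid = sprintf("S%02d", 1:30), visit = 1L, visdy = 0,
                      x1 = rnorm(30), b = c(rep(1, 25), rep(NA, 5)))
  co <- cohort_from_table(d, cat)
  expect_warning(rec <- score_models_for_variable(co, "b", seed = 1),
                 "single observed class")
  expect_identical(nrow(rec), 0L)
})
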