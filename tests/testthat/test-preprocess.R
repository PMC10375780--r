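# Inclusion rules, filtering, derived variables, structural inference and
# encoding, checked on hand-built tables and on generator cohorts with
# known truth.

mini_cohort <- function(data, catalog) cohort_from_table(data, catalog)

test_that("inclusion criteria exclude juvenile and out-of-range CAG", {
  cat <- dplyr::bind_rows(
    catalog_spec("caghigh", "Profile", "continuous", valid_min = 36, valid_max = 59),
    catalog_spec("hddiagn", "Profile", "continuous", valid_min = 21, valid_max = 95),
    catalog_spec("sxrater", "Profile", "continuous", valid_min = 21, valid_max = 95))
  data <- tibble::tibble(
    subjid = c("A", "B", "C", "D", "E"),
    visit = 1L, visdy = 0,
    caghigh = c(60, 36, 42, 35, 44),
    hddiagn = c(50, 45, NA, 40, 20),
    sxrater = c(50, 44, 19, 41, 22))
  out <- select_cohort(mini_cohort(data, cat))
  # A: cag > 59; C: rater 19 (juvenile); D: cag < 36; E: aao 20
  expect_identical(out$subjid, "B")
  log <- cohort_log(out)
  expect_setequal(log$reason[log$target == "A"], "caghigh_above_59")
  expect_setequal(log$reason[log$target == "C"], "aao_below_21")
  bad <- mini_cohort(data[, c("subjid", "visit", "visdy", "caghigh")],
                     cat[1, ])
  expect_error(select_cohort(bad), "schema error")
})

test_that("high-missingness and listed variables are dropped with categories", {
  cat <- dplyr::bind_rows(
    catalog_spec("a", "F1", "continuous", valid_min = 0, valid_max = 10),
    catalog_spec("b", "F1", "continuous", valid_min = 0, valid_max = 10),
    catalog_spec("sit", "F1", "boolean", valid_min = 0, valid_max = 1))
  data <- tibble::tibble(subjid = sprintf("S%02d", 1:10), visit = 1L, visdy = 0,
                         a = c(rep(NA, 7), 1, 2, 3),  # 70% missing
                         b = 1:10, sit = rep(1, 10))
  out <- filter_variables(mini_cohort(data, cat),
                          drop_list = tibble::tibble(variable = "sit",
                                                     category = "redundant"))
  expect_false("a" %in% names(out))
  expect_true("b" %in% names(out))
  expect_false("sit" %in% names(out))
  log <- cohort_log(out)
  expect_identical(log$reason[log$target == "a"], "high_missing")
  expect_identical(log$reason[log$target == "sit"], "redundant")
  # 69% missing exactly is kept (strict threshold)
  data2 <- tibble::tibble(subjid = sprintf("S%03d", 1:100), visit = 1L, visdy = 0,
                          a = c(rep(NA, 69), 1:31), b = 1, sit = 1)
  out2 <- filter_variables(mini_cohort(data2, cat))
  expect_true("a" %in% names(out2))
  expect_warning(
    filter_variables(mini_cohort(data, cat),
                     drop_list = tibble::tibble(variable = "nope",
                                                category = "other")),
    "unknown")
  expect_error(filter_variables(mini_cohort(data, cat), missing_threshold = 1.2),
               "threshold")
})

test_that("outlier flags match a brute-force scan and mutate nothing", {
  cat <- catalog_spec("x", "F", "continuous", valid_min = -Inf, valid_max = Inf)
  withr::with_seed(7, {
    x <- rnorm(500)
    x[17] <- mean(x) + 6 * sd(x)   # plant a gross outlier
  })
  data <- tibble::tibble(subjid = sprintf("S%03d", 1:500), visit = 1L,
                         visdy = 0, x = x)
  co <- mini_cohort(data, cat)
  rep <- detect_numeric_outliers(co)
  mu <- mean(x); sig <- sd(x)
  oracle <- which(abs(x - mu) > 4 * sig)
  expect_setequal(rep$subjid, data$subjid[oracle])
  expect_identical(co$x, x)  # report-only
  # constant column: sigma 0, no flags
  data_c <- tibble::tibble(subjid = sprintf("S%d", 1:5), visit = 1L, visdy = 0,
                           x = rep(5, 5))
  expect_identical(nrow(detect_numeric_outliers(mini_cohort(data_c, cat))), 0L)
  # a value exactly at mu + 4 sigma is not flagged (strict inequality):
  # check by scanning with the rule's own moments
  data_b <- tibble::tibble(subjid = sprintf("S%d", 1:11), visit = 1L, visdy = 0,
                           x = c(rep(0, 8), 1, -1, 3))
  rep_b <- detect_numeric_outliers(mini_cohort(data_b, cat))
  mu2 <- mean(data_b$x); s2 <- sd(data_b$x)
  expect_setequal(rep_b$subjid,
                  data_b$subjid[abs(data_b$x - mu2) > 4 * s2])
  at_bound <- tibble::tibble(subjid = c("P1", "P2", "P3"), visit = 1L,
                             visdy = 0, x = c(-1, 0, 1))
  # for {-1, 0, 1} the extremes sit at 1 sd, far inside the 4-sigma band
  expect_identical(nrow(detect_numeric_outliers(mini_cohort(at_bound, cat))), 0L)
  # fewer than two observations: skipped with a note
  data_s <- tibble::tibble(subjid = "S1", visit = 1L, visdy = 0, x = NA_real_)
  rep_s <- detect_numeric_outliers(mini_cohort(data_s, cat))
  expect_identical(attr(rep_s, "skipped"), "x")
})

test_that("derived variables follow the parent-minimum and CAP equations", {
  cat <- dplyr::bind_rows(
    catalog_spec("momagesx", "P", "continuous", valid_min = 15, valid_max = 95),
    catalog_spec("dadagesx", "P", "continuous", valid_min = 15, valid_max = 95),
    catalog_spec("age", "V", "continuous", valid_min = 0, valid_max = 110),
    catalog_spec("caghigh", "P", "continuous", valid_min = 36, valid_max = 59))
  data <- tibble::tibble(subjid = c("A", "B", "C", "D"), visit = 1L, visdy = 0,
                         momagesx = c(40, NA, 35, NA),
                         dadagesx = c(50, 60, NA, NA),
                         age = c(50, 0, 30, 41),
                         caghigh = c(42, 42, 30, 42))
  out <- derive_variables(mini_cohort(data, cat))
  expect_equal(out$parentagesx, c(40, 60, 35, NA))
  expect_false(any(c("momagesx", "dadagesx") %in% names(out)))
  # printed CAP form: A x (R - L) x K
  expect_equal(out$cap[1], 50 * (42 - 30) * 6.27)
  expect_equal(out$cap[1], 3762.0, tolerance = 1e-12)
  expect_equal(out$cap[2], 0)          # A = 0
  expect_equal(out$cap[3], 0)          # R = L
  warner <- derive_variables(mini_cohort(data, cat),
                             cap_parameters(combine_mode = "divide_warner"))
  expect_equal(warner$cap[1], 50 * 12 / 6.27)
})

test_that("structural inference restores baseline, LOCF, zero and rater values", {
  cat <- dplyr::bind_rows(
    catalog_spec("mhx", "MHX", "boolean", "baseline_only", valid_min = 0, valid_max = 1),
    catalog_spec("emp", "VII", "ordinal", "change_only", valid_min = 0, valid_max = 5),
    catalog_spec("tob", "P", "boolean", valid_min = 0, valid_max = 1),
    catalog_spec("tobcpd", "P", "continuous", "conditional",
                 trigger_variable = "tob", valid_min = 0, valid_max = 80),
    catalog_spec("hddiagn", "P", "continuous", valid_min = 21, valid_max = 95),
    catalog_spec("sxrater", "P", "continuous", valid_min = 21, valid_max = 95))
  data <- tibble::tibble(
    subjid = rep(c("A", "B"), each = 4), visit = rep(1:4, 2),
    visdy = rep(c(0, 360, 720, 1080), 2),
    mhx = c(1, NA, NA, NA, NA, NA, NA, NA),
    emp = c(2, NA, 3, NA, 1, NA, NA, NA),
    tob = c(rep(0, 4), rep(1, 4)),
    tobcpd = c(NA, NA, NA, NA, 10, 10, 10, 10),
    hddiagn = c(rep(NA, 4), rep(50, 4)),
    sxrater = c(rep(47, 4), rep(49, 4)))
  out <- infer_missing(mini_cohort(data, cat))
  expect_equal(out$mhx, c(1, 1, 1, 1, NA, NA, NA, NA))  # no backward fill
  expect_equal(out$emp, c(2, 2, 3, 3, 1, 1, 1, 1))
  expect_equal(out$tobcpd[1:4], rep(0, 4))
  expect_equal(out$hddiagn[1:4], rep(47, 4))
  expect_equal(out$hddiagn[5:8], rep(50, 4))  # observed never touched
  prov <- cohort_provenance(out)
  expect_identical(unique(prov$hddiagn[1:4]), "inferred_rater")
  expect_identical(unique(prov$mhx[2:4]), "inferred_baseline")
  expect_identical(prov$emp[2], "inferred_locf")
  expect_identical(unique(prov$tobcpd[1:4]), "inferred_zero")
  # idempotence
  twice <- infer_missing(out)
  expect_identical(as.data.frame(twice), as.data.frame(out))
  expect_identical(cohort_provenance(twice), cohort_provenance(out))
})

test_that("inference recovers generator truth exactly when MCAR is off", {
  sim <- tiny_sim(n = 150, seed = 13, mcar_rate = 0,
                  high_missingness_block_rate = 0)
  co <- infer_missing(as_cohort_table(sim))
  led <- dplyr::filter(sim$truth$masked,
                       mechanism %in% c("baseline_only", "change_only",
                                        "conditional"))
  for (tab in unique(led$table)) {
    sub <- led[led$table == tab, ]
    got <- vapply(seq_len(nrow(sub)), function(i) {
      rows <- if (tab == "visits")
        which(co$subjid == sub$subjid[i] & co$visit == sub$visit[i])
      else which(co$subjid == sub$subjid[i])
      val <- co[[sub$variable[i]]][rows[1]]
      !is.na(val) && as.character(val) == sub$true_value[i]
    }, logical(1))
    expect_true(all(got))
  }
})

test_that("rater-substitution validation matches its closed form", {
  # exact copy: r = 1
  catr <- dplyr::bind_rows(
    catalog_spec("hddiagn", "P", "continuous", valid_min = 21, valid_max = 95),
    catalog_spec("sxrater", "P", "continuous", valid_min = 21, valid_max = 95))
  aao <- withr::with_seed(3, runif(50, 30, 70))
  d <- tibble::tibble(subjid = sprintf("S%02d", 1:50), visit = 1L, visdy = 0,
                      hddiagn = aao, sxrater = aao)
  expect_equal(validate_aao_substitution(mini_cohort(d, catr))$r[1], 1.0)
  # noise chosen for true r = 0.95: sigma^2 = var * (1/r^2 - 1)
  withr::with_seed(5, {
    aao2 <- rnorm(2000, 50, 10)
    sigma <- sqrt(var(aao2) * (1 / 0.95^2 - 1))
    d2 <- tibble::tibble(subjid = sprintf("S%04d", 1:2000), visit = 1L,
                         visdy = 0, hddiagn = aao2,
                         sxrater = aao2 + rnorm(2000, 0, sigma))
  })
  res <- validate_aao_substitution(mini_cohort(d2, catr))
  expect_lt(abs(res$r[1] - 0.95), 0.02)
  # a weakly correlated substitute trips the adequacy warning
  withr::with_seed(6, {
    d_lo <- dplyr::mutate(d2, sxrater = hddiagn +
                            rnorm(2000, 0, sqrt(var(hddiagn) * (1 / 0.8^2 - 1))))
  })
  expect_warning(validate_aao_substitution(mini_cohort(d_lo, catr)),
                 "not above 0.9")
  # equality with a brute-force covariance implementation
  brute_r <- sum((d2$hddiagn - mean(d2$hddiagn)) *
                   (d2$sxrater - mean(d2$sxrater))) /
    sqrt(sum((d2$hddiagn - mean(d2$hddiagn))^2) *
           sum((d2$sxrater - mean(d2$sxrater))^2))
  expect_equal(res$r[1], brute_r, tolerance = 1e-12)
  # insufficient pairs
  few <- mini_cohort(d[1:2, ], catr)
  expect_identical(validate_aao_substitution(few)$note, "insufficient pairs")
})

test_that("symptom-onset pairs are dropped or gated by their indicator", {
  cat <- dplyr::bind_rows(
    catalog_spec("ind", "P", "boolean", valid_min = 0, valid_max = 1,
                 onset_indicator_for = "ons"),
    catalog_spec("ons", "P", "continuous", valid_min = 5, valid_max = 95))
  # 25% zeros -> pair dropped
  d1 <- tibble::tibble(subjid = sprintf("S%02d", 1:20), visit = 1L, visdy = 0,
                       ind = c(rep(1, 15), rep(0, 5)),
                       ons = c(round(runif(15, 30, 60)), rep(NA, 5)))
  out1 <- filter_symptom_onsets(mini_cohort(d1, cat))
  expect_false(any(c("ind", "ons") %in% names(out1)))
  # all ones -> retained, nobody excluded
  d2 <- dplyr::mutate(d1, ind = 1, ons = 40)
  out2 <- filter_symptom_onsets(mini_cohort(d2, cat))
  expect_identical(nrow(out2), 20L)
  # retained pair, missing indicator -> participant excluded;
  # indicator 0 -> onset cell marked ineligible
  d3 <- tibble::tibble(subjid = sprintf("S%02d", 1:20), visit = 1L, visdy = 0,
                       ind = c(rep(1, 17), 0, 0, NA),
                       ons = c(round(runif(17, 30, 60)), NA, NA, NA))
  out3 <- filter_symptom_onsets(mini_cohort(d3, cat))
  expect_identical(nrow(out3), 19L)
  expect_false("S20" %in% out3$subjid)
  prov <- cohort_provenance(out3)
  expect_identical(unique(prov$ons[out3$ind == 0]), "onset_not_applicable")
})

test_that("one-hot encoding partitions observed rows and keeps missingness", {
  cat <- catalog_spec("col", "V", "nominal", categories = "red,green,blue")
  d <- tibble::tibble(subjid = c("A", "B", "C", "D"), visit = 1L, visdy = 0,
                      col = c("green", "red", NA, "blue"))
  out <- one_hot_encode(mini_cohort(d, cat))
  expect_false("col" %in% names(out))
  expect_equal(out$col_green, c(1, 0, NA, 0))
  expect_equal(out$col_red, c(0, 1, NA, 0))
  expect_equal(out$col_blue, c(0, 0, NA, 1))
  block <- cbind(out$col_red, out$col_green, out$col_blue)
  expect_true(all(rowSums(block)[c(1, 2, 4)] == 1))
  expect_true(all(is.na(block[3, ])))   # absent, not (0,0,0)
  newcat <- active_catalog(out)
  expect_setequal(newcat$encoded_from[newcat$name %in%
                                        c("col_red", "col_green", "col_blue")],
                  "col")
})

test_that("completeness is exact arithmetic and aggregates by form", {
  cat <- dplyr::bind_rows(
    catalog_spec("u", "F1", "continuous", valid_min = 0, valid_max = 1),
    catalog_spec("v", "F2", "continuous", valid_min = 0, valid_max = 1))
  d <- tibble::tibble(subjid = sprintf("S%d", 1:5), visit = 1L, visdy = 0,
                      u = c(1, NA, 3, NA, 5), v = c(NA, 2, 3, 4, 5))
  co <- mini_cohort(d, cat)
  expect_equal(as.numeric(completeness(co)), 0.7)
  pf <- attr(completeness(co), "per_form")
  expect_equal(sum(pf$completeness * pf$cells) / sum(pf$cells), 0.7)
  full <- mini_cohort(dplyr::mutate(d, u = 1, v = 2), cat)
  expect_equal(as.numeric(completeness(full)), 1.0)
  expect_error(completeness(d[0, ], cat), "empty")
})

test_that("the pipeline only reduces completeness through logged drops", {
  sim <- tiny_sim(n = 120, seed = 21)
  co <- as_cohort_table(sim)
  c0 <- as.numeric(completeness(co))
  s1 <- select_cohort(co)
  s2 <- filter_variables(s1)
  s3 <- derive_variables(s2)
  s4 <- infer_missing(s3)
  s5 <- filter_symptom_onsets(s4)
  s6 <- one_hot_encode(s5)
  cs <- vapply(list(s1, s2, s3, s4, s5, s6),
               function(x) as.numeric(completeness(x)), numeric(1))
  # every decrease step must coincide with logged drops
  dec <- which(diff(c(c0, cs)) < -1e-12)
  logs <- list(s1, s2, s3, s4, s5, s6)
  for (i in dec) {
    expect_gt(nrow(cohort_log(logs[[i]])), 0)
  }
  # observed cells are conserved through inference (no downgrade)
  p3 <- cohort_provenance(s3); p4 <- cohort_provenance(s4)
  shared <- intersect(names(p3), names(p4))
  shared <- setdiff(shared, c("subjid", "visit", "visdy"))
  n_obs3 <- sum(vapply(shared, function(v) sum(p3[[v]] == "observed",
                                               na.rm = TRUE), numeric(1)))
  n_obs4 <- sum(vapply(shared, function(v) sum(p4[[v]] == "observed",
                                               na.rm = TRUE), numeric(1)))
  expect_identical(n_obs3, n_obs4)
})
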