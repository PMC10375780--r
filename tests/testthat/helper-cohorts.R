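# Shared small fixtures, built once per test run.

tiny_sim <- function(n = 150, seed = 42, ...) {
  generate_cohort(generator_config(n_participants = n, seed = seed, ...))
}

# cached mid-size imputed cohort for driving/tensor tests
.cache <- new.env()

cached_imputed <- function() {
  if (is.null(.cache$imp)) {
    sim <- tiny_sim(n = 250, seed = 9)
    pp <- preprocess(as_cohort_table(sim))
    .cache$imp <- run_cascade(pp, seed = 9,
                              control = cascade_control(num_trees = 60,
                                                        k_folds = 5))
    .cache$sim <- sim
  }
  .cache$imp
}

cached_tensor <- function() {
  if (is.null(.cache$tensor))
    .cache$tensor <- build_tensor(cached_imputed()$table)
  .cache$tensor
}

# rebuild a small hd_cohort from rows of an existing one, reusing its catalog
new_cohort_for_test <- function(data, template) {
  cohort_from_table(tibble::as_tibble(data), active_catalog(template))
}

# a toy longitudinal table with a known linear structure, as an hd_cohort
toy_catalog <- function() {
  dplyr::bind_rows(
    catalog_spec("x1", "Toy", "continuous", valid_min = -Inf, valid_max = Inf),
    catalog_spec("x2", "Toy", "continuous", valid_min = -Inf, valid_max = Inf),
    catalog_spec("y",  "Toy", "continuous", valid_min = -Inf, valid_max = Inf)
  )
}

toy_linear_cohort <- function(n = 400, seed = 1, r2 = 0.9, mcar = 0.2) {
  withr::with_seed(seed, {
    x1 <- rnorm(n); x2 <- rnorm(n)
    signal <- x1 + x2
    noise_sd <- sqrt(var(signal) * (1 - r2) / r2)
    y <- signal + rnorm(n, 0, noise_sd)
    data <- tibble::tibble(subjid = sprintf("S%04d", seq_len(n)),
                           visit = 1L, visdy = 0, x1 = x1, x2 = x2, y = y)
    miss <- sample(n, round(mcar * n))
    truth <- y
    data$y[miss] <- NA
    co <- cohort_from_table(data, toy_catalog())
    list(cohort = co, missing_rows = miss, truth = truth)
  })
}
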