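#' Synthetic cohort generator configuration
#'
#' Defines the study conditions a generated cohort emulates: CAG-repeat
#' distribution in the HD-causing adult range, a Langbehn-type CAG to
#' age-at-onset (AAO) mean curve with covariate and family effects plus
#' Gaussian noise, one-to-five roughly annual visits with jitter and dropout,
#' structural recording rules (baseline-only, change-only, conditional,
#' symptom-onset pairs), a high-missingness variable block, optional MCAR
#' noise, and a binary driving status declining in the CAG-age product (CAP).
#'
#' @param n_participants Number of participants.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param cag_range Inclusive integer range of `caghigh`, within 36-59.
#' @param cag_weights Optional sampling weights over `cag_range`
#'   (default: geometric-like decay away from 41).
#' @param aao_noise_sd SD (years) of the individual AAO noise.
#' @param family_effect_sd SD (years) of the shared additive family effect
#'   linking participant and parent AAO.
#' @param covariate_effects Named numeric slopes (years per unit) applied to
#'   generated covariates; the family effect always enters with slope 1.
#'   Gender has zero true effect by default.
#' @param rater_noise_sd SD (years) of the rater's AAO estimate around truth.
#' @param diagnosed_prob Probability that the clinical AAO (`hddiagn`)
#'   is recorded rather than left to the rater's estimate.
#' @param visit_interval_mean Mean days between consecutive visits.
#' @param visit_interval_jitter_sd SD (days) of the visit gap.
#' @param max_visits Maximum number of visits per participant.
#' @param dropout_prob_per_visit Probability of dropping out before each
#'   subsequent visit.
#' @param mcar_rate Completely-at-random missingness rate applied to the
#'   always-recorded per-visit clinical variables.
#' @param high_missingness_block_rate Missingness rate of the WPAI-like
#'   block (set above the 0.69 exclusion threshold by default).
#' @param driving_logistic_slope Decline of driving probability per Warner
#'   CAP unit. The default is calibrated so that the latent separability of
#'   the simulated labels (label-vs-probability AUC) is about 0.9.
#' @param driving_logistic_midpoint Warner CAP value at which the driving
#'   probability crosses 0.5 (100 marks expected onset).
#' @return A validated list of class `hd_generator_config`.
#' @export
generator_config <- function(n_participants = 1000,
                             seed = 1L,
                             cag_range = c(36L, 59L),
                             cag_weights = NULL,
                             aao_noise_sd = 5,
                             family_effect_sd = 5,
                             covariate_effects = c(sex_m = 0),
                             rater_noise_sd = 6,
                             diagnosed_prob = 0.75,
                             visit_interval_mean = 365,
                             visit_interval_jitter_sd = 30,
                             max_visits = 5L,
                             dropout_prob_per_visit = 0.3,
                             mcar_rate = 0.05,
                             high_missingness_block_rate = 0.9,
                             driving_logistic_slope = 0.135,
                             driving_logistic_midpoint = 100) {
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    cag_range = as.integer(cag_range), cag_weights = cag_weights,
    aao_noise_sd = aao_noise_sd, family_effect_sd = family_effect_sd,
    covariate_effects = covariate_effects, rater_noise_sd = rater_noise_sd,
    diagnosed_prob = diagnosed_prob,
    visit_interval_mean = visit_interval_mean,
    visit_interval_jitter_sd = visit_interval_jitter_sd,
    max_visits = as.integer(max_visits),
    dropout_prob_per_visit = dropout_prob_per_visit,
    mcar_rate = mcar_rate,
    high_missingness_block_rate = high_missingness_block_rate,
    driving_logistic_slope = driving_logistic_slope,
    driving_logistic_midpoint = driving_logistic_midpoint
  )
  probs <- c(cfg$diagnosed_prob, cfg$dropout_prob_per_visit, cfg$mcar_rate,
             cfg$high_missingness_block_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    abort("configuration error: probabilities must be in [0, 1]")
  if (length(cfg$cag_range) != 2 || cfg$cag_range[1] > cfg$cag_range[2] ||
      cfg$cag_range[1] < 36L || cfg$cag_range[2] > 59L)
    abort("configuration error: cag_range must be an ordered interval within [36, 59]")
  if (cfg$aao_noise_sd < 0 || cfg$family_effect_sd < 0 || cfg$rater_noise_sd < 0)
    abort("configuration error: noise SDs must be >= 0")
  if (cfg$max_visits < 1L)
    abort("configuration error: max_visits must be >= 1")
  if (cfg$n_participants < 1L)
    abort("configuration error: n_participants must be >= 1")
  structure(cfg, class = "hd_generator_config")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample true ages at onset
#'
#' The generative AAO model: the Langbehn exponential mean curve evaluated at
#' the participant's CAG repeat length, plus a linear combination of
#' covariates (per `config$covariate_effects`), plus Gaussian noise with SD
#' `config$aao_noise_sd`. Draws below 21 years are re-sampled (up to 100
#' attempts, then an error) so the adult-onset inclusion criterion holds by
#' construction.
#'
#' @param cag Integer vector of CAG repeat lengths, inside `config$cag_range`.
#' @param covariates Optional data frame of covariate columns named in
#'   `config$covariate_effects` (missing columns count as zero).
#' @param config An [generator_config()] object.
#' @return Numeric vector of AAO in years, all `>= 21`.
#' @export
sample_true_aao <- function(cag, covariates = NULL, config = generator_config()) {
  if (any(cag < config$cag_range[1] | cag > config$cag_range[2]))
    abort("cag outside the configured cag_range")
  mu <- langbehn_predict(cag)
  eff <- config$covariate_effects
  if (!is.null(covariates) && length(eff)) {
    for (nm in names(eff)) {
      if (nm %in% names(covariates)) mu <- mu + eff[[nm]] * covariates[[nm]]
    }
  }
  if (!is.null(covariates) && "family_effect" %in% names(covariates))
    mu <- mu + covariates[["family_effect"]]
  out <- mu + rnorm(length(mu), 0, config$aao_noise_sd)
  bad <- which(out < 21)
  attempts <- 0L
  while (length(bad) > 0) {
    attempts <- attempts + 1L
    if (attempts > 100L)
      abort("failed to sample AAO >= 21 within 100 attempts")
    out[bad] <- mu[bad] + rnorm(length(bad), 0, config$aao_noise_sd)
    bad <- bad[out[bad] < 21]
  }
  out
}

#' Probability of retained driving capability at a latent CAP value
#'
#' @param cap Warner-scaled CAP values (100 marks expected onset).
#' @param config An [generator_config()] object.
#' @return `sigmoid(-slope * (cap - midpoint))`.
#' @export
driving_probability <- function(cap, config = generator_config()) {
  plogis(-config$driving_logistic_slope * (cap - config$driving_logistic_midpoint))
}

#' Simulate per-visit binary driving status
#'
#' Bernoulli draws from [driving_probability()]. As the slope grows the
#' status becomes a deterministic step at the midpoint.
#'
#' @param latent_cap Warner-scaled CAP per visit.
#' @inheritParams driving_probability
#' @return Integer vector of 0/1 statuses, one per latent value.
#' @export
simulate_driving_status <- function(latent_cap, config = generator_config()) {
  p <- driving_probability(latent_cap, config)
  rbinom(length(p), 1L, p)
}

#' Generate a synthetic Enroll-HD-shaped cohort
#'
#' Produces a per-participant profile table, a per-visit table (keyed by
#' `subjid` and days-from-baseline `visdy`), the variable catalog, and a
#' complete ground-truth record: true AAO, per-visit latent CAP and driving
#' probability, and a per-cell ledger assigning every synthetically missing
#' cell exactly one mechanism among `baseline_only`, `change_only`,
#' `conditional`, `mcar` and `symptom_unknown`.
#'
#' @param config An [generator_config()] object.
#' @return A list of class `hd_cohort_sim` with elements `profile`, `visits`,
#'   `catalog` and `truth` (`$participants`, `$visits`, `$masked`).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "hd_generator_config"))
  with_local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_participants
  catalog <- default_catalog()
  subjid <- sprintf("P%05d", seq_len(n))

  cags <- seq(config$cag_range[1], config$cag_range[2])
  w <- config$cag_weights %||% 0.75^abs(cags - 41)
  caghigh <- sample(cags, n, replace = TRUE, prob = w / sum(w))
  caglow <- pmin(caghigh - 1L, sample(10:28, n, replace = TRUE))
  sex <- sample(c("f", "m"), n, replace = TRUE)
  momhd <- rbinom(n, 1L, 0.5)
  dadhd <- ifelse(momhd == 1L, rbinom(n, 1L, 0.05), rbinom(n, 1L, 0.85))
  fhx <- as.integer(momhd == 1L | dadhd == 1L)
  family_effect <- rnorm(n, 0, config$family_effect_sd)

  covars <- tibble(family_effect = family_effect,
                   sex_m = as.numeric(sex == "m"))
  true_aao <- sample_true_aao(caghigh, covars, config)

  parent_onset <- function(ind) {
    val <- 45 + family_effect + rnorm(n, 0, 5)
    ifelse(ind == 1L, clamp(val, 20, 90), NA_real_)
  }
  momagesx <- parent_onset(momhd)
  dadagesx <- parent_onset(dadhd)

  # indicator variables can themselves be unknown
  momhd_obs <- replace(momhd, runif(n) < 0.03, NA_integer_)
  dadhd_obs <- replace(dadhd, runif(n) < 0.03, NA_integer_)
  momagesx_obs <- ifelse(!is.na(momhd_obs) & momhd_obs == 1L, momagesx, NA_real_)
  dadagesx_obs <- ifelse(!is.na(dadhd_obs) & dadhd_obs == 1L, dadagesx, NA_real_)
  fhx_obs <- ifelse(is.na(momhd_obs) & is.na(dadhd_obs), NA_integer_, fhx)

  u <- runif(n)
  ccmtr <- ifelse(u < 0.88, 1L, ifelse(u < 0.95, 0L, NA_integer_))
  ccmtrage <- ifelse(!is.na(ccmtr) & ccmtr == 1L,
                     clamp(true_aao + rnorm(n, 0, 1.5), 5, 95), NA_real_)
  u <- runif(n)
  ccdep <- ifelse(u < 0.45, 1L, ifelse(u < 0.90, 0L, NA_integer_))
  ccdepage <- ifelse(!is.na(ccdep) & ccdep == 1L,
                     clamp(true_aao + rnorm(n, 0, 8), 5, 95), NA_real_)

  diagnosed <- rbinom(n, 1L, config$diagnosed_prob) == 1L
  hddiagn <- ifelse(diagnosed, round(true_aao, 1), NA_real_)
  sxrater <- round(pmax(21, true_aao + rnorm(n, 0, config$rater_noise_sd)), 1)
  sxestcnf <- sample(c("low", "unknown", "high"), n, replace = TRUE,
                     prob = c(0.2, 0.3, 0.5))

  tob <- rbinom(n, 1L, 0.3)
  tobcpd <- ifelse(tob == 1L, round(clamp(rnorm(n, 12, 6), 1, 80)), NA_real_)
  tobyos <- ifelse(tob == 1L, round(clamp(rnorm(n, 15, 8), 1, 70)), NA_real_)

  baseline_age <- pmax(21.5, true_aao + runif(n, -10, 12))

  profile <- tibble(
    subjid = subjid, caghigh = as.numeric(caghigh), caglow = as.numeric(caglow),
    sex = sex, fhx = fhx_obs, momhd = momhd_obs, momagesx = round(momagesx_obs, 1),
    dadhd = dadhd_obs, dadagesx = round(dadagesx_obs, 1),
    hddiagn = hddiagn, sxrater = sxrater, sxestcnf = sxestcnf,
    ccmtr = ccmtr, ccmtrage = round(ccmtrage, 1),
    ccdep = ccdep, ccdepage = round(ccdepage, 1),
    tob = tob, tobcpd = tobcpd, tobyos = tobyos
  )

  masked <- list()
  note <- function(table, sids, visit_ids, variable, mechanism, true_values) {
    if (length(sids) == 0) return(invisible(NULL))
    masked[[length(masked) + 1L]] <<- tibble(
      table = table, subjid = sids, visit = visit_ids, variable = variable,
      mechanism = mechanism, true_value = as.character(true_values)
    )
  }
  # profile-level mechanisms (symptom_unknown and conditional)
  for (v in c("momhd", "dadhd", "fhx", "momagesx", "dadagesx",
              "ccmtr", "ccmtrage", "ccdep", "ccdepage")) {
    col <- switch(v, momhd = momhd_obs, dadhd = dadhd_obs, fhx = fhx_obs,
                  momagesx = momagesx_obs, dadagesx = dadagesx_obs,
                  ccmtr = ccmtr, ccmtrage = ccmtrage,
                  ccdep = ccdep, ccdepage = ccdepage)
    idx <- which(is.na(col))
    note("profile", subjid[idx], rep(NA_integer_, length(idx)), v,
         "symptom_unknown", rep(NA_character_, length(idx)))
  }
  idx <- which(is.na(hddiagn))
  note("profile", subjid[idx], rep(NA_integer_, length(idx)), "hddiagn",
       "symptom_unknown", round(true_aao[idx], 1))
  idx <- which(tob == 0L)
  note("profile", subjid[idx], rep(NA_integer_, length(idx)), "tobcpd",
       "conditional", rep(0, length(idx)))
  note("profile", subjid[idx], rep(NA_integer_, length(idx)), "tobyos",
       "conditional", rep(0, length(idx)))

  # per-visit data
  n_visits <- vapply(seq_len(n), function(i) {
    v <- 1L
    while (v < config$max_visits && runif(1) >= config$dropout_prob_per_visit)
      v <- v + 1L
    v
  }, integer(1))

  mhx1 <- rbinom(n, 1L, 0.3); mhx2 <- rbinom(n, 1L, 0.2)
  mhx3 <- sample(0:3, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))

  visit_rows <- vector("list", n)
  truth_visit_rows <- vector("list", n)
  K_WARNER <- 6.27
  for (i in seq_len(n)) {
    nv <- n_visits[i]
    gaps <- if (nv > 1)
      pmax(180, rnorm(nv - 1, config$visit_interval_mean,
                      config$visit_interval_jitter_sd)) else numeric(0)
    visdy <- c(0, round(cumsum(gaps)))
    age <- baseline_age[i] + visdy / 365.25
    cap_w <- age * (caghigh[i] - 30) / K_WARNER
    s <- cap_w - 100
    ms <- vapply(1:4, function(j)
      clamp(round(4 * plogis(s / 15) + rnorm(nv, 0, 0.6)), 0, 4), numeric(nv))
    ms <- matrix(ms, nrow = nv)
    motscore <- rowSums(ms)
    tfc <- clamp(round(13 * (1 - plogis(s / 18)) + rnorm(nv, 0, 0.8)), 0, 13)
    sdmt <- round(clamp(55 - 25 * plogis(s / 20) + rnorm(nv, 0, 6), 0, 110), 1)
    verfct <- round(clamp(40 - 15 * plogis(s / 20) + rnorm(nv, 0, 5), 0, 60), 1)
    p_drive <- driving_probability(cap_w, config)
    driving <- rbinom(nv, 1L, p_drive)
    emp_lat <- cap_w + rnorm(nv, 0, 20)
    employ <- ifelse(emp_lat < 95, "employed",
                     ifelse(emp_lat < 115, "unemployed", "retired"))
    caresit <- ifelse(cap_w + rnorm(nv, 0, 20) < 100, 0,
                      ifelse(cap_w + rnorm(nv, 0, 20) < 125, 1, 2))
    wpai1 <- round(clamp(rnorm(nv, 5, 2), 0, 10), 1)
    wpai2 <- round(clamp(rnorm(nv, 4, 2), 0, 10), 1)

    visit_rows[[i]] <- tibble(
      subjid = subjid[i], visit = seq_len(nv), visdy = visdy,
      age = round(age, 2),
      ms1 = ms[, 1], ms2 = ms[, 2], ms3 = ms[, 3], ms4 = ms[, 4],
      motscore = motscore, tfc = tfc, sdmt = sdmt, verfct = verfct,
      employ = employ, caresit = caresit,
      mhx1 = as.numeric(mhx1[i]), mhx2 = as.numeric(mhx2[i]),
      mhx3 = as.numeric(mhx3[i]),
      wpai1 = wpai1, wpai2 = wpai2, driving = driving
    )
    truth_visit_rows[[i]] <- tibble(
      subjid = subjid[i], visit = seq_len(nv),
      cap_warner = cap_w, p_drive = p_drive
    )
  }
  visits <- bind_rows(visit_rows)
  truth_visits <- bind_rows(truth_visit_rows)

  # structural masking on the visit table -----------------------------------
  nvr <- nrow(visits)
  later <- which(visits$visit > 1L)
  for (v in c("mhx1", "mhx2", "mhx3")) {
    note("visits", visits$subjid[later], visits$visit[later], v,
         "baseline_only", visits[[v]][later])
    visits[[v]][later] <- NA_real_
  }
  # change-only recording: keep the first visit and changes, blank repeats;
  # a cell equal to the last *recorded* value collapses onto that record
  for (v in c("employ", "caresit")) {
    rec <- visits[[v]]
    hit <- integer(0)
    for (k in later) {
      back <- k - 1L
      while (back > 1L && visits$subjid[back] == visits$subjid[k] &&
             is.na(rec[back]))
        back <- back - 1L
      lastrec <- rec[back]
      if (!is.na(lastrec) && lastrec == visits[[v]][k]) {
        hit <- c(hit, k)
        rec[k] <- NA
      }
    }
    note("visits", visits$subjid[hit], visits$visit[hit], v, "change_only",
         visits[[v]][hit])
    visits[[v]] <- rec
  }
  # WPAI-like high-missingness block
  if (config$high_missingness_block_rate > 0) {
    for (v in c("wpai1", "wpai2")) {
      hit <- which(runif(nvr) < config$high_missingness_block_rate)
      note("visits", visits$subjid[hit], visits$visit[hit], v, "mcar",
           visits[[v]][hit])
      visits[[v]][hit] <- NA_real_
    }
  }
  # MCAR on the always-recorded clinical core
  if (config$mcar_rate > 0) {
    for (v in c("ms1", "ms2", "ms3", "ms4", "tfc", "sdmt", "verfct", "driving")) {
      hit <- which(runif(nvr) < config$mcar_rate & !is.na(visits[[v]]))
      note("visits", visits$subjid[hit], visits$visit[hit], v, "mcar",
           visits[[v]][hit])
      visits[[v]][hit] <- NA
    }
  }

  truth <- list(
    participants = tibble(
      subjid = subjid, true_aao = true_aao, family_effect = family_effect,
      baseline_age = baseline_age, caghigh = as.numeric(caghigh),
      n_visits = n_visits, diagnosed = diagnosed
    ),
    visits = truth_visits,
    masked = if (length(masked)) bind_rows(masked) else
      tibble(table = character(), subjid = character(), visit = integer(),
             variable = character(), mechanism = character(),
             true_value = character())
  )
  structure(list(profile = profile, visits = visits, catalog = catalog,
                 truth = truth, config = config),
            class = "hd_cohort_sim")
}

#' Latent label separability of a simulated cohort
#'
#' AUC of the true driving probability as a score for the sampled binary
#' status — the ceiling any classifier trained on the cohort can approach.
#'
#' @param sim An `hd_cohort_sim` object.
#' @return AUC in `[0.5, 1]`.
#' @export
driving_separability <- function(sim) {
  lab <- sim$visits$driving
  p <- sim$truth$visits$p_drive
  keep <- !is.na(lab)
  auc_score(lab[keep], p[keep])
}

#' Write a simulated cohort to a directory
#'
#' Emits `profile.csv`, `visits.csv`, `catalog.csv` and `truth.json`.
#'
#' @param sim An `hd_cohort_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(sim$profile, file.path(dir, "profile.csv"), row.names = FALSE)
  write.csv(sim$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  write.csv(as.data.frame(sim$catalog), file.path(dir, "catalog.csv"),
            row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null", digits = NA)
  invisible(dir)
}
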