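#' CAP score parameters
#'
#' The CAG-age product is computed from current age `A` and the larger CAG
#' allele length `R` as `C = A * (R - L) * K` (`multiply_as_printed`) or
#' `C = A * (R - L) / K` (`divide_warner`). The Warner scaling is the one
#' under which CAP = 100 marks expected motor onset; both modes are provided
#' because the two conventions disagree by a factor `K^2`.
#'
#' @param L Repeat offset, default 30.
#' @param K Scale constant, default 6.27.
#' @param combine_mode `"multiply_as_printed"` or `"divide_warner"`.
#' @return A list of class `hd_cap_parameters`.
#' @export
cap_parameters <- function(L = 30, K = 6.27,
                           combine_mode = c("multiply_as_printed", "divide_warner")) {
  if (K <= 0) abort("K must be > 0")
  structure(list(L = L, K = K, combine_mode = match.arg(combine_mode)),
            class = "hd_cap_parameters")
}

#' Outlier flagging rule
#'
#' Continuous values are flagged when they lie strictly outside
#' `mean +/- n_sigma * sd`. Flagging is report-only: values are never
#' mutated (flagged values are for human review).
#'
#' @param n_sigma SD multiplier, default 4.
#' @return A list of class `hd_outlier_rule`.
#' @export
outlier_rule <- function(n_sigma = 4) {
  if (n_sigma <= 0) abort("n_sigma must be > 0")
  structure(list(n_sigma = n_sigma, action = "report_only"),
            class = "hd_outlier_rule")
}

#' Apply the cohort inclusion criteria
#'
#' Excludes juvenile-onset participants (clinical AAO `hddiagn` or rater
#' estimate `sxrater` below 21 years) and participants with `caghigh`
#' outside the adult HD-causing range 36-59. Every exclusion is logged with
#' its reason.
#'
#' @param table An `hd_cohort`.
#' @return The filtered `hd_cohort`.
#' @export
select_cohort <- function(table) {
  need <- c("hddiagn", "sxrater", "caghigh")
  if (!all(need %in% names(table)))
    abort(paste("schema error: missing columns:",
                paste(setdiff(need, names(table)), collapse = ", ")))
  per <- table %>%
    group_by(.data$subjid) %>%
    summarise(hddiagn = first(.data$hddiagn), sxrater = first(.data$sxrater),
              caghigh = first(.data$caghigh), .groups = "drop")
  juvenile <- (!is.na(per$hddiagn) & per$hddiagn < 21) |
              (!is.na(per$sxrater) & per$sxrater < 21)
  cag_high <- !is.na(per$caghigh) & per$caghigh > 59
  cag_low <- !is.na(per$caghigh) & per$caghigh < 36
  out <- table
  out <- log_event(out, "select_cohort", "exclude_participant",
                   per$subjid[juvenile], "aao_below_21")
  out <- log_event(out, "select_cohort", "exclude_participant",
                   per$subjid[cag_high & !juvenile], "caghigh_above_59")
  out <- log_event(out, "select_cohort", "exclude_participant",
                   per$subjid[cag_low & !juvenile & !cag_high], "caghigh_below_36")
  drop <- per$subjid[juvenile | cag_high | cag_low]
  drop_cohort_rows(out, which(out$subjid %in% drop))
}

#' Drop high-missingness and configured variables
#'
#' Variables whose missing fraction strictly exceeds `missing_threshold`
#' are dropped as `high_missing`; variables on `drop_list` are dropped under
#' their configured category (`redundant`, `used_in_derived`,
#' `no_information`, `other`). Unknown names in `drop_list` raise a warning,
#' not an error.
#'
#' @param table An `hd_cohort`.
#' @param catalog Variable catalog (default: the active catalog).
#' @param missing_threshold Fraction in (0, 1); strict comparison.
#' @param drop_list Optional tibble with columns `variable` and `category`.
#' @return The pruned `hd_cohort` (catalog pruned in step).
#' @export
filter_variables <- function(table, catalog = active_catalog(table),
                             missing_threshold = 0.69, drop_list = NULL) {
  if (missing_threshold <= 0 || missing_threshold >= 1)
    abort("missing_threshold must be in (0, 1)")
  vars <- analysis_vars(table, catalog)
  frac <- vapply(vars, function(v) mean(is.na(table[[v]])), numeric(1))
  high <- vars[frac > missing_threshold]
  out <- log_event(table, "filter_variables", "drop_variable", high, "high_missing")
  out <- drop_cohort_cols(out, high)
  if (!is.null(drop_list)) {
    unknown <- setdiff(drop_list$variable, names(out))
    if (length(unknown))
      warn(paste("drop_list names unknown variables:",
                 paste(unknown, collapse = ", ")))
    dl <- drop_list[drop_list$variable %in% names(out), ]
    for (i in seq_len(nrow(dl))) {
      out <- log_event(out, "filter_variables", "drop_variable",
                       dl$variable[i], dl$category[i])
    }
    out <- drop_cohort_cols(out, dl$variable)
  }
  out
}

#' Flag numerical outliers (report-only)
#'
#' Scans every continuous catalog variable for values strictly outside
#' `mean +/- n_sigma * sd` (moments over the variable's non-missing cells).
#' The data is never mutated; constant columns yield no flags; variables
#' with fewer than two observations are skipped and listed in the
#' `skipped` attribute.
#'
#' @param table An `hd_cohort`.
#' @param catalog Variable catalog.
#' @param rule An [outlier_rule()].
#' @return A tibble of flags (`subjid`, `visit`, `variable`, `value`,
#'   `mean`, `sd`), with attribute `skipped`.
#' @export
detect_numeric_outliers <- function(table, catalog = active_catalog(table),
                                    rule = outlier_rule()) {
  vars <- intersect(catalog$name[catalog$dtype == "continuous"], names(table))
  skipped <- character(0)
  flags <- purrr::map_dfr(vars, function(v) {
    x <- table[[v]]
    obs <- which(!is.na(x))
    if (length(obs) < 2) {
      skipped <<- c(skipped, v)
      return(NULL)
    }
    mu <- mean(x[obs]); sig <- sd(x[obs])
    hit <- obs[abs(x[obs] - mu) > rule$n_sigma * sig]
    if (length(hit) == 0) return(NULL)
    tibble(subjid = table$subjid[hit],
           visit = if ("visit" %in% names(table)) table$visit[hit] else NA_integer_,
           variable = v, value = x[hit], mean = mu, sd = sig)
  })
  if (nrow(flags) == 0)
    flags <- tibble(subjid = character(), visit = integer(),
                    variable = character(), value = numeric(),
                    mean = numeric(), sd = numeric())
  attr(flags, "skipped") <- skipped
  flags
}

#' Compute derived variables (parent AAO and CAP)
#'
#' `parentagesx` is the younger of the recorded parental onset ages (the one
#' recorded if only one is; missing if both are). The CAP score combines
#' current age and excess repeat length per [cap_parameters()]. The parental
#' source columns are removed afterwards (logged as `used_in_derived`).
#'
#' @param table An `hd_cohort`.
#' @param cap_params A [cap_parameters()] object.
#' @return The `hd_cohort` with `parentagesx` and `cap` columns.
#' @export
derive_variables <- function(table, cap_params = cap_parameters()) {
  out <- table
  prov <- attr(out, "provenance")
  cat <- attr(out, "catalog")
  if (all(c("momagesx", "dadagesx") %in% names(out))) {
    parent <- pmin(out$momagesx, out$dadagesx, na.rm = TRUE)
    out$parentagesx <- parent
    prov$parentagesx <- ifelse(is.na(parent), NA_character_, "observed")
    cat <- bind_rows(cat, catalog_spec(
      "parentagesx", "Profile", "continuous",
      valid_min = 15, valid_max = 95, level = "profile"))
    attr(out, "provenance") <- prov
    attr(out, "catalog") <- cat
    out <- log_event(out, "derive_variables", "create_variable",
                     "parentagesx", "min_of_parent_aao")
    out <- log_event(out, "derive_variables", "drop_variable",
                     c("momagesx", "dadagesx"), "used_in_derived")
    out <- drop_cohort_cols(out, c("momagesx", "dadagesx"))
  }
  if (all(c("age", "caghigh") %in% names(out))) {
    excess <- out$caghigh - cap_params$L
    cap <- if (cap_params$combine_mode == "multiply_as_printed")
      out$age * excess * cap_params$K else out$age * excess / cap_params$K
    out$cap <- cap
    prov <- attr(out, "provenance")
    prov$cap <- ifelse(is.na(cap), NA_character_, "observed")
    attr(out, "provenance") <- prov
    attr(out, "catalog") <- bind_rows(
      attr(out, "catalog"),
      catalog_spec("cap", "Derived", "continuous",
                   valid_min = 0, valid_max = Inf))
    miss <- unique(out$subjid[is.na(cap)])
    out <- log_event(out, "derive_variables", "cap_missing", miss,
                     "caghigh_or_age_missing")
    out <- log_event(out, "derive_variables", "create_variable", "cap",
                     cap_params$combine_mode)
  }
  out
}

#' Infer structurally missing values
#'
#' Deterministic recovery of recording-rule missingness, in visit order
#' within participant (never backwards):
#' \itemize{
#'   \item baseline-only variables: the first-visit value is copied to later
#'     visits (`inferred_baseline`);
#'   \item change-only variables: last observation carried forward
#'     (`inferred_locf`);
#'   \item conditional variables whose trigger records 0 (not applicable):
#'     set to 0 (`inferred_zero`);
#'   \item missing clinical AAO with a rater estimate present:
#'     `hddiagn <- sxrater` (`inferred_rater`).
#' }
#' Running it twice equals running it once.
#'
#' @param table An `hd_cohort`, rows ordered by `visdy` within participant.
#' @param catalog Variable catalog.
#' @return The `hd_cohort` with structural gaps filled.
#' @export
infer_missing <- function(table, catalog = active_catalog(table)) {
  out <- table
  stopifnot(!is.unsorted(order(out$subjid, out$visdy)))
  sid <- out$subjid
  first_of_subj <- !duplicated(sid)

  for (v in intersect(catalog$name[catalog$recording_rule == "baseline_only"],
                      names(out))) {
    base <- out[[v]][first_of_subj]
    names(base) <- sid[first_of_subj]
    fill <- base[sid]
    rows <- which(is.na(out[[v]]) & !is.na(fill))
    out <- set_cells(out, rows, v, unname(fill[rows]), "inferred_baseline")
  }
  for (v in intersect(catalog$name[catalog$recording_rule == "change_only"],
                      names(out))) {
    x <- out[[v]]
    filled <- x
    for (k in seq_along(x)) {
      if (k > 1 && sid[k] == sid[k - 1] && is.na(filled[k]))
        filled[k] <- filled[k - 1]
    }
    rows <- which(is.na(x) & !is.na(filled))
    out <- set_cells(out, rows, v, filled[rows], "inferred_locf")
  }
  cond <- catalog[catalog$recording_rule == "conditional" &
                    catalog$name %in% names(out), ]
  for (i in seq_len(nrow(cond))) {
    v <- cond$name[i]; trig <- cond$trigger_variable[i]
    if (!trig %in% names(out)) next
    rows <- which(is.na(out[[v]]) & !is.na(out[[trig]]) & out[[trig]] == 0)
    out <- set_cells(out, rows, v, 0, "inferred_zero")
  }
  if (all(c("hddiagn", "sxrater") %in% names(out))) {
    rows <- which(is.na(out$hddiagn) & !is.na(out$sxrater))
    out <- set_cells(out, rows, "hddiagn", out$sxrater[rows], "inferred_rater")
  }
  out
}

#' Validate the rater substitution for clinical AAO
#'
#' Pearson correlation between the clinically diagnosed AAO and the rater's
#' estimate on participants where both were originally observed, overall and
#' per rater-confidence level (`sxestcnf` if present). A warning is emitted
#' if the overall r does not exceed 0.9.
#'
#' @param table An `hd_cohort` (before or after [infer_missing()]; original
#'   observation status is read from provenance).
#' @return A tibble with columns `level`, `n`, `r`, `p`. Fewer than three
#'   doubly-observed participants yields a one-row "insufficient pairs"
#'   report and no warning.
#' @export
validate_aao_substitution <- function(table) {
  prov <- cohort_provenance(table)
  per <- tibble(subjid = table$subjid,
                hddiagn = table$hddiagn, sxrater = table$sxrater,
                hd_obs = prov$hddiagn == "observed" & !is.na(prov$hddiagn),
                level = if ("sxestcnf" %in% names(table))
                  table$sxestcnf else NA_character_) %>%
    filter(.data$hd_obs, !is.na(.data$sxrater)) %>%
    distinct(.data$subjid, .keep_all = TRUE)
  if (nrow(per) < 3)
    return(tibble(level = "overall", n = nrow(per), r = NA_real_, p = NA_real_,
                  note = "insufficient pairs"))
  ct <- stats::cor.test(per$hddiagn, per$sxrater)
  res <- tibble(level = "overall", n = nrow(per),
                r = unname(ct$estimate), p = ct$p.value, note = NA_character_)
  lv <- per %>% filter(!is.na(.data$level)) %>% group_by(.data$level)
  if (dplyr::n_groups(lv) > 0) {
    by_lvl <- lv %>%
      summarise(n = dplyr::n(),
                r = if (dplyr::n() >= 3) cor(.data$hddiagn, .data$sxrater) else NA_real_,
                p = if (dplyr::n() >= 3)
                  stats::cor.test(.data$hddiagn, .data$sxrater)$p.value else NA_real_,
                .groups = "drop") %>%
      mutate(note = NA_character_)
    res <- bind_rows(res, by_lvl)
  }
  if (!is.na(res$r[1]) && res$r[1] <= 0.9)
    warn(sprintf("rater-substitution correlation r = %.3f is not above 0.9",
                 res$r[1]))
  res
}

#' Filter symptom-onset variable pairs
#'
#' Each onset-age variable is gated by an indicator (1 = onset occurred,
#' 0 = not yet, missing = unknown). If more than `max_unknown_fraction` of
#' participants record 0 or missing for the indicator, the pair is dropped.
#' For retained pairs, participants with a missing indicator are excluded,
#' and onset cells whose indicator is 0 are marked `onset_not_applicable`
#' (never eligible for imputation).
#'
#' @param table An `hd_cohort`.
#' @param catalog Variable catalog (pairs are declared via
#'   `onset_indicator_for`).
#' @param max_unknown_fraction Pair-dropping threshold, default 0.20.
#' @return The filtered `hd_cohort`.
#' @export
filter_symptom_onsets <- function(table, catalog = active_catalog(table),
                                  max_unknown_fraction = 0.20) {
  pairs <- catalog[!is.na(catalog$onset_indicator_for), c("name", "onset_indicator_for")]
  pairs <- pairs[pairs$onset_indicator_for %in% names(table) &
                   pairs$name %in% names(table), ]
  out <- table
  for (i in seq_len(nrow(pairs))) {
    ind <- pairs$name[i]; onset <- pairs$onset_indicator_for[i]
    per <- out %>% distinct(.data$subjid, .keep_all = TRUE)
    bad <- mean(is.na(per[[ind]]) | per[[ind]] == 0)
    if (bad > max_unknown_fraction) {
      out <- log_event(out, "filter_symptom_onsets", "drop_pair",
                       c(ind, onset),
                       sprintf("indicator_unknown_fraction_%.3f", bad))
      out <- drop_cohort_cols(out, c(ind, onset))
      next
    }
    excl <- unique(out$subjid[is.na(out[[ind]])])
    out <- log_event(out, "filter_symptom_onsets", "exclude_participant",
                     excl, paste0("missing_indicator_", ind))
    out <- drop_cohort_rows(out, which(out$subjid %in% excl))
    rows <- which(!is.na(out[[ind]]) & out[[ind]] == 0 & is.na(out[[onset]]))
    prov <- attr(out, "provenance")
    prov[[onset]][rows] <- "onset_not_applicable"
    attr(out, "provenance") <- prov
  }
  out
}

#' One-hot encode nominal variables
#'
#' Every nominal variable with C categories becomes C boolean indicator
#' columns named `<var>_<category>`. A missing source value yields C missing
#' indicators (absence is not the same as all-negative). The catalog is
#' updated in step, recording the source variable in `encoded_from`.
#'
#' @param table An `hd_cohort`.
#' @param catalog Variable catalog.
#' @return The encoded `hd_cohort` (catalog updated in step).
#' @export
one_hot_encode <- function(table, catalog = active_catalog(table)) {
  noms <- intersect(catalog$name[catalog$dtype == "nominal"], names(table))
  out <- table
  for (v in noms) {
    lvls <- cat_levels(catalog, v)
    if (length(lvls) == 1)
      warn(sprintf("nominal variable '%s' has a single category", v))
    prov <- attr(out, "provenance")
    row <- attr(out, "catalog")[attr(out, "catalog")$name == v, ]
    for (lv in lvls) {
      newv <- paste0(v, "_", lv)
      out[[newv]] <- ifelse(is.na(out[[v]]), NA_real_,
                            as.numeric(out[[v]] == lv))
      prov[[newv]] <- prov[[v]]
      spec <- catalog_spec(newv, row$form, "boolean", row$recording_rule,
                           trigger_variable = row$trigger_variable,
                           valid_min = 0, valid_max = 1, level = row$level)
      spec$encoded_from <- v
      attr(out, "catalog") <- bind_rows(attr(out, "catalog"), spec)
    }
    attr(out, "provenance") <- prov
    out <- log_event(out, "one_hot_encode", "encode_variable", v,
                     paste0("categories_", length(lvls)))
    out <- drop_cohort_cols(out, v)
  }
  out
}

#' Run the full pre-processing sequence
#'
#' Inclusion criteria, variable filtering, outlier flagging (report-only),
#' derived variables, structural inference, rater-substitution validation,
#' symptom-onset filtering and one-hot encoding, in that order. The returned
#' cohort carries a `reports` attribute with the outlier flags, the AAO
#' substitution report, and completeness before/after.
#'
#' @param table An `hd_cohort` from [as_cohort_table()].
#' @param missing_threshold Variable-exclusion threshold for missingness.
#' @param cap_params A [cap_parameters()] object.
#' @param drop_list Optional configured drop list (see [filter_variables()]).
#' @param max_unknown_fraction Symptom-pair threshold.
#' @return The pre-processed `hd_cohort`.
#' @export
preprocess <- function(table, missing_threshold = 0.69,
                       cap_params = cap_parameters(),
                       drop_list = NULL, max_unknown_fraction = 0.20) {
  before <- completeness(table)
  out <- select_cohort(table)
  out <- filter_variables(out, missing_threshold = missing_threshold,
                          drop_list = drop_list)
  outliers <- detect_numeric_outliers(out)
  out <- derive_variables(out, cap_params)
  out <- infer_missing(out)
  aao_rep <- validate_aao_substitution(out)
  out <- filter_symptom_onsets(out, max_unknown_fraction = max_unknown_fraction)
  out <- one_hot_encode(out)
  after <- completeness(out)
  attr(out, "reports") <- list(outliers = outliers,
                               aao_substitution = aao_rep,
                               completeness_before = before,
                               completeness_after = after)
  out
}
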