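#' Cohort tables
#'
#' An `hd_cohort` is a tibble with one row per participant-visit (profile
#' variables repeated across a participant's visits) plus three attributes
#' kept in sync by every pre-processing verb:
#' \itemize{
#'   \item `provenance`: a character tibble of the same shape tagging each
#'     cell (`observed`, `inferred_baseline`, `inferred_locf`,
#'     `inferred_zero`, `inferred_rater`, `imputed_ml`,
#'     `recomputed_composite`, plus the internal `onset_not_applicable`
#'     marker for known-not-applicable onset cells that stay empty);
#'   \item `catalog`: the active [catalog_spec()] table;
#'   \item `log`: an append-only tibble of decisions (stage, action, target,
#'     reason).
#' }
#' @name hd_cohort
NULL

new_cohort <- function(data, provenance, catalog, log = NULL) {
  log <- log %||% tibble(stage = character(), action = character(),
                         target = character(), reason = character())
  structure(data,
            provenance = provenance, catalog = catalog, log = log,
            class = c("hd_cohort", class(tibble())))
}

#' Build the analysis table from a simulated cohort
#'
#' Joins the per-visit table to the participant profile and initialises
#' per-cell provenance (`observed` wherever a value is present).
#'
#' @param sim An `hd_cohort_sim` from [generate_cohort()], or a list with
#'   `profile`, `visits` and `catalog` elements.
#' @return An `hd_cohort` tibble ordered by participant and `visdy`.
#' @export
as_cohort_table <- function(sim) {
  data <- dplyr::left_join(sim$visits, sim$profile, by = "subjid") %>%
    arrange(.data$subjid, .data$visdy)
  prov <- make_provenance(data)
  new_cohort(data, prov, sim$catalog)
}

make_provenance <- function(data) {
  prov <- as_tibble(lapply(data, function(col)
    ifelse(is.na(col), NA_character_, "observed")))
  for (key in intersect(c("subjid", "visit", "visdy"), names(prov)))
    prov[[key]] <- data[[key]]
  prov
}

#' Per-cell provenance of a cohort table
#' @param x An `hd_cohort`.
#' @return A character tibble mirroring the data.
#' @export
cohort_provenance <- function(x) attr(x, "provenance")

#' Decision log of a cohort table
#' @param x An `hd_cohort`.
#' @return A tibble with columns stage, action, target, reason.
#' @export
cohort_log <- function(x) attr(x, "log")

#' Active variable catalog of a cohort table
#' @param x An `hd_cohort`.
#' @return An `hd_catalog` tibble.
#' @export
active_catalog <- function(x) attr(x, "catalog")

log_event <- function(x, stage, action, target, reason) {
  if (length(target) == 0) return(x)
  attr(x, "log") <- bind_rows(
    attr(x, "log"),
    tibble(stage = stage, action = action,
           target = as.character(target), reason = reason))
  x
}

# assign values + provenance for given row indices of one variable;
# observed cells are never overwritten unless overwrite = TRUE
set_cells <- function(x, rows, var, values, tag, overwrite = FALSE) {
  if (length(rows) == 0) return(x)
  prov <- attr(x, "provenance")
  if (!overwrite) {
    keep <- is.na(prov[[var]][rows]) | prov[[var]][rows] != "observed"
    rows <- rows[keep]
    values <- if (length(values) > 1) values[keep] else values
    if (length(rows) == 0) return(x)
  }
  x[[var]][rows] <- values
  prov[[var]][rows] <- tag
  attr(x, "provenance") <- prov
  x
}

drop_cohort_cols <- function(x, vars) {
  vars <- intersect(vars, names(x))
  if (length(vars) == 0) return(x)
  prov <- attr(x, "provenance")
  cat <- attr(x, "catalog")
  keep <- setdiff(names(x), vars)
  out <- x[, keep]
  attr(out, "provenance") <- prov[, keep]
  attr(out, "catalog") <- cat[!(cat$name %in% vars), ]
  attr(out, "log") <- attr(x, "log")
  class(out) <- class(x)
  out
}

drop_cohort_rows <- function(x, rows) {
  if (length(rows) == 0) return(x)
  prov <- attr(x, "provenance")
  out <- x[-rows, ]
  attr(out, "provenance") <- prov[-rows, ]
  attr(out, "catalog") <- attr(x, "catalog")
  attr(out, "log") <- attr(x, "log")
  class(out) <- class(x)
  out
}

#' Variables of a cohort table covered by the catalog
#' @noRd
analysis_vars <- function(x, catalog = active_catalog(x)) {
  intersect(catalog$name, names(x))
}

#' Fraction of non-missing cells
#'
#' Completeness over all catalog-covered cells of the table: non-missing
#' cells divided by total cells. When a catalog is supplied the result also
#' carries a `per_form` attribute with the per-form fractions and cell
#' counts, whose cell-weighted mean equals the overall value exactly.
#'
#' @param table An `hd_cohort` (or any data frame).
#' @param catalog Variable catalog; defaults to the table's active catalog.
#' @return The overall fraction in `[0, 1]`, with attribute `per_form`.
#' @export
completeness <- function(table, catalog = NULL) {
  catalog <- catalog %||% attr(table, "catalog")
  vars <- if (!is.null(catalog)) intersect(catalog$name, names(table))
          else setdiff(names(table), c("subjid", "visit", "visdy"))
  if (length(vars) == 0 || nrow(table) == 0) abort("empty table")
  miss <- vapply(vars, function(v) sum(is.na(table[[v]])), numeric(1))
  cells <- nrow(table) * length(vars)
  overall <- 1 - sum(miss) / cells
  if (!is.null(catalog)) {
    per_form <- tibble(variable = vars,
                       form = catalog$form[match(vars, catalog$name)],
                       missing = miss) %>%
      group_by(.data$form) %>%
      summarise(cells = dplyr::n() * nrow(table),
                completeness = 1 - sum(.data$missing) / .data$cells,
                .groups = "drop")
    attr(overall, "per_form") <- per_form
  }
  overall
}
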