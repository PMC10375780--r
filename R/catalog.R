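#' Variable catalog
#'
#' The catalog is a tibble with one row per analysis variable, driving every
#' pre-processing decision. Columns:
#' \describe{
#'   \item{name}{variable identifier}
#'   \item{form}{the clinical form the variable belongs to (e.g. MHX,
#'     VarItemsII); completeness is also reported per form}
#'   \item{dtype}{one of `continuous`, `ordinal`, `nominal`, `boolean`}
#'   \item{recording_rule}{one of `always`, `baseline_only`, `change_only`,
#'     `conditional`}
#'   \item{trigger_variable}{for `conditional` variables, the boolean variable
#'     whose value 0 means "not applicable" (and implies the value 0)}
#'   \item{valid_min,valid_max}{numeric validity range (continuous/ordinal)}
#'   \item{categories}{comma-separated category labels (nominal)}
#'   \item{composite_of}{comma-separated component names for composite scores}
#'   \item{onset_indicator_for}{for symptom-indicator variables, the name of
#'     the onset-age variable they gate}
#'   \item{level}{`profile` (one value per participant) or `visit`}
#' }
#'
#' @param name,form,dtype,recording_rule,trigger_variable,valid_min,valid_max,categories,composite_of,onset_indicator_for,level
#'   Per-variable fields, recycled to common length.
#' @return A tibble of class `hd_catalog`.
#' @export
catalog_spec <- function(name, form, dtype,
                         recording_rule = "always",
                         trigger_variable = NA_character_,
                         valid_min = NA_real_, valid_max = NA_real_,
                         categories = NA_character_,
                         composite_of = NA_character_,
                         onset_indicator_for = NA_character_,
                         level = "visit") {
  out <- tibble(
    name = name, form = form, dtype = dtype,
    recording_rule = recording_rule,
    trigger_variable = trigger_variable,
    valid_min = valid_min, valid_max = valid_max,
    categories = categories,
    composite_of = composite_of,
    onset_indicator_for = onset_indicator_for,
    level = level
  )
  validate_catalog(out)
}

validate_catalog <- function(cat, check_refs = FALSE) {
  stopifnot(all(cat$dtype %in% c("continuous", "ordinal", "nominal", "boolean")))
  stopifnot(all(cat$recording_rule %in%
                  c("always", "baseline_only", "change_only", "conditional")))
  cond <- cat$recording_rule == "conditional"
  if (any(cond & is.na(cat$trigger_variable)))
    abort("conditional variables must declare a trigger_variable")
  if (any(cat$dtype == "nominal" & is.na(cat$categories)))
    abort("nominal variables must declare a finite category set")
  if (check_refs) {
    comps <- unlist(strsplit(cat$composite_of[!is.na(cat$composite_of)], ","))
    if (length(comps) && !all(trimws(comps) %in% cat$name))
      abort("composite_of refers to variables missing from the catalog")
  }
  class(cat) <- c("hd_catalog", class(cat))
  cat
}

#' Split a comma-separated catalog field
#' @noRd
cat_split <- function(x) if (is.na(x)) character(0) else trimws(strsplit(x, ",")[[1]])

#' Category labels of a nominal catalog variable
#' @noRd
cat_levels <- function(catalog, var) {
  cat_split(catalog$categories[catalog$name == var])
}

#' Default synthetic-cohort variable catalog
#'
#' About thirty variables covering every recording-rule category used by the
#' pre-processing rules: an always-recorded clinical core, a baseline-only
#' medical-history (MHX-like) block, a change-only (Var-Items-II-like) block,
#' smoking variables conditional on an ever-smoked trigger, symptom
#' onset-age/indicator pairs, a composite motor score that is the sum of its
#' items, and a high-missingness (WPAI-like) block that exceeds the variable
#' exclusion threshold.
#'
#' @return An `hd_catalog` tibble.
#' @export
default_catalog <- function() {
  bind_rows(
    # profile (one value per participant)
    catalog_spec("caghigh", "Profile", "continuous", valid_min = 36, valid_max = 59, level = "profile"),
    catalog_spec("caglow",  "Profile", "continuous", valid_min = 10, valid_max = 35, level = "profile"),
    catalog_spec("sex",     "Profile", "nominal", categories = "f,m", level = "profile"),
    catalog_spec("fhx",     "Profile", "boolean", valid_min = 0, valid_max = 1, level = "profile",
                 onset_indicator_for = "parentagesx"),
    catalog_spec("momhd",   "Profile", "boolean", valid_min = 0, valid_max = 1, level = "profile",
                 onset_indicator_for = "momagesx"),
    catalog_spec("momagesx", "Profile", "continuous", valid_min = 15, valid_max = 95, level = "profile"),
    catalog_spec("dadhd",   "Profile", "boolean", valid_min = 0, valid_max = 1, level = "profile",
                 onset_indicator_for = "dadagesx"),
    catalog_spec("dadagesx", "Profile", "continuous", valid_min = 15, valid_max = 95, level = "profile"),
    catalog_spec("hddiagn", "Profile", "continuous", valid_min = 21, valid_max = 95, level = "profile"),
    catalog_spec("sxrater", "Profile", "continuous", valid_min = 21, valid_max = 95, level = "profile"),
    catalog_spec("sxestcnf", "Profile", "nominal", categories = "low,unknown,high", level = "profile"),
    catalog_spec("ccmtr",   "Profile", "boolean", valid_min = 0, valid_max = 1, level = "profile",
                 onset_indicator_for = "ccmtrage"),
    catalog_spec("ccmtrage", "Profile", "continuous", valid_min = 5, valid_max = 95, level = "profile"),
    catalog_spec("ccdep",   "Profile", "boolean", valid_min = 0, valid_max = 1, level = "profile",
                 onset_indicator_for = "ccdepage"),
    catalog_spec("ccdepage", "Profile", "continuous", valid_min = 5, valid_max = 95, level = "profile"),
    catalog_spec("tob",     "Profile", "boolean", valid_min = 0, valid_max = 1, level = "profile"),
    catalog_spec("tobcpd",  "Profile", "continuous", "conditional", trigger_variable = "tob",
                 valid_min = 0, valid_max = 80, level = "profile"),
    catalog_spec("tobyos",  "Profile", "continuous", "conditional", trigger_variable = "tob",
                 valid_min = 0, valid_max = 70, level = "profile"),
    # per-visit clinical core
    catalog_spec("age",  "Visit", "continuous", valid_min = 21, valid_max = 105),
    catalog_spec("ms1",  "Motor", "ordinal", valid_min = 0, valid_max = 4),
    catalog_spec("ms2",  "Motor", "ordinal", valid_min = 0, valid_max = 4),
    catalog_spec("ms3",  "Motor", "ordinal", valid_min = 0, valid_max = 4),
    catalog_spec("ms4",  "Motor", "ordinal", valid_min = 0, valid_max = 4),
    catalog_spec("motscore", "Motor", "ordinal", valid_min = 0, valid_max = 16,
                 composite_of = "ms1,ms2,ms3,ms4"),
    catalog_spec("tfc",  "Function", "ordinal", valid_min = 0, valid_max = 13),
    catalog_spec("sdmt", "Cognitive", "continuous", valid_min = 0, valid_max = 110),
    catalog_spec("verfct", "Cognitive", "continuous", valid_min = 0, valid_max = 60),
    # change-only (Var-Items-II-like) block
    catalog_spec("employ",  "VarItemsII", "nominal", "change_only",
                 categories = "employed,unemployed,retired"),
    catalog_spec("caresit", "VarItemsII", "ordinal", "change_only",
                 valid_min = 0, valid_max = 2),
    # baseline-only (MHX-like) block
    catalog_spec("mhx1", "MHX", "boolean", "baseline_only", valid_min = 0, valid_max = 1),
    catalog_spec("mhx2", "MHX", "boolean", "baseline_only", valid_min = 0, valid_max = 1),
    catalog_spec("mhx3", "MHX", "ordinal", "baseline_only", valid_min = 0, valid_max = 3),
    # high-missingness block (exceeds the exclusion threshold)
    catalog_spec("wpai1", "WPAI", "continuous", valid_min = 0, valid_max = 10),
    catalog_spec("wpai2", "WPAI", "continuous", valid_min = 0, valid_max = 10),
    # driving label
    catalog_spec("driving", "Driving", "boolean", valid_min = 0, valid_max = 1)
  ) %>% validate_catalog(check_refs = TRUE)
}
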