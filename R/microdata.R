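#' Microdata schemas
#'
#' Survey microdata carry one row per woman with covariates, the three binary
#' outcomes (any contraceptive use, modern use, unmet need) and a positive
#' sampling weight. Census microdata carry the same covariates but no
#' outcomes and no weights.
#' @name microdata-schema
#' @keywords internal
NULL

fp_covariate_cols <- function() {
  c("state", "ethnic_group", "urbanicity", "age_group", "is_mother",
    "education", "not_attending_school", "working", "poor_walls",
    "house_or_apartment", "electricity", "internet", "partner_same_ethnic")
}

fp_outcome_cols <- function() c("y_use_any", "y_use_modern", "y_unmet")

#' Validate microdata against the codebook and source contract
#'
#' Checks the schema and row-level invariants for survey or census microdata:
#' known categories for every enum field, 0/1 coding for binary fields,
#' strictly positive weights in the survey, absence of outcome and weight
#' columns in the census, modern use implying any use, and unmet need only
#' among non-users. Errors name the offending row and field.
#'
#' @param data A data frame of microdata.
#' @param source `"survey"` or `"census"`.
#' @param codebook An [fp_codebook()].
#' @param allow_unmet_overlap If `TRUE`, the mutual exclusivity of current
#'   use and unmet need is not enforced (the two states are exclusive under
#'   standard DHS semantics, which is the default).
#' @return The validated data, invisibly as a tibble with enum columns as
#'   factors in codebook level order.
#' @export
validate_microdata <- function(data, source = c("survey", "census"),
                               codebook = fp_codebook(),
                               allow_unmet_overlap = FALSE) {
  source <- match.arg(source)
  data <- as_tibble(data)

  required <- c("id", fp_covariate_cols())
  if (source == "survey") required <- c(required, "weight", fp_outcome_cols())
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s) for ", source, " microdata: ",
                 paste(missing_cols, collapse = ", ")),
          class = "ethnosae_schema_error")
  }
  if (source == "census") {
    forbidden <- intersect(c("weight", fp_outcome_cols()), names(data))
    if (length(forbidden) > 0) {
      abort(paste0("census microdata must not contain outcome or weight ",
                   "column(s): ", paste(forbidden, collapse = ", ")),
            class = "ethnosae_schema_error")
    }
  }

  check_enum <- function(col, levels) {
    vals <- as.character(data[[col]])
    bad <- which(!vals %in% levels)
    if (length(bad) > 0) {
      abort(sprintf("unknown category '%s' in field '%s' (first at row %d)",
                    vals[bad[1]], col, bad[1]),
            class = "ethnosae_validation_error")
    }
    factor(vals, levels = levels)
  }
  data$ethnic_group <- check_enum("ethnic_group", codebook$ethnic_levels)
  data$urbanicity <- check_enum("urbanicity", codebook$urbanicity_levels)
  data$age_group <- check_enum("age_group", codebook$age_levels)
  data$education <- check_enum("education", codebook$education_levels)

  if (any(is.na(data$state)) || any(data$state != as.integer(data$state)) ||
      any(data$state < 1)) {
    abort("field 'state' must hold positive integer codes",
          class = "ethnosae_validation_error")
  }
  data$state <- as.integer(data$state)

  binaries <- codebook$binary_vars
  if (source == "survey") binaries <- c(binaries, fp_outcome_cols())
  if ("in_union" %in% names(data)) binaries <- c(binaries, "in_union")
  for (col in binaries) {
    vals <- data[[col]]
    bad <- which(is.na(vals) | !vals %in% c(0, 1))
    if (length(bad) > 0) {
      abort(sprintf("field '%s' must be 0/1 (violation at row %d)",
                    col, bad[1]),
            class = "ethnosae_validation_error")
    }
    data[[col]] <- as.integer(vals)
  }

  if (source == "survey") {
    bad <- which(is.na(data$weight) | data$weight <= 0)
    if (length(bad) > 0) {
      abort(sprintf("sampling weight must be > 0 (violation at row %d)",
                    bad[1]),
            class = "ethnosae_validation_error")
    }
    bad <- which(data$y_use_modern > data$y_use_any)
    if (length(bad) > 0) {
      abort(sprintf(
        "modern use implies any use: y_use_modern > y_use_any at row %d",
        bad[1]), class = "ethnosae_validation_error")
    }
    if (!allow_unmet_overlap) {
      bad <- which(data$y_unmet == 1 & data$y_use_any == 1)
      if (length(bad) > 0) {
        abort(sprintf(
          "unmet need and current use are mutually exclusive (row %d); set allow_unmet_overlap = TRUE to relax",
          bad[1]), class = "ethnosae_validation_error")
      }
    }
  }
  invisible(data)
}

#' Read survey or census microdata from CSV
#'
#' Reads a flat CSV with the declared schema, validates every row against the
#' codebook (unknown categories are rejected with the row and field named),
#' and returns a typed tibble. Missing values are rejected by default; with
#' `na_action = "drop"` incomplete rows are removed listwise and the count is
#' reported.
#'
#' @inheritParams validate_microdata
#' @param path Path to a CSV file.
#' @param na_action `"error"` (default) or `"drop"` (listwise deletion with a
#'   logged count).
#' @return A validated tibble, one row per woman.
#' @export
read_microdata <- function(path, source = c("survey", "census"),
                           codebook = fp_codebook(),
                           na_action = c("error", "drop"),
                           allow_unmet_overlap = FALSE) {
  source <- match.arg(source)
  na_action <- match.arg(na_action)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  incomplete <- !stats::complete.cases(data)
  if (any(incomplete)) {
    if (na_action == "error") {
      abort(sprintf("missing values at row %d; use na_action = 'drop' for listwise deletion",
                    which(incomplete)[1]),
            class = "ethnosae_validation_error")
    }
    inform(sprintf("dropped %d incomplete row(s)", sum(incomplete)))
    data <- data[!incomplete, , drop = FALSE]
  }
  validate_microdata(data, source, codebook,
                     allow_unmet_overlap = allow_unmet_overlap)
}

#' Write microdata to CSV
#'
#' Inverse of [read_microdata()]: categorical fields round-trip exactly and
#' weights to full double precision.
#'
#' @param data A validated microdata tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(data, path) {
  out <- dplyr::mutate(data, dplyr::across(where(is.factor), as.character))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Restrict microdata to eligible women
#'
#' The estimation universe is married or in-union women aged 13 to 49. The
#' in-union status is taken from the `in_union` column of the input file (or
#' from `in_union_flag` if supplied); age eligibility means an age band within
#' the 13-49 codebook bands.
#'
#' @param data A microdata tibble with an `age_group` column.
#' @param in_union_flag Optional 0/1 vector overriding the `in_union` column.
#' @param codebook An [fp_codebook()].
#' @return The eligible subset, as a tibble.
#' @export
filter_eligible <- function(data, in_union_flag = NULL,
                            codebook = fp_codebook()) {
  if (is.null(in_union_flag)) {
    if (!"in_union" %in% names(data)) {
      abort("no 'in_union' column and no in_union_flag supplied",
            class = "ethnosae_schema_error")
    }
    in_union_flag <- data$in_union
  }
  if (length(in_union_flag) != nrow(data)) {
    abort("in_union_flag must have one entry per row")
  }
  keep <- in_union_flag == 1 &
    as.character(data$age_group) %in% codebook$age_levels
  as_tibble(data[keep, , drop = FALSE])
}

#' Strip outcome and weight columns to obtain a census view
#'
#' Converts a population table that carries known outcomes (e.g. a synthetic
#' population with simulation truth) into valid census microdata by dropping
#' outcome, weight, and in-union columns.
#'
#' @param data A microdata tibble.
#' @return A census-schema tibble.
#' @export
as_census <- function(data) {
  drop <- intersect(c("weight", fp_outcome_cols()), names(data))
  as_tibble(data[, setdiff(names(data), drop), drop = FALSE])
}
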