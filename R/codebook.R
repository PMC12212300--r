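#' Shared covariate codebook
#'
#' The codebook is the single source of truth for the covariates entering the
#' unit-level logistic models, their categories, and their reference levels.
#' Both the survey and the census are validated against it, so the design
#' matrices built from either source are guaranteed to be conformable.
#'
#' The default codebook encodes the standard covariate set for
#' contraceptive-use models on DHS-type microdata: five-year age bands with
#' 45-49 as reference, motherhood, education level (reference: no education),
#' school attendance, employment, dwelling quality (wall material, dwelling
#' type, electricity, internet), partner of the same ethnic group, an
#' ethnic-minority indicator (Indigenous or Afro-descendant versus
#' non-ethnic), and the ethnic-minority x same-ethnic-partner interaction.
#'
#' @return An object of class `fp_codebook`: a list with the category levels,
#'   reference levels, and the fixed design-matrix column order (`terms`).
#' @examples
#' cb <- fp_codebook()
#' cb$terms
#' @export
fp_codebook <- function() {
  age_levels <- c("13-14", "15-19", "20-24", "25-29", "30-34",
                  "35-39", "40-44", "45-49")
  edu_levels <- c("none", "primary", "secondary", "higher")
  eth_levels <- c("indigenous", "afro", "nonethnic")
  binary_vars <- c("is_mother", "not_attending_school", "working",
                   "poor_walls", "house_or_apartment", "electricity",
                   "internet", "partner_same_ethnic")
  terms <- c(
    "(Intercept)",
    paste0("age", sub("-", "_", age_levels[-length(age_levels)])),
    "is_mother",
    "edu_primary", "edu_secondary", "edu_higher",
    "not_attending_school", "working", "poor_walls",
    "house_or_apartment", "electricity", "internet",
    "partner_same_ethnic", "ethnic_minority", "ethnic_minority_x_partner"
  )
  structure(
    list(
      age_levels = age_levels, age_ref = "45-49",
      education_levels = edu_levels, education_ref = "none",
      ethnic_levels = eth_levels, ethnic_ref = "nonethnic",
      urbanicity_levels = c("rural", "urban"),
      binary_vars = binary_vars,
      terms = terms
    ),
    class = "fp_codebook"
  )
}

#' @export
print.fp_codebook <- function(x, ...) {
  cat("<fp_codebook> ", length(x$terms), " design columns (incl. intercept)\n",
      sep = "")
  cat("  age:", paste(x$age_levels, collapse = " "),
      "(ref", x$age_ref, ")\n")
  cat("  education:", paste(x$education_levels, collapse = " "),
      "(ref", x$education_ref, ")\n")
  cat("  ethnic:", paste(x$ethnic_levels, collapse = " "),
      "(ref", x$ethnic_ref, ")\n")
  cat("  binary:", paste(x$binary_vars, collapse = " "), "\n")
  invisible(x)
}

#' Build the fixed-effects design matrix
#'
#' Expands validated microdata into the dummy design matrix used by all three
#' indicator models: an intercept, seven age-band dummies (45-49 reference),
#' motherhood, three education dummies (no-education reference), school
#' non-attendance, employment, poor wall material, house-or-apartment
#' dwelling, electricity, internet, same-ethnic partner, an ethnic-minority
#' indicator (Indigenous or Afro-descendant), and the ethnic-minority x
#' same-ethnic-partner interaction. Column order is fixed by the codebook. A
#' woman at every reference category has an all-zero covariate row.
#'
#' @param data A data frame of validated microdata (see [read_microdata()]).
#' @param codebook An `fp_codebook`; defaults to [fp_codebook()].
#' @return A numeric matrix with `nrow(data)` rows and `length(codebook$terms)`
#'   columns, in codebook order.
#' @examples
#' women <- simulate_fp_data(fp_truth(n_states = 2, rows_per_state = 50),
#'                           seed = 1)$census
#' X <- design_matrix(women)
#' colnames(X)
#' @export
design_matrix <- function(data, codebook = fp_codebook()) {
  stopifnot(inherits(codebook, "fp_codebook"))
  n <- nrow(data)
  X <- matrix(0, nrow = n, ncol = length(codebook$terms),
              dimnames = list(NULL, codebook$terms))
  X[, "(Intercept)"] <- 1
  age <- as.character(data$age_group)
  for (lev in setdiff(codebook$age_levels, codebook$age_ref)) {
    X[, paste0("age", sub("-", "_", lev))] <- as.numeric(age == lev)
  }
  edu <- as.character(data$education)
  for (lev in setdiff(codebook$education_levels, codebook$education_ref)) {
    X[, paste0("edu_", lev)] <- as.numeric(edu == lev)
  }
  for (v in setdiff(codebook$binary_vars, "partner_same_ethnic")) {
    X[, v] <- as.numeric(data[[v]])
  }
  X[, "partner_same_ethnic"] <- as.numeric(data$partner_same_ethnic)
  minority <- as.numeric(as.character(data$ethnic_group) != codebook$ethnic_ref)
  X[, "ethnic_minority"] <- minority
  X[, "ethnic_minority_x_partner"] <- minority * as.numeric(data$partner_same_ethnic)
  X
}

#' Domain key for ethnic-group x state cells
#'
#' Domains are the target estimation cells: one per combination of ethnic
#' group and state. The key is the string `"<ethnic_group>|<state>"`, used to
#' index random-effect predictions.
#'
#' @param data A data frame with `ethnic_group` and `state` columns.
#' @return A character vector of domain keys.
#' @export
domain_key <- function(data) {
  paste(as.character(data$ethnic_group), data$state, sep = "|")
}
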