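#' Reference coefficient estimates for the three indicator models
#'
#' Fixed-effects coefficients (logit scale) reported for unit-level
#' mixed-effects logistic models of contraceptive use (any method), modern
#' contraceptive use, and unmet need for family planning, fitted to married
#' or in-union women aged 13-49 in the 2015 Colombian DHS with an
#' ethnic-group-by-state random intercept. Reference categories: women aged
#' 45-49, not a mother, no education, attending school, not working, good
#' wall material, dwelling other than house or apartment, no electricity, no
#' internet, partner from a different ethnic group, non-ethnic.
#'
#' These estimates serve two purposes in the package: as the default truth of
#' the synthetic-data generator, and as the worked input for odds-ratio
#' arithmetic ([odds_ratios()], [combined_or()]).
#'
#' @return A tibble with columns `term`, `use_any`, `use_modern`, `unmet`
#'   (one coefficient column per indicator), rows in codebook order.
#' @examples
#' b <- reference_coefficients()
#' exp(b$unmet[b$term == "age13_14"])  # odds ratio for the youngest band
#' @export
reference_coefficients <- function() {
  tibble::tribble(
    ~term,                        ~use_any, ~use_modern, ~unmet,
    "(Intercept)",                  -3.538,      -3.711, -0.384,
    "age13_14",                      0.309,       0.359,  1.955,
    "age15_19",                      0.815,       0.737,  0.918,
    "age20_24",                      0.927,       0.932,  0.508,
    "age25_29",                      0.837,       0.834,  0.005,
    "age30_34",                      1.023,       0.888, -0.335,
    "age35_39",                      0.790,       0.685, -0.255,
    "age40_44",                      0.731,       0.605, -0.222,
    "is_mother",                     0.688,       0.577, -0.156,
    "edu_primary",                   0.981,       0.993, -0.425,
    "edu_secondary",                 1.396,       1.335, -0.798,
    "edu_higher",                    1.347,       1.184, -0.858,
    "not_attending_school",         -0.256,      -0.180,  0.465,
    "working",                       0.016,      -0.004, -0.098,
    "poor_walls",                   -0.197,      -0.201,  0.025,
    "house_or_apartment",            1.148,       1.379, -0.532,
    "electricity",                   0.289,       0.280, -0.256,
    "internet",                      0.208,       0.191, -0.066,
    "partner_same_ethnic",           0.213,       0.172, -0.502,
    "ethnic_minority",              -0.008,      -0.055, -0.149,
    "ethnic_minority_x_partner",    -0.304,      -0.218,  0.403
  )
}

#' Reference random-intercept standard deviations
#'
#' Default domain random-intercept standard deviations for the three
#' indicator models, chosen so that the latent-scale intraclass correlation
#' sigma^2 / (sigma^2 + pi^2/3) equals the values reported for the 2015
#' Colombian DHS fits: about 0.076 (any use), 0.07 (modern use) and 0.058
#' (unmet need).
#'
#' @return A named numeric vector over indicators.
#' @export
reference_sigma_v <- function() {
  icc <- c(use_any = 0.076, use_modern = 0.07, unmet = 0.058)
  sqrt(icc / (1 - icc) * pi^2 / 3)
}

fp_indicators <- function() c("use_any", "use_modern", "unmet")

fp_all_indicators <- function() {
  c("use_any", "use_modern", "unmet", "need_satisfied")
}
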