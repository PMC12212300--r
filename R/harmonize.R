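#' Harmonization maps between survey and census codings
#'
#' Survey and census instruments code the same construct with different
#' category lists. A harmonization map declares, per variable and per source,
#' a total mapping from source categories onto a shared harmonized codebook,
#' so the derived variable is identical in meaning across the two sources.
#'
#' @param variable Name of the harmonized variable the map produces.
#' @param source `"survey"` or `"census"`.
#' @param mapping Named list or named vector: source category -> harmonized
#'   category.
#' @param default Policy for categories absent from the mapping: `"error"`
#'   (reject, naming the category) or `"missing"` (emit `NA`).
#' @return An object of class `fp_harmonization_map`.
#' @export
harmonization_map <- function(variable, source = c("survey", "census"),
                              mapping, default = c("error", "missing")) {
  source <- match.arg(source)
  default <- match.arg(default)
  mapping <- unlist(mapping)
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    abort("every mapping entry must be named by its source category")
  }
  structure(
    list(variable = variable, source = source,
         mapping = mapping, default = default),
    class = "fp_harmonization_map"
  )
}

#' @export
print.fp_harmonization_map <- function(x, ...) {
  cat("<fp_harmonization_map>", x$variable, "/", x$source,
      sprintf("(%d categories, default = %s)\n",
              length(x$mapping), x$default))
  invisible(x)
}

#' Read harmonization maps from YAML
#'
#' One YAML document per variable per source, with fields `variable`,
#' `source`, `default`, and `mapping`.
#'
#' @param path Path to a YAML file (multi-document).
#' @return A list of [harmonization_map()] objects.
#' @export
read_harmonization_maps <- function(path) {
  docs <- yaml::read_yaml(path)
  # a single map reads as a named list rather than a list of maps
  if (!is.null(docs$variable)) docs <- list(docs)
  purrr::map(docs, function(d) {
    harmonization_map(d$variable, d$source, d$mapping,
                      d$default %||% "error")
  })
}

#' Apply harmonization maps to raw microdata
#'
#' Recodes each mapped variable of `data` from its source categories onto the
#' shared harmonized codebook. Values already equal to a harmonized category
#' pass through unchanged, so harmonization is idempotent. Under
#' `default = "error"` an unmapped category aborts, naming the category;
#' under `default = "missing"` it becomes `NA`.
#'
#' @param data A data frame of raw microdata.
#' @param maps A list of [harmonization_map()] objects (or a single map).
#' @param source `"survey"` or `"census"`: which source's maps to apply.
#' @return `data` with the mapped variables recoded, as a tibble.
#' @examples
#' m <- wall_material_maps()
#' raw <- tibble::tibble(poor_walls = c("cane/palm/trunks", "finished walls"))
#' harmonize(raw, m, source = "survey")$poor_walls
#' @export
harmonize <- function(data, maps, source = c("survey", "census")) {
  source <- match.arg(source)
  if (inherits(maps, "fp_harmonization_map")) maps <- list(maps)
  data <- as_tibble(data)
  for (m in maps) {
    if (m$source != source) next
    if (!m$variable %in% names(data)) {
      abort(sprintf("mapped variable '%s' not present in data", m$variable),
            class = "ethnosae_schema_error")
    }
    vals <- as.character(data[[m$variable]])
    harmonized_set <- unique(as.character(m$mapping))
    mapped <- unname(m$mapping[vals])
    passthrough <- is.na(mapped) & vals %in% harmonized_set
    mapped[passthrough] <- vals[passthrough]
    unmapped <- is.na(mapped) & !is.na(vals)
    if (any(unmapped)) {
      if (m$default == "error") {
        abort(sprintf("unmapped category '%s' for variable '%s' (%s)",
                      vals[which(unmapped)[1]], m$variable, m$source),
              class = "ethnosae_validation_error")
      }
      inform(sprintf("harmonize: %d value(s) of '%s' set to missing",
                     sum(unmapped), m$variable))
    }
    # keep numeric coding when the harmonized codebook is numeric (e.g. 0/1)
    if (!anyNA(suppressWarnings(as.numeric(harmonized_set)))) {
      mapped <- as.numeric(mapped)
    }
    data[[m$variable]] <- mapped
  }
  data
}

#' Built-in wall-material harmonization
#'
#' The canonical example of survey-to-census homologation: DHS and census
#' wall-material categories are collapsed into a shared binary variable,
#' 1 for inadequate materials (no walls, natural walls, cane/palm/trunks,
#' dirt, cardboard, reused wood, uncovered adobe, bamboo with mud, plywood on
#' the survey side; guadua, rough wood/board/plank, cane/mat/other vegetation,
#' no walls, waste materials on the census side) and 0 for good materials
#' (finished walls such as cement, stone, brick, blocks, covered adobe on the
#' survey side; block, brick, stone, polished wood, poured concrete, rammed
#' earth, bahareque, covered adobe, prefabricated on the census side).
#'
#' @return A list of two [harmonization_map()] objects (survey and census)
#'   for the `poor_walls` variable.
#' @export
wall_material_maps <- function() {
  survey_poor <- c("no walls", "natural walls", "cane/palm/trunks", "dirt",
                   "cardboard", "reused wood", "uncovered adobe",
                   "bamboo with mud", "plywood")
  survey_good <- c("finished walls", "cement", "stone with lime/cement",
                   "stone with mud", "bricks", "cement blocks",
                   "covered adobe")
  census_poor <- c("guadua", "rough wood", "board", "plank", "cane", "mat",
                   "other vegetation", "no walls", "waste materials")
  census_good <- c("block, brick, stone", "polished wood", "poured concrete",
                   "rammed earth", "bahareque", "covered adobe",
                   "prefabricated material")
  list(
    harmonization_map(
      "poor_walls", "survey",
      setNames(c(rep("1", length(survey_poor)), rep("0", length(survey_good))),
               c(survey_poor, survey_good))),
    harmonization_map(
      "poor_walls", "census",
      setNames(c(rep("1", length(census_poor)), rep("0", length(census_good))),
               c(census_poor, census_good)))
  )
}
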