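#' Nutrient codes used by the NRD9.3 index
#'
#' The nutrient-density score tracks twelve nutrients: nine *qualifying*
#' (encouraging) nutrients whose intake is rewarded, and three *limiting*
#' nutrients whose intake is penalized.
#'
#' @return Character vector of nutrient codes, in canonical order
#'   (qualifying first, then limiting).
#' @export
#' @examples
#' nutrient_codes()
nutrient_codes <- function() c(qualifying_nutrients(), limiting_nutrients())

#' @rdname nutrient_codes
#' @export
qualifying_nutrients <- function() {
  c("protein", "fiber", "Ca", "Fe", "Mg", "K", "vitA", "vitC", "vitE")
}

#' @rdname nutrient_codes
#' @export
limiting_nutrients <- function() c("satfat", "sugar_added", "Na")

# daily amounts: g for macronutrients, mg/ug for micronutrients
nutrient_units <- function() {
  c(protein = "g", fiber = "g", Ca = "mg", Fe = "mg", Mg = "mg", K = "mg",
    vitA = "ug", vitC = "mg", vitE = "mg",
    satfat = "g", sugar_added = "g", Na = "mg")
}

#' Construct a nutrient reference (recommended and maximum daily values)
#'
#' Holds the daily recommended values (RV) for the nine qualifying
#' nutrients, the daily maximum values (MV) for the three limiting
#' nutrients, and the daily energy target used for isocaloric comparison.
#'
#' @param rv Named numeric vector of recommended daily values, one entry per
#'   qualifying nutrient, all positive. Units follow the nutrient codes
#'   (g for protein/fiber, mg for Ca/Fe/Mg/K/vitC/vitE, ug for vitA).
#' @param mv Named numeric vector of maximum daily values for the limiting
#'   nutrients (g for satfat/sugar_added, mg for Na), all positive.
#' @param energy_target Daily energy target in kcal (default 2228, the
#'   weighted average recommended intake for an adult in the Spanish
#'   context the method was developed for).
#' @return An object of class `nutrient_reference`.
#' @seealso [default_nutrient_reference()], [read_nutrient_reference()]
#' @export
nutrient_reference <- function(rv, mv, energy_target = 2228) {
  rv <- unlist(rv)[qualifying_nutrients()]
  mv <- unlist(mv)[limiting_nutrients()]
  if (anyNA(rv)) {
    stop("`rv` must name all qualifying nutrients: ",
         paste(setdiff(qualifying_nutrients(), names(rv)), collapse = ", "))
  }
  if (anyNA(mv)) {
    stop("`mv` must name all limiting nutrients: ",
         paste(setdiff(limiting_nutrients(), names(mv)), collapse = ", "))
  }
  if (any(rv <= 0)) stop("all recommended values (RV) must be > 0")
  if (any(mv <= 0)) stop("all maximum values (MV) must be > 0")
  if (!is.numeric(energy_target) || length(energy_target) != 1 ||
      energy_target <= 0) {
    stop("`energy_target` must be a single positive number")
  }
  structure(list(rv = rv, mv = mv, energy_target = as.numeric(energy_target)),
            class = "nutrient_reference")
}

#' Default nutrient reference shipped with the package
#'
#' Reads the default reference configuration installed with the package.
#' The provenance of these numbers is documented in the config file itself
#' (`inst/extdata/nutrient_reference.yaml`): EU/EFSA-style adult reference
#' values for the qualifying nutrients, maxima for saturated fat and added
#' sugar at 10% of the energy target, and the EFSA safe sodium intake.
#' They are sensible defaults, not universal constants; population-specific
#' work should supply its own file via [read_nutrient_reference()].
#'
#' @return A `nutrient_reference` object.
#' @export
default_nutrient_reference <- function() {
  read_nutrient_reference(
    system.file("extdata", "nutrient_reference.yaml", package = "dietopt",
                mustWork = TRUE))
}

#' Read a nutrient reference from a YAML or JSON config file
#'
#' The file must contain keys `rv:` (map of qualifying nutrient to daily
#' recommended value), `mv:` (map of limiting nutrient to daily maximum)
#' and `energy_target_kcal:`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `nutrient_reference` object.
#' @export
read_nutrient_reference <- function(path) {
  if (!file.exists(path)) stop("nutrient reference file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("rv", "mv", "energy_target_kcal")) {
    if (is.null(cfg[[key]])) stop("nutrient reference config misses key: ", key)
  }
  nutrient_reference(rv = cfg$rv, mv = cfg$mv,
                     energy_target = cfg$energy_target_kcal)
}

#' @export
print.nutrient_reference <- function(x, ...) {
  cat("Nutrient reference (daily):\n")
  cat("  energy target:", x$energy_target, "kcal\n")
  cat("  RV:", paste(names(x$rv), x$rv, sep = "=", collapse = ", "), "\n")
  cat("  MV:", paste(names(x$mv), x$mv, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
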