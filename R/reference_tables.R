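#' Published benchmark indices for six Spanish dietary patterns
#'
#' Aggregate sustainability indices reported for six pre-defined Spanish
#' dietary patterns: average current consumption (CC), the national dietary
#' guidelines (NDG), Mediterranean (MED), ovo-lacto-vegetarian (OLV), vegan
#' (VEG) and planetary health (PLH) patterns, all isocaloric at
#' 2228 kcal/day. Columns: NRD9.3 score, total cost (EUR/day), GHG
#' emissions (kg CO2eq/day) and the corresponding normalized indices
#' X_NUTR, X_ENV, X_EC (environment and cost normalized over this diet
#' set). These published aggregates serve as reference inputs for the
#' distance and normalization calculations; the underlying food-level data
#' are not redistributable and are emulated by
#' [generate_synthetic_database()].
#'
#' @return Data frame with one row per diet.
#' @export
#' @examples
#' idx <- predefined_diet_indices()
#' normalized_distance(unlist(idx[idx$diet == "VEG", c("x_nutr", "x_env", "x_ec")]))
predefined_diet_indices <- function() {
  utils::read.csv(system.file("extdata", "predefined_diet_indices.csv",
                              package = "dietopt", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published comparison factors for the same diet benchmark
#'
#' Per-diet price, NRD9.3, GHG emissions, residual income score (RIS),
#' nutritional score (NS, reference: the planetary health pattern) and the
#' corrected emissions (c-GHG) as published, for the six pre-defined
#' patterns and their optimized counterparts (all isocaloric, so the energy
#' score alpha is 1).
#'
#' @return Data frame with one row per diet scenario.
#' @export
diet_comparison_factors <- function() {
  utils::read.csv(system.file("extdata", "diet_comparison_factors.csv",
                              package = "dietopt", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
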