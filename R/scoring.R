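#' Context for corrected-emissions comparison of diets
#'
#' Cross-diet comparison of greenhouse-gas emissions uses a functional unit
#' that accounts for affordability, energy and nutritional quality. The
#' context fixes the daily consumption income (money left after financial
#' obligations, EUR/day), the reference diet's nutrient-density score and
#' its daily energy.
#'
#' The default income of 29.3 EUR/day is back-derived: it is (the midpoint
#' of) the interval of incomes that reproduces, at two decimals, the
#' residual-income scores printed in the published evaluation of the six
#' Spanish dietary patterns shipped with the package (see
#' [diet_comparison_factors()]). It is a derived calibration constant, not
#' an official statistic, and should be overridden for other settings.
#'
#' @param consumption_income Daily consumption income, EUR/day.
#' @param reference_nrd93 NRD9.3 of the reference diet (the planetary
#'   health pattern, 680, in the shipped benchmark).
#' @param reference_energy Daily energy of the reference diet, kcal/day.
#' @return An object of class `comparison_context`.
#' @export
comparison_context <- function(consumption_income = 29.3,
                               reference_nrd93 = 680,
                               reference_energy = 2228) {
  vals <- c(consumption_income, reference_nrd93, reference_energy)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all comparison-context values must be positive")
  }
  structure(list(consumption_income = consumption_income,
                 reference_nrd93 = reference_nrd93,
                 reference_energy = reference_energy),
            class = "comparison_context")
}

#' Residual income score (affordability correction)
#'
#' RIS = 1 - cost / consumption income: the fraction of the consumption
#' income left after paying for the diet. A free diet scores 1; a diet
#' costing the whole income (or more) is unaffordable and raises an error.
#'
#' @param cost Daily diet cost, EUR/day.
#' @param ctx A `comparison_context`.
#' @return RIS in (0, 1].
#' @export
residual_income_score <- function(cost, ctx = comparison_context()) {
  if (any(cost >= ctx$consumption_income)) {
    stop("unaffordable diet: cost (", format(max(cost)),
         ") >= consumption income (", format(ctx$consumption_income), ")")
  }
  1 - cost / ctx$consumption_income
}

#' Energy score (alpha)
#'
#' Ratio of the diet's energy to the reference energy when the diet
#' delivers less energy than the reference, and 1 otherwise; isocaloric
#' diets always score 1, so for the isocaloric comparisons this package
#' targets, alpha is neutral.
#'
#' @param de_diet Daily energy of the diet, kcal/day.
#' @inheritParams residual_income_score
#' @return Alpha in (0, 1].
#' @export
energy_score <- function(de_diet, ctx = comparison_context()) {
  ifelse(de_diet < ctx$reference_energy, de_diet / ctx$reference_energy, 1)
}

#' Nutritional score (NS)
#'
#' Ratio of the diet's NRD9.3 to the reference diet's; may exceed 1 for
#' diets denser in nutrients than the reference.
#'
#' @param nrd93_diet NRD9.3 of the diet.
#' @inheritParams residual_income_score
#' @return NS (dimensionless).
#' @export
nutritional_score <- function(nrd93_diet, ctx = comparison_context()) {
  nrd93_diet / ctx$reference_nrd93
}

#' Corrected greenhouse-gas emissions (c-GHG)
#'
#' c-GHG = GHG / (RIS * alpha * NS): daily emissions expressed per unit of
#' affordable, energy-adequate, nutritious diet, enabling comparison of
#' diets on a common functional unit. Because the correction divides by the
#' three scores, values near zero would explode the metric; scores at or
#' below 1e-6 raise an error instead of returning infinities.
#'
#' @param ghg Daily emissions, kg CO2eq/day.
#' @param ris,alpha,ns The three correction scores.
#' @return c-GHG in corrected kg CO2eq/day.
#' @export
#' @examples
#' corrected_ghg(1.41, ris = 0.92, alpha = 1, ns = 0.93)  # about 1.65
corrected_ghg <- function(ghg, ris, alpha, ns) {
  s <- c(ris, alpha, ns)
  if (any(!is.finite(s)) || any(s <= 1e-6)) {
    stop("undefined correction: RIS, alpha and NS must all exceed 1e-6")
  }
  ghg / (ris * alpha * ns)
}

#' Corrected-emissions comparison table for a set of diets
#'
#' Builds the standard comparison layout (price, NRD9.3, GHG, RIS, NS,
#' c-GHG per diet) from raw per-diet indicators, assuming isocaloric diets
#' (alpha = 1) unless per-diet energies are supplied.
#'
#' @param factors Data frame with columns `diet`, `cost`, `nrd93`, `ghg`
#'   and optionally `energy`.
#' @param ctx A `comparison_context`.
#' @return Data frame with the factors plus `ris`, `alpha`, `ns`, `c_ghg`.
#' @export
corrected_ghg_table <- function(factors, ctx = comparison_context()) {
  factors <- as.data.frame(factors)
  need <- c("diet", "cost", "nrd93", "ghg")
  missing <- setdiff(need, names(factors))
  if (length(missing)) {
    stop("factors table misses column(s): ", paste(missing, collapse = ", "))
  }
  factors$ris <- residual_income_score(factors$cost, ctx)
  factors$alpha <- if (is.null(factors$energy)) 1 else {
    energy_score(factors$energy, ctx)
  }
  factors$ns <- nutritional_score(factors$nrd93, ctx)
  factors$c_ghg <- mapply(corrected_ghg, factors$ghg, factors$ris,
                          factors$alpha, factors$ns)
  factors
}
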