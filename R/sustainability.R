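#' Total greenhouse-gas emissions and cost of a diet
#'
#' Both are linear aggregations over the food basket: the daily quantity of
#' each product (grams, converted to kg) times its unitary footprint
#' (kg CO2eq per kg) or price (EUR per kg).
#'
#' @param diet A `diet` (grams/day per product).
#' @param db A `food_database`.
#' @return `total_ghg()`: kg CO2eq per day; `total_cost()`: EUR per day.
#' @export
total_ghg <- function(diet, db) {
  db <- food_database(db)
  idx <- diet_index(diet, db)
  sum(diet$quantities * 1e-3 * db$ghg_kgco2e_per_kg[idx])
}

#' @rdname total_ghg
#' @export
total_cost <- function(diet, db) {
  db <- food_database(db)
  idx <- diet_index(diet, db)
  sum(diet$quantities * 1e-3 * db$price_eur_per_kg[idx])
}

#' Normalization context for the environment and cost indices
#'
#' The nutrition index is normalized by its theoretical maximum (900), but
#' emissions and cost have no natural maximum, so they are normalized by
#' the largest value observed across a set of whole diets under comparison
#' (normalizing by single products would be meaningless, as no single
#' product is a diet). The context is built once from the baseline diet set
#' and then held fixed, e.g. during optimization.
#'
#' @param diet_scores Data frame (or list coercible to one) with columns
#'   `cost` and `ghg`, one row per diet.
#' @return An object of class `normalization_context` with `ghg_max` and
#'   `tc_max`.
#' @export
build_normalization <- function(diet_scores) {
  diet_scores <- as.data.frame(diet_scores)
  if (!nrow(diet_scores)) stop("need at least one diet to normalize against")
  for (col in c("cost", "ghg")) {
    if (is.null(diet_scores[[col]])) stop("diet_scores misses column: ", col)
  }
  ghg_max <- max(diet_scores$ghg)
  tc_max <- max(diet_scores$cost)
  if (ghg_max <= 0 || tc_max <= 0) {
    stop("cannot normalize: maximal cost and GHG must be positive")
  }
  structure(list(ghg_max = ghg_max, tc_max = tc_max),
            class = "normalization_context")
}

#' Normalized three-dimensional score vector of a diet
#'
#' Maps the raw indicators onto dimensionless indices: X_NUTR = NRD9.3/900,
#' X_ENV = GHG/GHG_max, X_EC = TC/TC_max. Diets outside the normalization
#' set may legitimately exceed 1 on the environment or cost axis.
#'
#' @param nrd93 Nutrient-density score (percentage points).
#' @param cost Daily cost (EUR/day).
#' @param ghg Daily emissions (kg CO2eq/day).
#' @param ctx A `normalization_context`.
#' @return A `score_vector`: list with the raw indicators and `x_nutr`,
#'   `x_env`, `x_ec`.
#' @export
normalize_scores <- function(nrd93, cost, ghg, ctx) {
  stopifnot(inherits(ctx, "normalization_context"))
  structure(list(nrd93 = nrd93, cost = cost, ghg = ghg,
                 x_nutr = nrd93 / 900,
                 x_env = ghg / ctx$ghg_max,
                 x_ec = cost / ctx$tc_max),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf(
    "NRD9.3 %.1f | TC %.2f EUR/day | GHG %.2f kgCO2e/day | X = (%.3f, %.3f, %.3f)\n",
    x$nrd93, x$cost, x$ghg, x$x_nutr, x$x_env, x$x_ec))
  invisible(x)
}

#' Evaluate one or more diets on all three sustainability dimensions
#'
#' @param diets A `diet` or list of diets.
#' @param db A `food_database`.
#' @param ref A `nutrient_reference`.
#' @param ctx Optional `normalization_context`; if `NULL` it is built from
#'   the evaluated diets themselves.
#' @return A data frame with one row per diet: `diet`, `nrd93`, `cost`,
#'   `ghg`, `x_nutr`, `x_env`, `x_ec` (the layout of a standard diet-index
#'   comparison table).
#' @export
score_table <- function(diets, db, ref = default_nutrient_reference(),
                        ctx = NULL) {
  if (inherits(diets, "diet")) diets <- list(diets)
  raw <- do.call(rbind, lapply(diets, function(d) {
    data.frame(diet = d$name,
               nrd93 = compute_nrd93(compute_intake(d, db), ref)$nrd93,
               cost = total_cost(d, db),
               ghg = total_ghg(d, db),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ctx)) ctx <- build_normalization(raw)
  raw$x_nutr <- raw$nrd93 / 900
  raw$x_env <- raw$ghg / ctx$ghg_max
  raw$x_ec <- raw$cost / ctx$tc_max
  rownames(raw) <- NULL
  raw
}
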