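# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sampling ranges for the synthetic food database
#'
#' Reads the versioned category-conditioned range configuration shipped
#' with the package (or a user-supplied file with the same layout).
#'
#' @param path Optional path to a ranges YAML file; defaults to the
#'   installed configuration.
#' @return A list with elements `categories` (per-category ranges) and
#'   `animal_categories`.
#' @export
synthetic_ranges <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_ranges.yaml",
                        package = "dietopt", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$categories) || !length(cfg$categories)) {
    stop("ranges config misses `categories`")
  }
  cfg
}

#' Food categories used by the synthetic generator
#'
#' @param ranges A ranges configuration, see [synthetic_ranges()].
#' @return Character vector of category names.
#' @export
food_categories <- function(ranges = synthetic_ranges()) names(ranges$categories)

#' @rdname food_categories
#' @export
animal_categories <- function(ranges = synthetic_ranges()) {
  unlist(ranges$animal_categories)
}

sample_range <- function(rng, n = 1) {
  rng <- unlist(rng)
  if (length(rng) != 2 || rng[1] > rng[2] || any(rng < 0)) {
    stop("invalid range [", paste(rng, collapse = ", "), "]")
  }
  stats::runif(n, rng[1], rng[2])
}

#' Generate a synthetic food database
#'
#' Draws products with category-conditioned uniform sampling from the range
#' configuration, emulating a retail food basket: animal-source categories
#' carry higher greenhouse-gas intensities than plant categories, legumes
#' and vegetables are fiber- and potassium-rich, dairy is calcium-rich, and
#' oils are energy-dense. The generator is a stand-in for real composition,
#' price and footprint databases, intended for method studies; it makes no
#' claim to represent any particular national basket.
#'
#' @param n_products Number of products (>= 3). Categories are assigned
#'   cyclically in the configured order, so any `n_products >=` the number
#'   of categories covers them all (the default configuration has 14).
#' @param seed Integer seed; generation is deterministic given the seed and
#'   leaves the caller's RNG state untouched.
#' @param ranges Range configuration, see [synthetic_ranges()].
#' @return A `food_database` with `n_products` rows.
#' @export
#' @examples
#' db <- generate_synthetic_database(63, seed = 1)
#' table(db$category)
generate_synthetic_database <- function(n_products, seed,
                                        ranges = synthetic_ranges()) {
  if (!is.numeric(n_products) || length(n_products) != 1 || n_products < 3) {
    stop("`n_products` must be a single integer >= 3")
  }
  n_products <- as.integer(n_products)
  cats <- rep_len(food_categories(ranges), n_products)
  with_seed(seed, {
    rows <- lapply(seq_len(n_products), function(i) {
      cat_cfg <- ranges$categories[[cats[i]]]
      nut <- vapply(nutrient_codes(),
                    function(nc) sample_range(cat_cfg$nutrients[[nc]]),
                    numeric(1))
      c(list(energy_kcal_per_g = sample_range(cat_cfg$energy_kcal_per_g)),
        as.list(nut),
        list(price_eur_per_kg = sample_range(cat_cfg$price_eur_per_kg),
             ghg_kgco2e_per_kg = sample_range(cat_cfg$ghg_kgco2e_per_kg)))
    })
    df <- do.call(rbind, lapply(rows, as.data.frame))
    idx_in_cat <- stats::ave(seq_len(n_products), cats, FUN = seq_along)
    df <- cbind(
      data.frame(id = sprintf("%s_%02d", cats, idx_in_cat),
                 name = sprintf("synthetic %s %02d", gsub("_", " ", cats),
                                idx_in_cat),
                 category = cats, stringsAsFactors = FALSE),
      df)
    food_database(df)
  })
}

# grams/day per category for the built-in baseline patterns
baseline_patterns <- function() {
  list(
    omnivorous = c(red_meat = 100, white_meat = 80, fish = 70, eggs = 30,
                   dairy = 300, vegetables = 250, legumes = 25, grains = 180,
                   nuts = 10, fruits = 300, tubers = 70, oils = 40,
                   sweets = 40, beverages = 150),
    mediterranean = c(red_meat = 30, white_meat = 50, fish = 90, eggs = 25,
                      dairy = 250, vegetables = 450, legumes = 60,
                      grains = 200, nuts = 25, fruits = 350, tubers = 80,
                      oils = 50, sweets = 10, beverages = 100),
    plant_based = c(vegetables = 400, legumes = 130, grains = 280, nuts = 40,
                    fruits = 350, tubers = 100, oils = 40, sweets = 10,
                    beverages = 200))
}

# Deterministic adequacy repair: nudge category quantities until the diet
# meets all recommended values and stays below all maxima, rescaling to the
# energy target after every step. Emulates how guideline diets are
# formulated to cover reference intakes.
repair_adequacy <- function(q, db, ref, max_iter = 80) {
  idx <- match(names(q), db$id)
  en <- db$energy_kcal_per_g[idx]
  nut <- as.matrix(as.data.frame(db)[idx, nutrient_codes(), drop = FALSE])
  cats <- db$category[idx]
  qn <- qualifying_nutrients()
  ln <- limiting_nutrients()
  for (it in seq_len(max_iter)) {
    q <- q * ref$energy_target / sum(q * en)
    intake <- as.numeric(crossprod(nut, q))
    names(intake) <- nutrient_codes()
    rq <- intake[qn] / ref$rv
    rl <- intake[ln] / ref$mv
    if (all(rq >= 1.01) && all(rl <= 0.99)) break
    if (any(rl > 0.99)) {
      worst <- ln[which.max(rl)]
      contrib <- tapply(q * nut[, worst], cats, sum)
      target_cat <- names(contrib)[which.max(contrib)]
      q[cats == target_cat] <- q[cats == target_cat] * 0.85
    } else {
      worst <- qn[which.min(rq)]
      # best source per kcal so the post-hoc energy rescale does not undo it
      dens <- tapply(nut[, worst] / pmax(en, 1e-9), cats, max)
      dens <- dens[names(dens) %in% cats[q > 0]]
      target_cat <- names(dens)[which.max(dens)]
      q[cats == target_cat] <- pmax(q[cats == target_cat], 1) * 1.25
    }
  }
  q * ref$energy_target / sum(q * en)
}

#' Generate baseline diets over a (typically synthetic) food database
#'
#' Builds named dietary patterns -- an omnivorous, a Mediterranean-like and
#' a fully plant-based pattern -- by allocating pattern-specific grams per
#' food category, splitting each category's grams across its products with
#' a seeded random allocation, then repairing the diet deterministically so
#' it meets all recommended nutrient values, respects the limiting-nutrient
#' maxima, and delivers exactly the daily energy target.
#'
#' @param db A `food_database`.
#' @param ref A `nutrient_reference`; its `energy_target` fixes the diets'
#'   energy.
#' @param seed Integer seed for the within-category allocation.
#' @param repair If `TRUE` (default) run the adequacy-repair loop.
#' @return Named list of `diet` objects.
#' @export
generate_baseline_diets <- function(db, ref = default_nutrient_reference(),
                                    seed = 1, repair = TRUE) {
  db <- food_database(db)
  if (all(db$energy_kcal_per_g == 0)) {
    stop("infeasible: all products have zero energy density")
  }
  patterns <- baseline_patterns()
  with_seed(seed, {
    diets <- lapply(names(patterns), function(pn) {
      pat <- patterns[[pn]]
      q <- stats::setNames(numeric(nrow(db)), db$id)
      for (cat in names(pat)) {
        sel <- which(db$category == cat & db$energy_kcal_per_g > 0)
        if (!length(sel)) next
        w <- stats::rgamma(length(sel), shape = 2)
        q[sel] <- pat[[cat]] * w / sum(w)
      }
      if (sum(q * db$energy_kcal_per_g) <= 0) {
        stop("infeasible: pattern '", pn, "' has zero energy on this database")
      }
      if (repair) {
        q <- repair_adequacy(q, db, ref)
      } else {
        q <- q * ref$energy_target / sum(q * db$energy_kcal_per_g)
      }
      diet(q, name = pn)
    })
    stats::setNames(diets, names(patterns))
  })
}
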