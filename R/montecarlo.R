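#' Sample nutrient weights uniformly over the floor-constrained simplices
#'
#' Draws weight sets satisfying the NRD9.3w constraints exactly: the nine
#' qualifying weights sum to 9 with floor 0.5, the three limiting weights
#' sum to 3 with floor 0.2. Each draw is `floor + slack * Dirichlet(1)`
#' componentwise -- the flat (maximum-entropy) distribution on the shifted
#' simplex.
#'
#' @param n_draws Number of draws (>= 1).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return An object of class `weight_samples`: list with matrices `kr`
#'   (`n_draws` x 9) and `km` (`n_draws` x 3), rows indexed by draw.
#' @export
sample_weights <- function(n_draws, seed) {
  if (!is.numeric(n_draws) || length(n_draws) != 1 || n_draws < 1) {
    stop("`n_draws` must be a single integer >= 1")
  }
  n_draws <- as.integer(n_draws)
  rdirichlet <- function(n, d) {
    g <- matrix(stats::rgamma(n * d, shape = 1), nrow = n)
    g / rowSums(g)
  }
  with_seed(seed, {
    kr <- 0.5 + (9 - 9 * 0.5) * rdirichlet(n_draws, 9)
    km <- 0.2 + (3 - 3 * 0.2) * rdirichlet(n_draws, 3)
    colnames(kr) <- qualifying_nutrients()
    colnames(km) <- limiting_nutrients()
    structure(list(kr = kr, km = km, n_draws = n_draws, seed = seed),
              class = "weight_samples")
  })
}

#' @export
print.weight_samples <- function(x, ...) {
  cat("weight_samples:", x$n_draws, "draws (seed", x$seed, ")\n")
  invisible(x)
}

#' Distribution of NRD9.3w under sampled nutrient weights
#'
#' Applies every sampled weight set to one intake. Each value equals
#' [compute_nrd93_weighted()] for that draw, and the whole distribution
#' lies inside the linear-programming envelope of
#' [extremal_weighted_scores()].
#'
#' @param intake A `nutrient_intake`.
#' @param ref A `nutrient_reference`.
#' @param samples A `weight_samples` object.
#' @return Numeric vector of scores, one per draw.
#' @export
score_distribution <- function(intake, ref, samples) {
  stopifnot(inherits(samples, "weight_samples"))
  ri <- relative_intakes(intake, ref)
  cq <- pmin(ri$qualifying, 1)
  100 * (as.numeric(samples$kr %*% cq) -
         as.numeric(samples$km %*% ri$limiting))
}

#' Paired weight-sensitivity comparison of two diets
#'
#' Applies the *same* weight draws to both intakes (a paired design, as
#' needed for a per-draw scatter) and reports the fraction of draws in
#' which the first diet scores strictly higher. Ties do not count as wins,
#' so two identical intakes give a win fraction of 0.
#'
#' @param intake_a,intake_b `nutrient_intake` objects for the two diets.
#' @inheritParams score_distribution
#' @return List with `win_fraction` and a data frame `scores` (columns
#'   `draw`, `score_a`, `score_b`).
#' @export
pairwise_comparison <- function(intake_a, intake_b, ref, samples) {
  sa <- score_distribution(intake_a, ref, samples)
  sb <- score_distribution(intake_b, ref, samples)
  list(win_fraction = mean(sa > sb),
       scores = data.frame(draw = seq_along(sa), score_a = sa, score_b = sb))
}
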