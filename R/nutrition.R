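#' Nutrient weighting factors for the weighted nutrient-density score
#'
#' The weighted score NRD9.3w assigns a weight to each nutrient. The
#' weights over the nine qualifying nutrients must sum to 9 with each
#' weight at least 0.5; the weights over the three limiting nutrients must
#' sum to 3 with each at least 0.2. These floors keep every nutrient with a
#' non-negligible contribution.
#'
#' @param kr Named (or canonically ordered) numeric vector of nine
#'   qualifying-nutrient weights.
#' @param km Numeric vector of three limiting-nutrient weights.
#' @return An object of class `nutrient_weights`.
#' @export
nutrient_weights <- function(kr, km) {
  kr <- normalize_weight_names(kr, qualifying_nutrients(), "kr")
  km <- normalize_weight_names(km, limiting_nutrients(), "km")
  tol <- 1e-9
  if (abs(sum(kr) - 9) > tol) {
    stop("qualifying weights must sum to 9 (got ", format(sum(kr)), ")")
  }
  if (any(kr < 0.5 - tol)) {
    stop("qualifying weight below floor 0.5 for: ",
         paste(names(kr)[kr < 0.5 - tol], collapse = ", "))
  }
  if (abs(sum(km) - 3) > tol) {
    stop("limiting weights must sum to 3 (got ", format(sum(km)), ")")
  }
  if (any(km < 0.2 - tol)) {
    stop("limiting weight below floor 0.2 for: ",
         paste(names(km)[km < 0.2 - tol], collapse = ", "))
  }
  structure(list(kr = kr, km = km), class = "nutrient_weights")
}

normalize_weight_names <- function(w, codes, what) {
  w <- unlist(w)
  if (length(w) != length(codes)) {
    stop("`", what, "` must have length ", length(codes))
  }
  if (is.null(names(w))) names(w) <- codes else {
    w <- w[codes]
    if (anyNA(w)) stop("`", what, "` must be named by nutrient codes")
  }
  w
}

#' @rdname nutrient_weights
#' @export
uniform_nutrient_weights <- function() {
  nutrient_weights(rep(1, 9), rep(1, 3))
}

#' Relative nutrient intakes (fractions of RV and MV)
#'
#' @param intake A `nutrient_intake`.
#' @param ref A `nutrient_reference`.
#' @return List with `qualifying` (NRI_i / RV_i, uncapped) and `limiting`
#'   (LNI_i / MV_i).
#' @export
relative_intakes <- function(intake, ref) {
  list(qualifying = intake$intake[qualifying_nutrients()] / ref$rv,
       limiting = intake$intake[limiting_nutrients()] / ref$mv)
}

#' Nutrient-density score NRD9.3
#'
#' NRD9.3 = TNR9 - TNL3, where TNR9 sums the percent coverage of the
#' recommended value over the nine qualifying nutrients -- with each
#' nutrient's credited intake capped at its recommended value, so
#' overconsumption earns no extra score -- and TNL3 sums the (uncapped)
#' percent of the maximum value over the three limiting nutrients. The
#' theoretical maximum is 900: full coverage of every qualifying nutrient
#' with complete avoidance of the limiting ones.
#'
#' @param intake A `nutrient_intake` (whole-diet daily totals).
#' @param ref A `nutrient_reference`.
#' @return An object of class `nutrition_score`: list with `tnr9`, `tnl3`,
#'   `nrd93` (all in percentage points) and `relative_intakes`.
#' @export
#' @examples
#' ref <- default_nutrient_reference()
#' full <- nutrient_intake(
#'   c(ref$rv, stats::setNames(rep(0, 3), limiting_nutrients())),
#'   energy = ref$energy_target)
#' compute_nrd93(full, ref)$nrd93  # 900
compute_nrd93 <- function(intake, ref) {
  ri <- relative_intakes(intake, ref)
  tnr9 <- 100 * sum(pmin(ri$qualifying, 1))
  tnl3 <- 100 * sum(ri$limiting)
  structure(list(tnr9 = tnr9, tnl3 = tnl3, nrd93 = tnr9 - tnl3,
                 relative_intakes = ri),
            class = "nutrition_score")
}

#' @export
print.nutrition_score <- function(x, ...) {
  cat(sprintf("NRD9.3 = %.1f (TNR9 = %.1f, TNL3 = %.1f)\n",
              x$nrd93, x$tnr9, x$tnl3))
  invisible(x)
}

#' Weighted nutrient-density score NRD9.3w
#'
#' Same capping rule as [compute_nrd93()], with per-nutrient weighting
#' factors. Reduces exactly to NRD9.3 under uniform weights.
#'
#' @inheritParams compute_nrd93
#' @param w A `nutrient_weights` object (validated on construction).
#' @return The weighted score in percentage points.
#' @export
compute_nrd93_weighted <- function(intake, ref, w) {
  if (!inherits(w, "nutrient_weights")) w <- nutrient_weights(w$kr, w$km)
  ri <- relative_intakes(intake, ref)
  100 * (sum(w$kr * pmin(ri$qualifying, 1)) - sum(w$km * ri$limiting))
}

# vertices of {sum(k) = total, k >= floor}: one coordinate takes all slack
simplex_vertices <- function(d, total, floor) {
  peak <- total - (d - 1) * floor
  vapply(seq_len(d), function(i) {
    v <- rep(floor, d); v[i] <- peak; v
  }, numeric(d))
}

#' Extremal weighted nutrient scores over the weight polytope
#'
#' NRD9.3w is linear in the weights at fixed intakes, so its extremes over
#' the floor-constrained simplices sit at vertices: all the slack weight on
#' a single nutrient (5 for a qualifying nutrient, 2.6 for a limiting one)
#' and the floor on the rest. The maximum overweights the best-performing
#' qualifying nutrient and the least-consumed limiting nutrient; the
#' minimum does the opposite. Ties are broken by canonical nutrient order.
#'
#' @inheritParams compute_nrd93
#' @return List with `min`, `max` (scores), and `min_weights`,
#'   `max_weights` (`nutrient_weights` attaining them).
#' @export
extremal_weighted_scores <- function(intake, ref) {
  ri <- relative_intakes(intake, ref)
  cq <- pmin(ri$qualifying, 1)
  rl <- ri$limiting
  vq <- simplex_vertices(9, 9, 0.5)    # 9 x 9, one column per vertex
  vl <- simplex_vertices(3, 3, 0.2)
  qs <- as.numeric(crossprod(vq, cq))  # score contribution per vertex
  ls <- as.numeric(crossprod(vl, rl))
  pick <- function(scores, which_fun) which_fun(scores)
  i_max <- pick(qs, which.max); j_max <- pick(ls, which.min)
  i_min <- pick(qs, which.min); j_min <- pick(ls, which.max)
  mk <- function(i, j) nutrient_weights(vq[, i], vl[, j])
  list(min = 100 * (qs[i_min] - ls[j_min]),
       max = 100 * (qs[i_max] - ls[j_max]),
       min_weights = mk(i_min, j_min),
       max_weights = mk(i_max, j_max))
}
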