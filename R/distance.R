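objective_names <- function() c("NUTR", "ENV", "EC")

#' Objective weights for the distance-to-target indicator
#'
#' Weights over the three objectives (nutrition, environment, economy) must
#' sum to the number of objectives and respect a common floor V_L (default
#' 0.2) so that no objective is silenced when minimizing the distance.
#'
#' @param nutr,env,ec Weights of the three objectives.
#' @param floor Minimal admissible weight V_L, in (0, 1].
#' @return An object of class `objective_weights` (named numeric `k` plus
#'   the floor).
#' @export
objective_weights <- function(nutr = 1, env = 1, ec = 1, floor = 0.2) {
  k <- c(NUTR = nutr, ENV = env, EC = ec)
  if (!is.numeric(floor) || floor <= 0 || floor > 1) {
    stop("`floor` (V_L) must lie in (0, 1]")
  }
  if (abs(sum(k) - 3) > 1e-9) {
    stop("objective weights must sum to 3 (got ", format(sum(k)), ")")
  }
  if (any(k < floor - 1e-9)) {
    stop("objective weight below floor ", floor, " for: ",
         paste(names(k)[k < floor - 1e-9], collapse = ", "))
  }
  structure(list(k = k, floor = floor), class = "objective_weights")
}

#' Plain Euclidean distance to a target vector
#'
#' @param f Numeric vector to be assessed.
#' @param g Target vector of the same length.
#' @return `sqrt(sum((f - g)^2))`.
#' @export
euclidean_distance <- function(f, g) {
  if (length(f) != length(g)) {
    stop("dimension mismatch: length(f) = ", length(f),
         ", length(g) = ", length(g))
  }
  sqrt(sum((f - g)^2))
}

default_target <- function() c(NUTR = 1, ENV = 0, EC = 0)

as_score_triplet <- function(x) {
  if (inherits(x, "score_vector")) {
    x <- c(x$x_nutr, x$x_env, x$x_ec)
  }
  x <- unlist(x)
  if (length(x) != 3) stop("expected a 3-dimensional normalized score vector")
  stats::setNames(as.numeric(x), objective_names())
}

#' Normalized weighted distance to target (Dn)
#'
#' The central indicator: `Dn = sqrt( sum_i k_i (F_i - G_i)^2 / n )` over
#' the n = 3 normalized objectives, with targets full nutrition
#' (X_NUTR = 1) and zero emissions and cost (X_ENV = X_EC = 0). With
#' normalized scores in [0, 1] and weights summing to n, Dn lies in [0, 1]:
#' 0 is on-target, 1 is maximally distant on every axis.
#'
#' @param x A `score_vector` or numeric triplet `(x_nutr, x_env, x_ec)`.
#' @param w An `objective_weights` object (uniform by default).
#' @param target Target triplet G (defaults to `(1, 0, 0)`).
#' @return The distance Dn.
#' @export
#' @examples
#' normalized_distance(c(0.702, 0.312, 0.518))  # about 0.389
normalized_distance <- function(x, w = objective_weights(),
                                target = default_target()) {
  if (!inherits(w, "objective_weights")) {
    stop("`w` must be created with objective_weights()")
  }
  f <- as_score_triplet(x)
  g <- as_score_triplet(target)
  sqrt(sum(w$k * (f - g)^2) / 3)
}

#' Extremal distances over the floor-constrained weight simplex
#'
#' Dn^2 is linear in the objective weights, so its extremes over
#' `{sum k = 3, k >= V_L}` are attained at the three vertices that put all
#' slack weight (3 - 2 V_L) on a single objective. The maximal distance
#' overweights the objective with the largest squared deviation from
#' target (the least favorable aspect); the minimal distance overweights
#' the smallest (the most favorable aspect). Vertex ties are broken in the
#' order NUTR, ENV, EC.
#'
#' @inheritParams normalized_distance
#' @param floor Weight floor V_L in (0, 1].
#' @return List with `min`, `max` (distances), `min_aspect`, `max_aspect`
#'   (the overweighted objective), and the corresponding
#'   `objective_weights`.
#' @export
extremal_distances <- function(x, floor = 0.2, target = default_target()) {
  if (floor > 1 || floor <= 0) stop("infeasible floor: V_L must be in (0, 1]")
  f <- as_score_triplet(x)
  g <- as_score_triplet(target)
  dev2 <- (f - g)^2
  verts <- simplex_vertices(3, 3, floor)   # column j overweights objective j
  d2 <- as.numeric(crossprod(verts, dev2)) / 3
  j_max <- which.max(d2)
  j_min <- which.min(d2)
  wts <- function(j) objective_weights(verts[1, j], verts[2, j], verts[3, j],
                                       floor = floor)
  list(min = sqrt(d2[j_min]), max = sqrt(d2[j_max]),
       min_aspect = objective_names()[j_min],
       max_aspect = objective_names()[j_max],
       min_weights = wts(j_min), max_weights = wts(j_max))
}

#' Distance table for a set of diets (uniform and extremal weightings)
#'
#' @param scores Data frame as returned by [score_table()] (columns `diet`,
#'   `x_nutr`, `x_env`, `x_ec`).
#' @param floor Weight floor V_L.
#' @return Data frame with one row per diet: equally weighted Dn, maximal
#'   and minimal Dn and the overweighted aspects.
#' @export
distance_table <- function(scores, floor = 0.2) {
  scores <- as.data.frame(scores)
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    x <- c(scores$x_nutr[i], scores$x_env[i], scores$x_ec[i])
    ext <- extremal_distances(x, floor = floor)
    data.frame(diet = scores$diet[i],
               dn_uniform = normalized_distance(x),
               dn_max = ext$max, max_aspect = ext$max_aspect,
               dn_min = ext$min, min_aspect = ext$min_aspect,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
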