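#' Acceptability constraint on deviations from a baseline diet
#'
#' Optimized quantities are kept close to the baseline pattern either by a
#' symmetric band of `tv` percent around every baseline amount
#' (`mode = "tv"`; the lower bound is clamped at zero, and products absent
#' from the baseline stay absent), or -- for baselines too distant from the
#' nutritional targets -- by the asymmetric band
#' `[10% of baseline, nv x baseline]` (`mode = "nv"`). `mode = "none"`
#' leaves intakes free (only non-negativity and the natural energy box).
#'
#' @param mode `"none"`, `"tv"` or `"nv"`.
#' @param tv Percentage band for `"tv"` mode; >= 0, may exceed 100.
#' @param nv Multiplier for `"nv"` mode; >= 1.
#' @return An object of class `acceptability_spec`.
#' @export
acceptability_spec <- function(mode = c("none", "tv", "nv"), tv = NULL,
                               nv = NULL) {
  mode <- match.arg(mode)
  if (mode == "tv") {
    if (is.null(tv) || !is.numeric(tv) || length(tv) != 1 || tv < 0) {
      stop("`tv` must be a single percentage >= 0")
    }
  }
  if (mode == "nv") {
    if (is.null(nv) || !is.numeric(nv) || length(nv) != 1 || nv < 1) {
      stop("`nv` must be a single multiplier >= 1")
    }
  }
  structure(list(mode = mode, tv = tv, nv = nv), class = "acceptability_spec")
}

#' Solver settings for the diet optimizer
#'
#' @param maxeval Maximum objective evaluations per start.
#' @param xtol_rel Relative parameter tolerance of the SLSQP solver.
#' @param energy_tol Relative half-width of the energy-equality band (the
#'   equality is implemented as two inequalities for solver friendliness).
#' @param feas_tol Relative tolerance when re-checking constraints of a
#'   reported solution.
#' @param seeds Integer seeds of the random multistart points (at least one;
#'   the baseline/midpoint starts are always added).
#' @return List of class `solver_control`.
#' @export
solver_control <- function(maxeval = 5000, xtol_rel = 1e-10,
                           energy_tol = 1e-6, feas_tol = 1e-6,
                           seeds = 1:5) {
  structure(list(maxeval = maxeval, xtol_rel = xtol_rel,
                 energy_tol = energy_tol, feas_tol = feas_tol,
                 seeds = as.integer(seeds)),
            class = "solver_control")
}

# precomputed linear maps of the NLP: everything is linear in the gram
# quantities except the distance objective itself
problem_data <- function(db, ref, ctx, w) {
  db <- food_database(db)
  nut <- as.matrix(as.data.frame(db)[, nutrient_codes(), drop = FALSE])
  list(db = db,
       ids = db$id,
       en = db$energy_kcal_per_g,
       E = ref$energy_target,
       Aq = sweep(nut[, qualifying_nutrients(), drop = FALSE], 2, ref$rv, "/"),
       Al = sweep(nut[, limiting_nutrients(), drop = FALSE], 2, ref$mv, "/"),
       ghg_g = 1e-3 * db$ghg_kgco2e_per_kg,
       cost_g = 1e-3 * db$price_eur_per_kg,
       k = w$k, ctx = ctx, ref = ref)
}

# distance objective (Dn^2 * 3, a monotone transform of Dn) and gradient
dn_objective <- function(pd) {
  list(
    fn = function(q) {
      rq <- as.numeric(crossprod(pd$Aq, q))
      rl <- as.numeric(crossprod(pd$Al, q))
      x_nutr <- (sum(pmin(rq, 1)) - sum(rl)) / 9
      x_env <- sum(pd$ghg_g * q) / pd$ctx$ghg_max
      x_ec <- sum(pd$cost_g * q) / pd$ctx$tc_max
      pd$k[["NUTR"]] * (1 - x_nutr)^2 + pd$k[["ENV"]] * x_env^2 +
        pd$k[["EC"]] * x_ec^2
    },
    gr = function(q) {
      rq <- as.numeric(crossprod(pd$Aq, q))
      rl <- as.numeric(crossprod(pd$Al, q))
      x_nutr <- (sum(pmin(rq, 1)) - sum(rl)) / 9
      x_env <- sum(pd$ghg_g * q) / pd$ctx$ghg_max
      x_ec <- sum(pd$cost_g * q) / pd$ctx$tc_max
      d_xnutr <- (pd$Aq %*% as.numeric(rq < 1) - rowSums(pd$Al)) / 9
      as.numeric(-2 * pd$k[["NUTR"]] * (1 - x_nutr) * d_xnutr +
                 2 * pd$k[["ENV"]] * x_env * pd$ghg_g / pd$ctx$ghg_max +
                 2 * pd$k[["EC"]] * x_ec * pd$cost_g / pd$ctx$tc_max)
    })
}

# nutritional constraints as hin(q) <= 0 with analytic jacobian
nutrition_constraints <- function(pd, energy_tol, extra_hin = NULL,
                                  extra_jac = NULL) {
  list(
    hin = function(q) {
      e_rel <- sum(pd$en * q) / pd$E
      rq <- as.numeric(crossprod(pd$Aq, q))
      rl <- as.numeric(crossprod(pd$Al, q))
      base <- c(1 - energy_tol - e_rel, e_rel - 1 - energy_tol, 1 - rq, rl - 1)
      if (is.null(extra_hin)) base else c(base, extra_hin(q))
    },
    hinjac = function(q) {
      base <- rbind(-pd$en / pd$E, pd$en / pd$E, -t(pd$Aq), t(pd$Al))
      if (is.null(extra_jac)) base else rbind(base, extra_jac(q))
    })
}

# independent re-check of a candidate solution against all constraints
constraint_report <- function(q, pd, lower, upper, feas_tol) {
  e_rel <- sum(pd$en * q) / pd$E
  rq <- as.numeric(crossprod(pd$Aq, q))
  rl <- as.numeric(crossprod(pd$Al, q))
  bound_tol <- feas_tol * pmax(1, upper)
  data.frame(
    constraint = c("energy", paste0("adequacy_", qualifying_nutrients()),
                   paste0("limit_", limiting_nutrients()),
                   "lower_bounds", "upper_bounds"),
    value = c(e_rel, rq, rl, min(q - lower), max(q - upper)),
    ok = c(abs(e_rel - 1) <= 2 * feas_tol,
           rq >= 1 - feas_tol,
           rl <= 1 + feas_tol,
           all(q >= lower - bound_tol),
           all(q <= upper + bound_tol)),
    stringsAsFactors = FALSE)
}

#' Re-check the nutritional constraints of a diet
#'
#' Independent constraint evaluator: recomputes energy, adequacy and
#' limiting-nutrient ratios of a diet and reports whether each holds within
#' tolerance. Used to validate reported-feasible optimizer solutions.
#'
#' @param diet A `diet`.
#' @param db A `food_database`.
#' @param ref A `nutrient_reference`.
#' @param feas_tol Relative tolerance.
#' @return Data frame with columns `constraint`, `value`, `ok`.
#' @export
check_constraints <- function(diet, db, ref = default_nutrient_reference(),
                              feas_tol = 1e-6) {
  pd <- problem_data(db, ref, ctx = structure(list(ghg_max = 1, tc_max = 1),
                                              class = "normalization_context"),
                     w = objective_weights())
  q <- stats::setNames(numeric(length(pd$ids)), pd$ids)
  q[names(diet$quantities)] <- diet$quantities
  constraint_report(q, pd, lower = rep(0, length(q)),
                    upper = rep(Inf, length(q)), feas_tol = feas_tol)
}

acceptability_bounds <- function(baseline_q, acc, pd) {
  switch(acc$mode,
    none = list(lower = rep(0, length(pd$ids)),
                upper = pd$E / pmax(pd$en, 1e-12)),
    tv = list(lower = pmax(0, baseline_q * (1 - acc$tv / 100)),
              upper = baseline_q * (1 + acc$tv / 100)),
    nv = list(lower = 0.1 * baseline_q, upper = baseline_q * acc$nv))
}

# multistart SLSQP over box [lower, upper] with the nutritional constraints
solve_diet_nlp <- function(pd, lower, upper, starts, objective, control) {
  cons <- nutrition_constraints(pd, control$energy_tol)
  best <- NULL
  statuses <- integer(0)
  for (x0 in starts) {
    x0 <- pmin(pmax(x0, lower), upper)
    res <- tryCatch(
      nloptr::slsqp(x0, fn = objective$fn, gr = objective$gr,
                    lower = lower, upper = upper,
                    hin = cons$hin, hinjac = cons$hinjac,
                    control = list(maxeval = control$maxeval,
                                   xtol_rel = control$xtol_rel),
                    deprecatedBehavior = FALSE),
      error = function(e) list(par = x0, value = objective$fn(x0),
                               convergence = -99L))
    statuses <- c(statuses, res$convergence)
    rep_i <- constraint_report(res$par, pd, lower, upper, control$feas_tol)
    cand <- list(par = res$par, value = objective$fn(res$par),
                 feasible = all(rep_i$ok), report = rep_i,
                 status = res$convergence)
    if (is.null(best) ||
        (cand$feasible && !best$feasible) ||
        (cand$feasible == best$feasible && cand$value < best$value)) {
      best <- cand
    }
  }
  if (all(statuses < 0)) {
    stop("solver failed to converge from all ", length(starts), " starts")
  }
  best$n_starts <- length(starts)
  best
}

multistart_points <- function(lower, upper, base, control) {
  pts <- list(base, (lower + upper) / 2)
  finite_ub <- ifelse(is.finite(upper), upper, pmax(1, 2 * base))
  for (s in control$seeds) {
    pts <- c(pts, list(with_seed(s, stats::runif(length(lower), lower,
                                                 finite_ub))))
  }
  pts
}

finish_result <- function(best, pd, baseline_name, control) {
  q <- stats::setNames(pmax(best$par, 0), pd$ids)
  d <- diet(q, name = paste0(baseline_name, "-opt"))
  intake <- compute_intake(d, pd$db)
  sc <- normalize_scores(compute_nrd93(intake, pd$ref)$nrd93,
                         total_cost(d, pd$db), total_ghg(d, pd$db), pd$ctx)
  w <- objective_weights(pd$k[["NUTR"]], pd$k[["ENV"]], pd$k[["EC"]],
                         floor = min(pd$k))
  structure(list(diet = d, scores = sc, dn = normalized_distance(sc, w),
                 solver_status = best$status, n_starts = best$n_starts,
                 feasible = best$feasible, violations = best$report,
                 n_support = sum(q > 1)),
            class = "diet_optimization")
}

#' @export
print.diet_optimization <- function(x, ...) {
  cat(sprintf("Optimized diet '%s': Dn = %.4f (%s, %d starts, status %d)\n",
              x$diet$name, x$dn,
              if (x$feasible) "feasible" else "INFEASIBLE",
              x$n_starts, x$solver_status))
  print(x$scores)
  invisible(x)
}

#' Optimize a diet by minimizing the distance to target
#'
#' Solves the constrained nonlinear program over the daily gram quantities:
#' minimize the normalized weighted distance Dn of the candidate's score
#' vector (computed against a *frozen* normalization context) subject to
#' the energy equality, full adequacy of the nine qualifying nutrients,
#' the limiting-nutrient maxima, and the acceptability bounds around the
#' baseline. A sequential quadratic programming solver (SLSQP) is run from
#' several starting points; the best solution that an independent
#' constraint re-check confirms feasible is returned.
#'
#' @param baseline A `diet` defining the acceptability bounds (and one of
#'   the starting points).
#' @param db A `food_database`.
#' @param ref A `nutrient_reference`.
#' @param ctx A `normalization_context`, typically built once from the
#'   baseline diet set and held fixed.
#' @param w An `objective_weights`.
#' @param acc An `acceptability_spec`.
#' @param control A `solver_control`.
#' @return An object of class `diet_optimization`: the optimal `diet`, its
#'   `score_vector`, the distance `dn`, `feasible`, `solver_status`,
#'   `n_starts` and the constraint re-check report.
#' @export
optimize_diet <- function(baseline, db, ref, ctx, w = objective_weights(),
                          acc = acceptability_spec("tv", tv = 60),
                          control = solver_control()) {
  pd <- problem_data(db, ref, ctx, w)
  q0 <- stats::setNames(numeric(length(pd$ids)), pd$ids)
  q0[names(baseline$quantities)] <- baseline$quantities
  b <- acceptability_bounds(q0, acc, pd)
  if (max(b$upper - b$lower) < 1e-9) {  # degenerate band: baseline is fixed
    best <- list(par = q0, value = dn_objective(pd)$fn(q0),
                 feasible = all(constraint_report(q0, pd, b$lower, b$upper,
                                                  control$feas_tol)$ok),
                 report = constraint_report(q0, pd, b$lower, b$upper,
                                            control$feas_tol),
                 status = 1L, n_starts = 1L)
    return(finish_result(best, pd, baseline$name, control))
  }
  starts <- multistart_points(b$lower, b$upper, q0, control)
  best <- solve_diet_nlp(pd, b$lower, b$upper, starts, dn_objective(pd),
                         control)
  finish_result(best, pd, baseline$name, control)
}

#' Optimize without acceptability restrictions
#'
#' Same program as [optimize_diet()] with only non-negativity (and the
#' natural per-product energy box) on the quantities. Unrestricted optima
#' are typically sparse -- few products suffice to meet the constraints at
#' minimal distance -- and the result reports the support size
#' (`n_support`, products above 1 g/day).
#'
#' @inheritParams optimize_diet
#' @return A `diet_optimization`.
#' @export
optimize_unrestricted <- function(db, ref, ctx, w = objective_weights(),
                                  control = solver_control()) {
  pd <- problem_data(db, ref, ctx, w)
  n <- length(pd$ids)
  lower <- rep(0, n)
  upper <- pd$E / pmax(pd$en, 1e-12)
  # equal-energy-share start satisfies the energy equality exactly
  base <- pd$E / (n * pmax(pd$en, 1e-12))
  starts <- multistart_points(lower, upper, base, control)
  starts <- lapply(starts, function(q) q * pd$E / sum(pd$en * q))
  best <- solve_diet_nlp(pd, lower, upper, starts, dn_objective(pd), control)
  finish_result(best, pd, "unrestricted", control)
}

# phase-1 feasibility: squared-hinge violation minimized over the box
feasibility_gap <- function(pd, lower, upper) {
  fn <- function(q) {
    e_rel <- sum(pd$en * q) / pd$E
    rq <- as.numeric(crossprod(pd$Aq, q))
    rl <- as.numeric(crossprod(pd$Al, q))
    (e_rel - 1)^2 + sum(pmax(1 - rq, 0)^2) + sum(pmax(rl - 1, 0)^2)
  }
  gr <- function(q) {
    e_rel <- sum(pd$en * q) / pd$E
    rq <- as.numeric(crossprod(pd$Aq, q))
    rl <- as.numeric(crossprod(pd$Al, q))
    as.numeric(2 * (e_rel - 1) * pd$en / pd$E -
               2 * pd$Aq %*% pmax(1 - rq, 0) +
               2 * pd$Al %*% pmax(rl - 1, 0))
  }
  if (max(upper - lower) < 1e-12) {
    return(list(gap = fn(lower), par = lower))
  }
  starts <- list((lower + upper) / 2, lower, upper)
  best <- NULL
  for (x0 in starts) {
    res <- stats::optim(x0, fn, gr, method = "L-BFGS-B", lower = lower,
                        upper = upper,
                        control = list(maxit = 500, factr = 1e4))
    if (is.null(best) || res$value < best$gap) {
      best <- list(gap = res$value, par = res$par)
    }
    if (best$gap < 1e-14) break
  }
  best
}

violated_nutrients <- function(pd, q, tol = 1e-6) {
  rq <- as.numeric(crossprod(pd$Aq, q))
  rl <- as.numeric(crossprod(pd$Al, q))
  c(qualifying_nutrients()[rq < 1 - tol], limiting_nutrients()[rl > 1 + tol])
}

#' Minimal acceptability margin for a baseline diet
#'
#' Finds the smallest symmetric band (integer percentage `tv`) around the
#' baseline under which the energy, adequacy and limiting-nutrient
#' constraints admit a feasible diet; feasibility is monotone in the band
#' width, so the search is a bisection over integer margins, each level
#' decided by a smooth phase-1 feasibility subproblem. If no band up to
#' `tv_max` suffices (a baseline very distant from its targets), the search
#' switches to the asymmetric `nv` mode and returns the smallest multiplier
#' on a 0.5 grid. Also reports the nutrients still violated just below the
#' threshold -- the constraints that bind the diet.
#'
#' @inheritParams optimize_diet
#' @param tv_max Largest symmetric margin tried (percent).
#' @param nv_max Largest multiplier tried in `nv` mode.
#' @return List with `mode` (`"tv"` or `"nv"`), `value`, (vector)
#'   `limiting_nutrients`, and `trace` (data frame of levels probed with
#'   their feasibility).
#' @export
minimal_acceptability_margin <- function(baseline, db,
                                         ref = default_nutrient_reference(),
                                         tv_max = 100, nv_max = 20,
                                         control = solver_control()) {
  pd <- problem_data(db, ref,
                     ctx = structure(list(ghg_max = 1, tc_max = 1),
                                     class = "normalization_context"),
                     w = objective_weights())
  q0 <- stats::setNames(numeric(length(pd$ids)), pd$ids)
  q0[names(baseline$quantities)] <- baseline$quantities
  trace <- list()
  gap_tol <- 1e-12
  probe <- function(mode, value) {
    acc <- if (mode == "tv") acceptability_spec("tv", tv = value) else {
      acceptability_spec("nv", nv = value)
    }
    b <- acceptability_bounds(q0, acc, pd)
    g <- feasibility_gap(pd, b$lower, b$upper)
    trace[[length(trace) + 1]] <<- data.frame(mode = mode, value = value,
                                              gap = g$gap,
                                              feasible = g$gap < gap_tol)
    g
  }
  done <- function(mode, value, below) {
    limiting <- if (is.null(below)) character(0) else {
      violated_nutrients(pd, below$par)
    }
    list(mode = mode, value = value, limiting_nutrients = limiting,
         trace = do.call(rbind, trace))
  }
  g0 <- probe("tv", 0)
  if (g0$gap < gap_tol) return(done("tv", 0, NULL))
  g_hi <- probe("tv", tv_max)
  if (g_hi$gap < gap_tol) {
    lo <- 0; hi <- tv_max; g_lo <- g0
    while (hi - lo > 1) {
      mid <- floor((lo + hi) / 2)
      g_mid <- probe("tv", mid)
      if (g_mid$gap < gap_tol) hi <- mid else { lo <- mid; g_lo <- g_mid }
    }
    return(done("tv", hi, g_lo))
  }
  # tv exhausted: switch to the multiplier band
  levels <- seq(1, nv_max, by = 0.5)
  g_top <- probe("nv", nv_max)
  if (!(g_top$gap < gap_tol)) {
    stop("infeasible even at nv = ", nv_max, "; unsatisfiable nutrient(s): ",
         paste(violated_nutrients(pd, g_top$par), collapse = ", "))
  }
  lo_i <- 1L; hi_i <- length(levels)
  g_lo <- probe("nv", levels[1])
  if (g_lo$gap < gap_tol) return(done("nv", 1, g_hi))
  while (hi_i - lo_i > 1L) {
    mid_i <- as.integer(floor((lo_i + hi_i) / 2))
    g_mid <- probe("nv", levels[mid_i])
    if (g_mid$gap < gap_tol) hi_i <- mid_i else { lo_i <- mid_i; g_lo <- g_mid }
  }
  done("nv", levels[hi_i], g_lo)
}

dominated <- function(i, pts) {
  any(vapply(seq_len(nrow(pts)), function(j) {
    if (i == j) return(FALSE)
    ge <- pts$nrd93[j] >= pts$nrd93[i] - 1e-9 &&
      pts$cost[j] <= pts$cost[i] + 1e-9 && pts$ghg[j] <= pts$ghg[i] + 1e-9
    strict <- pts$nrd93[j] > pts$nrd93[i] + 1e-9 ||
      pts$cost[j] < pts$cost[i] - 1e-9 || pts$ghg[j] < pts$ghg[i] - 1e-9
    ge && strict
  }, logical(1)))
}

#' Pareto front by the epsilon-constraint method
#'
#' For each level of the cost budget, optimizes one objective (maximize
#' NRD9.3 or minimize GHG emissions) subject to the energy equality, the
#' nutritional constraints and `cost <= eps`, without acceptability
#' restrictions. Infeasible levels are skipped with a message. The returned
#' points are filtered to the mutually non-dominated set over
#' (NRD9.3 up, cost down, GHG down).
#'
#' @inheritParams optimize_diet
#' @param cost_levels Numeric vector of cost budgets (EUR/day).
#' @param objective `"nrd93"` (maximize) or `"ghg"` (minimize).
#' @param nutritional_constraints Keep adequacy/limit constraints (default
#'   `TRUE`).
#' @return List with `points` (all solved levels: `eps`, `nrd93`, `cost`,
#'   `ghg`, `feasible`) and `front` (the non-dominated subset).
#' @export
pareto_front <- function(db, ref, cost_levels,
                         objective = c("nrd93", "ghg"),
                         nutritional_constraints = TRUE,
                         control = solver_control()) {
  objective <- match.arg(objective)
  pd <- problem_data(db, ref,
                     ctx = structure(list(ghg_max = 1, tc_max = 1),
                                     class = "normalization_context"),
                     w = objective_weights())
  n <- length(pd$ids)
  lower <- rep(0, n)
  upper <- pd$E / pmax(pd$en, 1e-12)
  obj <- if (objective == "nrd93") {
    list(fn = function(q) {
      rq <- as.numeric(crossprod(pd$Aq, q))
      rl <- as.numeric(crossprod(pd$Al, q))
      -(sum(pmin(rq, 1)) - sum(rl)) / 9
    }, gr = function(q) {
      rq <- as.numeric(crossprod(pd$Aq, q))
      as.numeric(-(pd$Aq %*% as.numeric(rq < 1) - rowSums(pd$Al)) / 9)
    })
  } else {
    list(fn = function(q) sum(pd$ghg_g * q),
         gr = function(q) pd$ghg_g)
  }
  rows <- list()
  for (eps in sort(cost_levels)) {
    cons <- nutrition_constraints(
      pd, control$energy_tol,
      extra_hin = function(q) sum(pd$cost_g * q) / eps - 1,
      extra_jac = function(q) matrix(pd$cost_g / eps, nrow = 1))
    if (!nutritional_constraints) {
      cons <- list(
        hin = function(q) {
          e_rel <- sum(pd$en * q) / pd$E
          c(1 - control$energy_tol - e_rel, e_rel - 1 - control$energy_tol,
            sum(pd$cost_g * q) / eps - 1)
        },
        hinjac = function(q) rbind(-pd$en / pd$E, pd$en / pd$E,
                                   pd$cost_g / eps))
    }
    base <- pd$E / (n * pmax(pd$en, 1e-12))
    starts <- lapply(multistart_points(lower, upper, base, control)[1:4],
                     function(q) q * pd$E / sum(pd$en * q))
    best <- NULL
    for (x0 in starts) {
      res <- tryCatch(
        nloptr::slsqp(pmin(pmax(x0, lower), upper), fn = obj$fn, gr = obj$gr,
                      lower = lower, upper = upper,
                      hin = cons$hin, hinjac = cons$hinjac,
                      control = list(maxeval = control$maxeval,
                                     xtol_rel = control$xtol_rel),
                      deprecatedBehavior = FALSE),
        error = function(e) NULL)
      if (is.null(res)) next
      q <- pmax(res$par, 0)
      feas <- max(cons$hin(q)) <= control$feas_tol
      cand <- list(par = q, value = obj$fn(q), feasible = feas)
      if (is.null(best) || (cand$feasible && !best$feasible) ||
          (cand$feasible == best$feasible && cand$value < best$value)) {
        best <- cand
      }
    }
    if (is.null(best) || !best$feasible) {
      message("epsilon level ", eps, " EUR/day infeasible; skipped")
      next
    }
    d <- diet(stats::setNames(best$par, pd$ids), name = paste0("eps_", eps))
    intake <- compute_intake(d, pd$db)
    rows[[length(rows) + 1]] <- data.frame(
      eps = eps, nrd93 = compute_nrd93(intake, pd$ref)$nrd93,
      cost = total_cost(d, pd$db), ghg = total_ghg(d, pd$db),
      feasible = TRUE)
  }
  points <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(eps = numeric(0), nrd93 = numeric(0), cost = numeric(0),
               ghg = numeric(0), feasible = logical(0))
  }
  keep <- if (nrow(points)) {
    !vapply(seq_len(nrow(points)), dominated, logical(1), pts = points)
  } else logical(0)
  list(points = points, front = points[keep, , drop = FALSE])
}
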