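test_that("a zero-width acceptability band returns the baseline itself", {
  p <- toy_problem()
  r <- optimize_diet(p$baseline, p$db, p$ref, p$ctx,
                     acc = acceptability_spec("tv", tv = 0))
  expect_true(r$feasible)
  expect_equal(unname(r$diet$quantities), unname(p$baseline$quantities),
               tolerance = 1e-9)
  base_sv <- normalize_scores(
    compute_nrd93(compute_intake(p$baseline, p$db), p$ref)$nrd93,
    total_cost(p$baseline, p$db), total_ghg(p$baseline, p$db), p$ctx)
  expect_equal(r$dn, normalized_distance(base_sv), tolerance = 1e-9)
})

test_that("the NLP optimum matches a 1-gram grid-search oracle", {
  p <- toy_problem()
  r <- optimize_diet(p$baseline, p$db, p$ref, p$ctx,
                     acc = acceptability_spec("tv", tv = 30))
  expect_true(r$feasible)
  expect_equal(r$dn, grid_oracle(p, 30), tolerance = 1e-3)
})

test_that("reported-feasible solutions pass an independent constraint check", {
  p <- toy_problem()
  r <- optimize_diet(p$baseline, p$db, p$ref, p$ctx,
                     acc = acceptability_spec("tv", tv = 40))
  expect_true(r$feasible)
  intake <- compute_intake(r$diet, p$db)
  expect_equal(intake$energy, 2228, tolerance = 2228 * 2e-6)
  ri <- relative_intakes(intake, p$ref)
  expect_true(all(ri$qualifying >= 1 - 1e-6))
  expect_true(all(ri$limiting <= 1 + 1e-6))
  rep_df <- check_constraints(r$diet, p$db, p$ref)
  expect_true(all(rep_df$ok))
  # quantities respect the acceptability band
  lb <- p$baseline$quantities * 0.6
  ub <- p$baseline$quantities * 1.4
  expect_true(all(r$diet$quantities >= lb - 1e-6))
  expect_true(all(r$diet$quantities <= ub + 1e-6))
})

test_that("widening the acceptability band never increases the distance", {
  p <- toy_problem()
  dns <- vapply(c(10, 20, 40, 60), function(tv) {
    optimize_diet(p$baseline, p$db, p$ref, p$ctx,
                  acc = acceptability_spec("tv", tv = tv))$dn
  }, numeric(1))
  expect_true(all(diff(dns) <= 1e-6))
})

test_that("multistart returns consistent optima across extra seed sets", {
  p <- toy_problem()
  r1 <- optimize_diet(p$baseline, p$db, p$ref, p$ctx,
                      acc = acceptability_spec("tv", tv = 30),
                      control = solver_control(seeds = 1:5))
  r2 <- optimize_diet(p$baseline, p$db, p$ref, p$ctx,
                      acc = acceptability_spec("tv", tv = 30),
                      control = solver_control(seeds = 6:10))
  expect_equal(r1$dn, r2$dn, tolerance = 1e-4)
  expect_gte(r1$n_starts, 5)
})

test_that("unrestricted optima are sparse and fully adequate", {
  db <- generate_synthetic_database(28, seed = 4)
  ref <- default_nutrient_reference()
  diets <- generate_baseline_diets(db, ref, seed = 4)
  ctx <- build_normalization(score_table(diets, db, ref))
  u <- optimize_unrestricted(db, ref, ctx,
                             control = solver_control(seeds = 1:3))
  expect_true(u$feasible)
  intake <- compute_intake(u$diet, db)
  expect_equal(intake$energy, 2228, tolerance = 2228 * 2e-6)
  ri <- relative_intakes(intake, ref)
  expect_true(all(ri$qualifying >= 1 - 1e-6))
  support_base <- min(vapply(diets, function(d) sum(d$quantities > 1),
                             numeric(1)))
  # sparsity is observed and logged, not asserted as a hard bound
  cat(sprintf("\nunrestricted support %d vs smallest baseline support %d\n",
              u$n_support, support_base))
  expect_lt(u$dn, min(vapply(diets, function(d) {
    sv <- score_table(list(d), db, ref, ctx)
    normalized_distance(unlist(sv[, c("x_nutr", "x_env", "x_ec")]))
  }, numeric(1))))
})

test_that("minimal margin search finds the constructed threshold and nutrient", {
  f <- margin_fixture()
  rv_ca_fixture_check(f)
  m <- minimal_acceptability_margin(f$baseline, f$db, f$ref)
  expect_equal(m$mode, "tv")
  expect_equal(m$value, 30)
  expect_equal(m$limiting_nutrients, "Ca")
  # feasibility is monotone along the probed trace
  tr <- m$trace[m$trace$mode == "tv", ]
  feas_lv <- tr$value[tr$feasible]
  infeas_lv <- tr$value[!tr$feasible]
  expect_true(all(outer(infeas_lv, feas_lv, `<`)))
})

test_that("a baseline already satisfying all constraints needs no margin", {
  p <- toy_problem()
  m <- minimal_acceptability_margin(p$baseline, p$db, p$ref)
  expect_equal(m$mode, "tv")
  expect_equal(m$value, 0)
  expect_length(m$limiting_nutrients, 0)
})

test_that("margin search falls back to the multiplier band when needed", {
  # deficit so large that even +100% on the calcium source cannot close it
  f <- margin_fixture()
  rv <- f$ref$rv
  rv["Ca"] <- 1100  # ca_rich can reach 500 * (1 + 1) = 1000 < 1100 under tv
  ref <- nutrient_reference(rv, f$ref$mv, f$ref$energy_target)
  m <- minimal_acceptability_margin(f$baseline, f$db, ref)
  expect_equal(m$mode, "nv")
  expect_gte(m$value, 2)
  expect_true("Ca" %in% m$limiting_nutrients)
  # the returned multiplier is feasible: ca_rich * nv >= 1100 and energy holds
  expect_gte(500 * m$value, 1100)
})

test_that("epsilon-constraint front matches the analytic front on a toy", {
  # two isocaloric products; only fiber scores; product f2 is nutritious but
  # 4x the price: the attainable score is a known piecewise-linear function
  # of the cost budget
  rows <- rbind(
    product_row("cheap", "grains", energy = 1, price = 1, ghg = 1),
    product_row("rich", "legumes", energy = 1, price = 4, ghg = 1,
                fiber = 25 / 500))
  trace <- setdiff(qualifying_nutrients(), "fiber")
  rows[, trace] <- 1
  db <- food_database(rows)
  rv <- setNames(rep(1e-6, 9), qualifying_nutrients())
  rv["fiber"] <- 25
  ref <- nutrient_reference(rv, setNames(rep(1000, 3), limiting_nutrients()),
                            energy_target = 1000)
  analytic <- function(eps) {
    q2 <- min(1000, (1000 * eps - 1000) / 3)
    # 8 trace nutrients are fully covered at any intake; fiber caps at 500 g
    800 + 100 * min(q2 / 500, 1)
  }
  pf <- pareto_front(db, ref, cost_levels = c(1.5, 2.5, 4),
                     nutritional_constraints = FALSE,
                     control = solver_control(seeds = 1:3))
  expect_equal(nrow(pf$points), 3)
  expect_equal(pf$points$nrd93, vapply(c(1.5, 2.5, 4), analytic, numeric(1)),
               tolerance = 1e-5)
  # relaxing the budget never worsens the attainable score
  expect_true(all(diff(pf$points$nrd93) >= -1e-9))
  # returned front is mutually non-dominated
  fr <- pf$front
  for (i in seq_len(nrow(fr))) {
    for (j in seq_len(nrow(fr))) {
      if (i == j) next
      dom <- fr$nrd93[j] >= fr$nrd93[i] + 1e-9 &&
        fr$cost[j] <= fr$cost[i] + 1e-9 && fr$ghg[j] <= fr$ghg[i] + 1e-9
      expect_false(dom)
    }
  }
})
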