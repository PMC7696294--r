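test_that("NRD9.3 hits its bounds and caps qualifying surpluses", {
  ref <- unit_ref()
  full <- intake_from_ratios(rq = rep(1, 9), rl = rep(0, 3))
  expect_equal(compute_nrd93(full, ref)$nrd93, 900)
  zero <- intake_from_ratios(rq = rep(0, 9), rl = rep(0, 3))
  expect_equal(compute_nrd93(zero, ref)$nrd93, 0)
  over <- intake_from_ratios(rq = rep(1.5, 9), rl = rep(0.5, 3))
  s <- compute_nrd93(over, ref)
  expect_equal(s$tnr9, 900)   # surpluses earn nothing
  expect_equal(s$tnl3, 150)   # limiting ratios are NOT capped
  expect_equal(s$nrd93, 750)
  # invariance: raising an already-covered qualifying nutrient changes nothing
  more <- intake_from_ratios(rq = c(5, rep(1.5, 8)), rl = rep(0.5, 3))
  expect_equal(compute_nrd93(more, ref)$nrd93, s$nrd93)
  # monotonicity: any extra limiting intake strictly lowers the score
  worse <- intake_from_ratios(rq = rep(1.5, 9), rl = c(0.6, 0.5, 0.5))
  expect_lt(compute_nrd93(worse, ref)$nrd93, s$nrd93)
})

test_that("weight constraints are validated with a pointer to the failure", {
  expect_error(nutrient_weights(rep(1.1, 9), rep(1, 3)), "sum to 9")
  kr <- c(5.8, rep(0.4, 8))  # sums to 9 but breaches the 0.5 floor
  expect_error(nutrient_weights(kr, rep(1, 3)), "floor 0.5")
  expect_error(nutrient_weights(rep(1, 9), c(2, 0.9, 0.2)), "sum to 3")
  expect_error(nutrient_weights(rep(1, 9), c(2.7, 0.2, 0.1)), "floor 0.2")
})

test_that("weighted score reduces to NRD9.3 under uniform weights", {
  ref <- toy_ref()
  db <- toy_db()
  intake <- compute_intake(diet(c(bread = 250, milk = 400, lentils = 180)), db)
  expect_equal(compute_nrd93_weighted(intake, ref, uniform_nutrient_weights()),
               compute_nrd93(intake, ref)$nrd93, tolerance = 1e-12)
})

test_that("weighted score equals an explicit dot-product oracle", {
  ref <- unit_ref()
  intake <- intake_from_ratios(rq = rep(0.5, 9), rl = rep(0.5, 3))
  kr <- c(4.5, rep(0.5625, 8))  # sums to 9, floor respected
  km <- rep(1, 3)
  w <- nutrient_weights(kr, km)
  oracle <- 0
  for (i in 1:9) oracle <- oracle + kr[i] * 0.5 * 100
  for (i in 1:3) oracle <- oracle - km[i] * 0.5 * 100
  expect_equal(compute_nrd93_weighted(intake, ref, w), oracle,
               tolerance = 1e-12)
  # full coverage and zero limiting: any feasible kr gives exactly 900
  full <- intake_from_ratios(rq = rep(1.2, 9), rl = rep(0, 3))
  expect_equal(compute_nrd93_weighted(full, ref, w), 900, tolerance = 1e-12)
})

test_that("extremal weighted scores match vertex enumeration", {
  ref <- unit_ref()
  # one qualifying nutrient at 0, rest at 1, limiting at 0
  intake <- intake_from_ratios(rq = c(0, rep(1, 8)), rl = rep(0, 3))
  ext <- extremal_weighted_scores(intake, ref)
  expect_equal(ext$min, 400)  # slack weight 5 on the uncovered nutrient
  expect_equal(ext$max, 850)  # floor weight 0.5 on it
  # symmetric intakes: extremes collapse onto the uniform score
  sym <- intake_from_ratios(rq = rep(0.7, 9), rl = rep(0.3, 3))
  exts <- extremal_weighted_scores(sym, ref)
  uni <- compute_nrd93(sym, ref)$nrd93
  expect_equal(exts$min, uni, tolerance = 1e-9)
  expect_equal(exts$max, uni, tolerance = 1e-9)
})

test_that("extremal scores agree with brute force and sandwich random intakes", {
  ref <- unit_ref()
  brute_force <- function(cq, rl) {
    best <- c(Inf, -Inf)
    for (i in 1:9) {
      kr <- rep(0.5, 9); kr[i] <- 5
      for (j in 1:3) {
        km <- rep(0.2, 3); km[j] <- 2.6
        s <- 100 * (sum(kr * cq) - sum(km * rl))
        best[1] <- min(best[1], s)
        best[2] <- max(best[2], s)
      }
    }
    best
  }
  set.seed(42)
  for (rep_i in 1:100) {
    rq <- runif(9, 0, 1.6)
    rl <- runif(3, 0, 1.4)
    intake <- intake_from_ratios(rq, rl)
    ext <- extremal_weighted_scores(intake, ref)
    bf <- brute_force(pmin(rq, 1), rl)
    expect_equal(ext$min, bf[1], tolerance = 1e-9)
    expect_equal(ext$max, bf[2], tolerance = 1e-9)
    uni <- compute_nrd93(intake, ref)$nrd93
    expect_lte(ext$min, uni + 1e-9)
    expect_gte(ext$max, uni - 1e-9)
  }
})
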