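# toy optimization problem used by several blocks: 3 products, adequacy
# driven by protein/Ca, small TV band around a feasible baseline
toy_problem <- function() {
  rows <- rbind(
    product_row("a", "grains", energy = 2, price = 1, ghg = 1,
                protein = 0.10, Ca = 0.1),
    product_row("b", "dairy", energy = 1, price = 3, ghg = 4,
                protein = 0.05, Ca = 1.0),
    product_row("c", "oils", energy = 4, price = 2, ghg = 2,
                protein = 0.02, Ca = 0.2))
  trace <- setdiff(qualifying_nutrients(), c("protein", "Ca"))
  rows[, trace] <- 1  # trace nutrients trivially covered by any intake
  db <- food_database(rows)
  rv <- setNames(rep(1e-6, 9), qualifying_nutrients())
  rv["protein"] <- 60
  rv["Ca"] <- 500
  ref <- nutrient_reference(rv = rv,
                            mv = setNames(rep(1000, 3), limiting_nutrients()),
                            energy_target = 2228)
  baseline <- diet(c(a = 500, b = 600, c = 157), name = "toy")
  # energy: 1000 + 600 + 628 = 2228 exactly
  ctx <- build_normalization(score_table(list(baseline), db, ref))
  list(db = db, ref = ref, baseline = baseline, ctx = ctx)
}

# independent oracle: scan a 1-gram grid over (Qa, Qb), solve Qc from the
# energy equality, keep feasible points, and take the best exact distance
grid_oracle <- function(p, tv) {
  qb0 <- p$baseline$quantities
  lb <- qb0 * (1 - tv / 100)
  ub <- qb0 * (1 + tv / 100)
  qa <- seq(ceiling(lb["a"]), floor(ub["a"]), by = 1)
  qb <- seq(ceiling(lb["b"]), floor(ub["b"]), by = 1)
  g <- expand.grid(a = qa, b = qb)
  g$c <- (2228 - 2 * g$a - 1 * g$b) / 4
  ok <- g$c >= lb["c"] & g$c <= ub["c"]
  g <- g[ok, ]
  protein <- 0.10 * g$a + 0.05 * g$b + 0.02 * g$c
  ca <- 0.1 * g$a + 1.0 * g$b + 0.2 * g$c
  feas <- protein >= 60 & ca >= 500
  g <- g[feas, ]
  dn <- vapply(seq_len(nrow(g)), function(i) {
    d <- diet(c(a = g$a[i], b = g$b[i], c = g$c[i]))
    sv <- normalize_scores(
      compute_nrd93(compute_intake(d, p$db), p$ref)$nrd93,
      total_cost(d, p$db), total_ghg(d, p$db), p$ctx)
    normalized_distance(sv)
  }, numeric(1))
  min(dn)
}
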