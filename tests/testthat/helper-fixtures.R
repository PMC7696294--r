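# Shared in-code fixtures: tiny food databases and references with known
# arithmetic, built fresh for every test run.

all_codes <- function() c(qualifying_nutrients(), limiting_nutrients())

# a product row as a one-row data.frame; nutrient densities default to zero
product_row <- function(id, category = "grains", energy = 1, price = 1,
                        ghg = 1, ...) {
  dens <- setNames(rep(0, 12), all_codes())
  extra <- unlist(list(...))
  dens[names(extra)] <- extra
  cbind(data.frame(id = id, name = id, category = category,
                   energy_kcal_per_g = energy, stringsAsFactors = FALSE),
        as.data.frame(as.list(dens)),
        data.frame(price_eur_per_kg = price, ghg_kgco2e_per_kg = ghg))
}

# 3-product toy database with hand-checkable numbers
toy_db <- function() {
  food_database(rbind(
    product_row("bread", "grains", energy = 2.5, price = 1.5, ghg = 0.8,
                protein = 0.09, fiber = 0.05, Fe = 0.02, Mg = 0.6, K = 2,
                Ca = 0.2, vitE = 0.004, satfat = 0.005, Na = 3),
    product_row("milk", "dairy", energy = 0.6, price = 1.0, ghg = 1.6,
                protein = 0.034, Ca = 1.2, Mg = 0.11, K = 1.5, vitA = 0.4,
                satfat = 0.02, Na = 0.5),
    product_row("lentils", "legumes", energy = 3.3, price = 2.0, ghg = 0.9,
                protein = 0.24, fiber = 0.15, Ca = 1.0, Fe = 0.07, Mg = 1.2,
                K = 9, vitA = 0.05, vitC = 0.04, vitE = 0.01,
                satfat = 0.002, Na = 0.05)))
}

# reference with modest demands so the toy diets are near-adequate
toy_ref <- function() {
  nutrient_reference(
    rv = setNames(c(50, 25, 800, 14, 375, 3500, 800, 80, 12),
                  qualifying_nutrients()),
    mv = setNames(c(24.8, 55.7, 2000), limiting_nutrients()),
    energy_target = 2228)
}

# uniform-nutrient reference where every ratio is trivial to read off
unit_ref <- function(energy_target = 2000) {
  nutrient_reference(
    rv = setNames(rep(100, 9), qualifying_nutrients()),
    mv = setNames(rep(100, 3), limiting_nutrients()),
    energy_target = energy_target)
}

# intake with chosen relative ratios under unit_ref (RV = MV = 100)
intake_from_ratios <- function(rq, rl, energy = 2000) {
  nutrient_intake(setNames(c(rq * 100, rl * 100), all_codes()),
                  energy = energy)
}

# fixture for the minimal-margin search: deficient only in Ca, and the
# calcium-rich product must grow by exactly 30% to close the gap
margin_fixture <- function() {
  staple <- product_row("staple", "grains", energy = 1, price = 1, ghg = 1)
  carich <- product_row("ca_rich", "dairy", energy = 1, price = 1, ghg = 1,
                        Ca = 1)
  for (nc in qualifying_nutrients()) {
    if (nc != "Ca") staple[[nc]] <- 1
  }
  db <- food_database(rbind(staple, carich))
  rv <- setNames(rep(100, 9), qualifying_nutrients())
  rv["Ca"] <- 650
  ref <- nutrient_reference(
    rv = rv, mv = setNames(rep(1000, 3), limiting_nutrients()),
    energy_target = 2000)
  # baseline: staple 1500 g + ca_rich 500 g -> energy 2000, Ca 500 < 650
  list(db = db, ref = ref,
       baseline = diet(c(staple = 1500, ca_rich = 500), name = "toy"))
}

rv_ca_fixture_check <- function(f) {
  # sanity: Ca is the only deficit at baseline
  ri <- relative_intakes(compute_intake(f$baseline, f$db), f$ref)
  stopifnot(sum(ri$qualifying < 1) == 1, names(which(ri$qualifying < 1)) == "Ca")
}

# random feasible objective-weight triplet (floor-respecting)
random_objective_weights <- function(floor = 0.2) {
  d <- rgamma(3, 1)
  k <- floor + (3 - 3 * floor) * d / sum(d)
  objective_weights(k[1], k[2], k[3], floor = floor)
}
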