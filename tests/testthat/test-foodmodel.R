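test_that("food database round-trips losslessly through CSV and JSON", {
  db <- generate_synthetic_database(9, seed = 7)
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_food_database(db, path)
    back <- read_food_database(path)
    expect_equal(as.data.frame(back), as.data.frame(db), tolerance = 1e-12)
  }
})

test_that("database validation names the missing column and the bad product", {
  df <- as.data.frame(toy_db())
  expect_error(food_database(df[, setdiff(names(df), "ghg_kgco2e_per_kg")]),
               "ghg_kgco2e_per_kg")
  bad <- df
  bad$price_eur_per_kg[2] <- -1
  expect_error(food_database(bad), "milk")
  dup <- rbind(df, df[1, ])
  expect_error(food_database(dup), "bread")
})

test_that("diet files round-trip and validate", {
  diets <- list(a = diet(c(bread = 100, milk = 200), name = "a"),
                b = diet(c(lentils = 50), name = "b"))
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_diets(diets, path)
    back <- read_diets(path)
    expect_setequal(names(back), c("a", "b"))
    expect_equal(back$a$quantities[c("bread", "milk")],
                 diets$a$quantities)
  }
  expect_error(diet(c(bread = -1)), "negative")
  expect_error(compute_intake(diet(c(nope = 10)), toy_db()), "nope")
})

test_that("compute_intake matches an independent hand summation", {
  db <- toy_db()
  q <- c(bread = 120, milk = 350, lentils = 80)
  got <- compute_intake(diet(q), db)
  dfd <- as.data.frame(db)
  rownames(dfd) <- dfd$id
  manual_energy <- 0
  manual <- setNames(rep(0, 12), nutrient_codes())
  for (p in names(q)) {
    manual_energy <- manual_energy + q[[p]] * dfd[p, "energy_kcal_per_g"]
    for (nc in nutrient_codes()) {
      manual[nc] <- manual[nc] + q[[p]] * dfd[p, nc]
    }
  }
  expect_equal(got$energy, manual_energy, tolerance = 1e-12)
  expect_equal(got$intake, manual, tolerance = 1e-12)
})

test_that("compute_intake is additive and zero on the empty diet", {
  db <- toy_db()
  zero <- compute_intake(diet(c(bread = 0, milk = 0, lentils = 0)), db)
  expect_equal(zero$energy, 0)
  expect_true(all(zero$intake == 0))
  one <- compute_intake(diet(c(bread = 100)), db)
  expect_equal(one$energy, 250)  # 100 g at 2.5 kcal/g
  d1 <- c(bread = 10, milk = 40, lentils = 5)
  d2 <- c(bread = 70, milk = 0, lentils = 55)
  i1 <- compute_intake(diet(d1), db)
  i2 <- compute_intake(diet(d2), db)
  i12 <- compute_intake(diet(d1 + d2), db)
  expect_equal(i12$intake, i1$intake + i2$intake, tolerance = 1e-12)
  expect_equal(i12$energy, i1$energy + i2$energy, tolerance = 1e-12)
})

test_that("synthetic generation is seed-deterministic and category-structured", {
  a <- generate_synthetic_database(63, seed = 1)
  b <- generate_synthetic_database(63, seed = 1)
  expect_identical(a, b)
  c <- generate_synthetic_database(63, seed = 2)
  expect_false(identical(a, c))
  expect_gte(length(unique(a$category)), 8)
  med <- tapply(a$ghg_kgco2e_per_kg, a$category, median)
  expect_gt(med[["red_meat"]], med[["vegetables"]])
  expect_gt(median(a$fiber[a$category == "legumes"]),
            median(a$fiber[a$category == "red_meat"]))
  expect_gt(median(a$Ca[a$category == "dairy"]), median(a$Ca))
  expect_gt(min(a$energy_kcal_per_g[a$category == "oils"]),
            max(a$energy_kcal_per_g[a$category != "oils"]))
  expect_error(generate_synthetic_database(2, seed = 1), ">= 3")
})

test_that("baseline diets hit the energy target and respect their pattern", {
  db <- generate_synthetic_database(63, seed = 1)
  ref <- default_nutrient_reference()
  diets <- generate_baseline_diets(db, ref, seed = 1)
  expect_gte(length(diets), 2)
  for (d in diets) {
    expect_equal(compute_intake(d, db)$energy, 2228, tolerance = 1e-6)
  }
  again <- generate_baseline_diets(db, ref, seed = 1)
  expect_identical(diets, again)
  omni <- diets$omnivorous
  plant <- diets$plant_based
  red_ids <- db$id[db$category == "red_meat"]
  animal_ids <- db$id[db$category %in% animal_categories()]
  expect_gt(sum(omni$quantities[red_ids]), 0)
  expect_equal(unname(sum(plant$quantities[animal_ids])), 0)
  zero_db <- as.data.frame(db)
  zero_db$energy_kcal_per_g <- 0
  expect_error(generate_baseline_diets(food_database(zero_db), ref, seed = 1),
               "infeasible")
})
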