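db_required_columns <- function() {
  c("id", "name", "category", "energy_kcal_per_g", nutrient_codes(),
    "price_eur_per_kg", "ghg_kgco2e_per_kg")
}

db_numeric_columns <- function() {
  c("energy_kcal_per_g", nutrient_codes(), "price_eur_per_kg",
    "ghg_kgco2e_per_kg")
}

#' Construct and validate a food database
#'
#' A food database is a data frame with one row per food product carrying
#' per-gram energy and nutrient densities, the retail price in EUR per kg
#' and the cradle-to-consumption greenhouse-gas intensity in kg CO2eq per
#' kg. Nutrient columns follow [nutrient_codes()]: amounts per gram of
#' product, in the same units as the daily reference (g, mg or ug).
#'
#' @param products Data frame with columns `id`, `name`, `category`,
#'   `energy_kcal_per_g`, one column per nutrient code,
#'   `price_eur_per_kg`, `ghg_kgco2e_per_kg`.
#' @return The validated data frame with class `food_database`.
#' @export
food_database <- function(products) {
  products <- as.data.frame(products, stringsAsFactors = FALSE)
  missing <- setdiff(db_required_columns(), names(products))
  if (length(missing)) {
    stop("food database misses column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(products) == 0) stop("food database must contain at least one product")
  products$id <- as.character(products$id)
  if (anyDuplicated(products$id)) {
    stop("duplicated product id(s): ",
         paste(unique(products$id[duplicated(products$id)]), collapse = ", "))
  }
  for (col in db_numeric_columns()) {
    v <- products[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("column '", col, "' must be numeric without missing values")
    }
    if (any(v < 0)) {
      bad <- products$id[v < 0]
      stop("negative value in column '", col, "' for product(s): ",
           paste(bad, collapse = ", "))
    }
  }
  products <- products[, db_required_columns()]
  class(products) <- c("food_database", "data.frame")
  products
}

#' Read a food database from CSV or JSON
#'
#' @param path Path to the file. CSV files are UTF-8 with a header row and
#'   `.` as decimal mark; JSON files mirror the same columns as an array of
#'   records.
#' @param format `"csv"` or `"json"`; guessed from the file extension by
#'   default.
#' @return A `food_database`.
#' @seealso [write_food_database()]
#' @export
read_food_database <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("food database file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  raw <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8"),
    json = as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                         stringsAsFactors = FALSE))
  food_database(raw)
}

#' Write a food database to CSV or JSON
#'
#' @param db A `food_database`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_food_database <- function(db, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  db <- food_database(db)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  switch(format,
    csv = utils::write.csv(as.data.frame(db), path, row.names = FALSE,
                           fileEncoding = "UTF-8"),
    json = jsonlite::write_json(as.data.frame(db), path, digits = NA,
                                auto_unbox = FALSE))
  invisible(path)
}

#' Construct a diet (daily intake quantities over a food database)
#'
#' @param quantities Named numeric vector: grams per day of each product id.
#'   All values must be non-negative.
#' @param name Diet name (used in tables and reports).
#' @return An object of class `diet` with fields `name` and `quantities`.
#' @export
diet <- function(quantities, name = "diet") {
  quantities <- unlist(quantities)
  if (is.null(names(quantities)) || any(!nzchar(names(quantities)))) {
    stop("`quantities` must be named by product id")
  }
  if (anyDuplicated(names(quantities))) stop("duplicated product id in diet")
  if (!is.numeric(quantities) || anyNA(quantities)) {
    stop("`quantities` must be numeric without missing values")
  }
  if (any(quantities < 0)) {
    stop("negative intake for product(s): ",
         paste(names(quantities)[quantities < 0], collapse = ", "))
  }
  structure(list(name = as.character(name), quantities = quantities),
            class = "diet")
}

#' @export
print.diet <- function(x, ...) {
  cat("Diet '", x$name, "': ", sum(x$quantities > 0), " products, ",
      round(sum(x$quantities)), " g/day total\n", sep = "")
  invisible(x)
}

# match diet quantities onto database rows; error on unknown ids
diet_index <- function(diet, db) {
  idx <- match(names(diet$quantities), db$id)
  if (anyNA(idx)) {
    stop("diet '", diet$name, "' references unknown product id(s): ",
         paste(names(diet$quantities)[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Read and write diets (long CSV or JSON)
#'
#' The CSV layout has columns `diet`, `product_id`, `grams_per_day`; the
#' JSON layout is a map from diet name to a map of product id to grams per
#' day.
#'
#' @param path File path (`.csv` or `.json`).
#' @return `read_diets()` returns a named list of `diet` objects.
#' @export
read_diets <- function(path) {
  if (!file.exists(path)) stop("diet file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    diets <- lapply(names(lst), function(nm) diet(unlist(lst[[nm]]), name = nm))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    need <- c("diet", "product_id", "grams_per_day")
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      stop("diet file misses column(s): ", paste(missing, collapse = ", "))
    }
    if (nrow(df) == 0) stop("diet file contains no rows")
    diets <- lapply(split(df, df$diet), function(d) {
      diet(stats::setNames(d$grams_per_day, d$product_id), name = d$diet[1])
    })
  }
  stats::setNames(diets, vapply(diets, function(d) d$name, character(1)))
}

#' @param diets A list of `diet` objects (or a single `diet`).
#' @rdname read_diets
#' @export
write_diets <- function(diets, path) {
  if (inherits(diets, "diet")) diets <- list(diets)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- lapply(diets, function(d) as.list(d$quantities))
    names(lst) <- vapply(diets, function(d) d$name, character(1))
    jsonlite::write_json(lst, path, digits = NA, auto_unbox = TRUE)
  } else {
    df <- do.call(rbind, lapply(diets, function(d) {
      data.frame(diet = d$name, product_id = names(d$quantities),
                 grams_per_day = unname(d$quantities),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Daily nutrient intake of a diet
#'
#' Aggregates a diet over a food database: energy is the quantity-weighted
#' sum of energy densities, and each nutrient intake the quantity-weighted
#' sum of that nutrient's densities. Both are linear in the quantities.
#'
#' @param diet A `diet`.
#' @param db A `food_database` containing every product in the diet.
#' @return An object of class `nutrient_intake`: list with `intake` (named
#'   vector over [nutrient_codes()], daily amounts) and `energy` (kcal/day).
#' @export
compute_intake <- function(diet, db) {
  db <- food_database(db)
  idx <- diet_index(diet, db)
  q <- diet$quantities
  nut <- as.matrix(as.data.frame(db)[idx, nutrient_codes(), drop = FALSE])
  intake <- as.numeric(crossprod(nut, q))
  names(intake) <- nutrient_codes()
  nutrient_intake(intake, energy = sum(q * db$energy_kcal_per_g[idx]))
}

#' @param intake Named numeric vector of daily amounts over all twelve
#'   nutrient codes.
#' @param energy Daily energy in kcal.
#' @rdname compute_intake
#' @export
nutrient_intake <- function(intake, energy) {
  intake <- unlist(intake)[nutrient_codes()]
  if (anyNA(intake)) stop("`intake` must cover all 12 nutrient codes")
  if (any(intake < 0) || energy < 0) stop("intakes and energy must be >= 0")
  structure(list(intake = intake, energy = as.numeric(energy)),
            class = "nutrient_intake")
}

#' @export
print.nutrient_intake <- function(x, ...) {
  cat("Daily intake:", round(x$energy, 1), "kcal\n")
  print(round(x$intake, 2))
  invisible(x)
}
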