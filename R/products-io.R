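#' @importFrom rlang .data
NULL

# Canonical product-table schema. Nutrients are per stated serving.
product_columns <- function() {
  c(product_id = "c", brand = "c", name = "c", category_code = "c",
    source = "c", is_main_dish = "l", store_id = "c",
    serving_size = "d", serving_unit = "c", basis_state = "c",
    energy_kcal = "d", sodium_mg = "d", sugars_g = "d", satfat_g = "d",
    transfat_g = "d", totalfat_g = "d", carb_g = "d", protein_g = "d",
    ingredients_text = "c", flag_sodium = "c", flag_sugars = "c",
    flag_fat = "c")
}

nutrient_columns <- function() {
  c("energy_kcal", "sodium_mg", "sugars_g", "satfat_g", "transfat_g",
    "totalfat_g", "carb_g", "protein_g")
}

#' Read a product table
#'
#' Reads a delimited product table (comma-separated, UTF-8, header row)
#' into the canonical product tibble used by the whole pipeline. One row
#' is one product or menu item with its per-serving nutrient declaration.
#' Empty nutrient cells become explicit `NA` values, never zero. Rows that
#' violate basic invariants (negative nutrient amount, non-positive
#' serving size, empty brand or name) are skipped and reported via the
#' `row_errors` attribute and a warning.
#'
#' Expected columns (extra columns are dropped with a message): see
#' [product_template()]. If the file carries `energy_kj` instead of
#' `energy_kcal`, energy is converted to kcal (divided by 4.184) on read.
#'
#' @param path Path to a CSV file.
#' @return A tibble of products with attribute `row_errors` (a tibble of
#'   skipped rows with reasons; zero rows when the file is fully valid).
#' @seealso [write_products()], [validate_products()]
#' @export
read_products <- function(path) {
  if (!file.exists(path)) {
    stop("product file not found: ", path, call. = FALSE)
  }
  spec <- product_columns()
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  if ("energy_kj" %in% names(raw) && !"energy_kcal" %in% names(raw)) {
    raw$energy_kcal <- raw$energy_kj / 4.184
    raw$energy_kj <- NULL
  }
  required <- c("product_id", "brand", "name", "category_code", "source",
                "serving_size", "serving_unit", "energy_kcal", "sodium_mg",
                "sugars_g", "satfat_g")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("product file is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(names(spec), names(raw))) {
    raw[[col]] <- if (spec[[col]] == "d") NA_real_
                  else if (spec[[col]] == "l") NA else NA_character_
  }
  raw <- raw[names(spec)]
  for (col in names(spec)) {
    raw[[col]] <- switch(spec[[col]],
                         d = as.numeric(raw[[col]]),
                         l = as.logical(raw[[col]]),
                         c = as.character(raw[[col]]))
  }
  raw$is_main_dish[is.na(raw$is_main_dish)] <- FALSE
  raw$basis_state[is.na(raw$basis_state)] <- "as_sold"
  validate_products(tibble::as_tibble(raw))
}

#' Write a product table
#'
#' Writes products in the same delimited format [read_products()] accepts,
#' so that write-then-read is an identity (including missing-value
#' markers, stored as empty cells).
#'
#' @param products Product tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_products <- function(products, path) {
  readr::write_csv(products, path, na = "")
  invisible(path)
}

#' Empty product table template
#'
#' Returns a zero-row tibble with the canonical product columns and types,
#' documenting the input schema.
#' @return A zero-row tibble.
#' @export
product_template <- function() {
  spec <- product_columns()
  cols <- lapply(spec, function(t) switch(t, d = numeric(), l = logical(),
                                          c = character()))
  tibble::as_tibble(cols)
}

#' Validate a product table and drop invalid rows
#'
#' Applies row-level invariants: nutrient amounts must be non-negative
#' when present, serving size positive, brand and name non-empty,
#' saturated and trans fat no greater than total fat when all are
#' present, and `source` one of `"packaged"`/`"restaurant"`. Offending
#' rows are removed and collected in the `row_errors` attribute.
#'
#' @param products Product tibble.
#' @return The valid rows, with attribute `row_errors`.
#' @export
validate_products <- function(products) {
  n <- nrow(products)
  reason <- character(n)
  flag <- function(bad, msg) {
    bad <- which(bad & !nzchar(reason))
    reason[bad] <<- msg
  }
  trimmed <- function(x) !is.na(x) & nzchar(trimws(x))
  flag(!trimmed(products$brand) | !trimmed(products$name),
       "empty brand or name")
  flag(is.na(products$serving_size) | products$serving_size <= 0,
       "non-positive or missing serving size")
  for (col in nutrient_columns()) {
    flag(!is.na(products[[col]]) & products[[col]] < 0,
         paste0("negative ", col))
  }
  sat_tot <- !is.na(products$satfat_g) & !is.na(products$totalfat_g) &
    products$satfat_g > products$totalfat_g + 1e-9
  trans_tot <- !is.na(products$transfat_g) & !is.na(products$totalfat_g) &
    products$transfat_g > products$totalfat_g + 1e-9
  flag(sat_tot, "saturated fat exceeds total fat")
  flag(trans_tot, "trans fat exceeds total fat")
  flag(!products$source %in% c("packaged", "restaurant"),
       "source must be 'packaged' or 'restaurant'")
  bad <- nzchar(reason)
  errors <- tibble::tibble(product_id = products$product_id[bad],
                           row = which(bad), reason = reason[bad])
  if (nrow(errors)) {
    warning(sprintf("%d invalid product row(s) skipped (see attr(, 'row_errors'))",
                    nrow(errors)), call. = FALSE)
  }
  out <- products[!bad, , drop = FALSE]
  attr(out, "row_errors") <- errors
  out
}

exclusion_entry <- function(product_id, reason, detail) {
  tibble::tibble(product_id = as.character(product_id),
                 reason = as.character(reason),
                 detail = as.character(detail))
}

#' Collapse duplicate store listings
#'
#' The same product collected from multiple stores is analysed only once:
#' rows identical on the deduplication key (brand, name, serving size,
#' category code; case-insensitive, whitespace-normalised) collapse to the
#' first occurrence in input order. Different package sizes, flavours and
#' varieties have different names or serving sizes and are all kept.
#'
#' @param products Product tibble.
#' @return A list with `products` (kept rows, input order preserved) and
#'   `exclusions` (one `duplicate` entry per dropped row).
#' @export
deduplicate_products <- function(products) {
  if (nrow(products) == 0) {
    return(list(products = products,
                exclusions = exclusion_entry(character(), character(), character())))
  }
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  key <- paste(norm(products$brand), norm(products$name),
               format(products$serving_size, digits = 15),
               norm(products$category_code), sep = "\r")
  dup <- duplicated(key)
  exclusions <- exclusion_entry(
    products$product_id[dup], "duplicate",
    paste0("duplicate of first listing of '", products$name[dup],
           "' (", products$brand[dup], ")"))
  list(products = products[!dup, , drop = FALSE], exclusions = exclusions)
}

#' Atwater energy plausibility check
#'
#' Computes energy from the declared macronutrients with the general
#' Atwater factors (4 kcal/g protein, 4 kcal/g carbohydrate, 9 kcal/g
#' fat) and compares it with the declared energy. The declaration passes
#' when the absolute difference is within `tolerance` of the larger of
#' the two energies, or when both are below 5 kcal (where relative error
#' is meaningless). Rows missing any required macronutrient or the
#' declared energy are `"not_assessable"`, distinct from `"fail"`.
#'
#' @param protein,carbohydrate,fat Grams per serving (vectors recycle).
#' @param energy Declared energy in kcal per serving.
#' @param tolerance Relative tolerance (default 0.20).
#' @return A tibble with `verdict` (`"pass"`, `"fail"`,
#'   `"not_assessable"`) and `computed_kcal`.
#' @examples
#' atwater_check(2, 27, 1, 125)           # computed 125 kcal, pass
#' atwater_check(10, 10, 10, 500)         # computed 170 kcal, fail
#' @export
atwater_check <- function(protein, carbohydrate, fat, energy,
                          tolerance = 0.20) {
  computed <- 4 * protein + 4 * carbohydrate + 9 * fat
  assessable <- !is.na(protein) & !is.na(carbohydrate) & !is.na(fat) &
    !is.na(energy)
  diff_ok <- abs(computed - energy) <= tolerance * pmax(energy, computed)
  both_small <- energy < 5 & computed < 5
  verdict <- ifelse(!assessable, "not_assessable",
                    ifelse(diff_ok | both_small, "pass", "fail"))
  tibble::tibble(verdict = verdict, computed_kcal = computed)
}

#' Exclude products with implausible energy declarations
#'
#' Applies [atwater_check()] across a product table and excludes failing
#' rows (reason `atwater_fail`). Not-assessable rows are kept: only a
#' demonstrated mismatch is treated as inaccurate nutrition information.
#'
#' @param products Product tibble.
#' @param params [npm_params()] (uses `atwater_tolerance`).
#' @return A list with `products` and `exclusions`.
#' @export
filter_atwater <- function(products, params = npm_params()) {
  params <- as_npm_params(params)
  chk <- atwater_check(products$protein_g, products$carb_g,
                       products$totalfat_g, products$energy_kcal,
                       params$atwater_tolerance)
  bad <- chk$verdict == "fail"
  exclusions <- exclusion_entry(
    products$product_id[bad], "atwater_fail",
    sprintf("declared %.1f kcal vs computed %.1f kcal",
            products$energy_kcal[bad], chk$computed_kcal[bad]))
  list(products = products[!bad, , drop = FALSE], exclusions = exclusions)
}

#' Exclude products missing sugars or saturated fat
#'
#' Total sugars and saturated fat are required to apply the nutrient
#' profile model; rows missing either are excluded (missing sugars is the
#' primary reason when both are absent). Other missing fields do not
#' exclude — in particular a missing trans fat value is handled
#' downstream as 0 g with a warning.
#'
#' @param products Product tibble.
#' @return A list with `products` and `exclusions` (reasons
#'   `missing_sugars` / `missing_satfat`).
#' @export
filter_missing <- function(products) {
  miss_sugars <- is.na(products$sugars_g)
  miss_satfat <- is.na(products$satfat_g) & !miss_sugars
  exclusions <- dplyr::bind_rows(
    exclusion_entry(products$product_id[miss_sugars], "missing_sugars",
                    "total sugars not declared"),
    exclusion_entry(products$product_id[miss_satfat], "missing_satfat",
                    "saturated fat not declared"))
  keep <- !(miss_sugars | miss_satfat)
  list(products = products[keep, , drop = FALSE], exclusions = exclusions)
}

#' Run all cleaning steps
#'
#' Deduplicates store listings, excludes Atwater-implausible
#' declarations, then excludes rows missing sugars or saturated fat.
#' Every input row ends up in exactly one of the cleaned table or the
#' exclusion log, each excluded row with exactly one primary reason.
#'
#' @param products Product tibble.
#' @param params [npm_params()].
#' @return A list with `products`, `exclusions` (columns `product_id`,
#'   `reason`, `detail`) and `stage_counts` (named integer vector of row
#'   counts after each stage).
#' @export
clean_products <- function(products, params = npm_params()) {
  d <- deduplicate_products(products)
  a <- filter_atwater(d$products, params)
  m <- filter_missing(a$products)
  list(products = m$products,
       exclusions = dplyr::bind_rows(d$exclusions, a$exclusions, m$exclusions),
       stage_counts = c(input = nrow(products),
                        deduplicated = nrow(d$products),
                        atwater_checked = nrow(a$products),
                        complete = nrow(m$products)))
}

#' Write an exclusion log
#'
#' @param exclusions Exclusion tibble (`product_id`, `reason`, `detail`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exclusions <- function(exclusions, path) {
  readr::write_csv(exclusions, path, na = "")
  invisible(path)
}
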