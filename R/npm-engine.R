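#' Rescale a per-serving amount to the evaluation basis
#'
#' Nutrient declarations are per stated serving; thresholds apply at the
#' evaluation basis. Scaling is linear:
#' `amount_at_basis = amount_per_serving * basis / serving_size`.
#'
#' @param amount Amount per serving (any unit); vectorised.
#' @param serving_size Stated serving size in g or mL; must be positive.
#' @param basis Evaluation basis in g.
#' @return Amount at the basis, same unit as `amount`.
#' @examples
#' scale_to_basis(10, 100, 55)  # 5.5
#' @export
scale_to_basis <- function(amount, serving_size, basis) {
  if (any(is.na(serving_size)) || any(serving_size <= 0)) {
    stop("serving_size must be positive", call. = FALSE)
  }
  amount * basis / serving_size
}

# Threshold comparisons: exact arithmetic with a relative tolerance used
# only to absorb floating-point noise, never to soften a boundary.
exceeds_max <- function(amount, limit, rel_tol) amount > limit * (1 + rel_tol)
at_least <- function(value, limit, rel_tol) value >= limit * (1 - rel_tol)

#' Evaluate the sodium threshold
#'
#' A product is exempt from the sodium threshold unless it contains
#' added sodium. Non-exempt products exceed when sodium at the
#' evaluation basis is above 140 mg (compliant at exactly 140 mg: the
#' limit is inclusive).
#'
#' @param sodium_mg Sodium in mg per serving.
#' @param flag `"present"`/`"absent"` added-sodium flag.
#' @param serving_size,basis Serving size and evaluation basis in g.
#' @param params [npm_params()].
#' @return A tibble with `status` (`exempt`/`compliant`/`exceeds`) and
#'   `amount_at_basis` (mg; `NA` when exempt and sodium undeclared).
#' @export
evaluate_sodium <- function(sodium_mg, flag, serving_size, basis,
                            params = npm_params()) {
  params <- as_npm_params(params)
  assessed <- flag == "present"
  if (any(assessed & is.na(sodium_mg))) {
    stop("sodium is missing for a product with added sodium", call. = FALSE)
  }
  at_basis <- scale_to_basis(sodium_mg, serving_size, basis)
  status <- ifelse(!assessed, "exempt",
                   ifelse(exceeds_max(at_basis, params$sodium_max, params$rel_tol),
                          "exceeds", "compliant"))
  tibble::tibble(status = status, amount_at_basis = at_basis)
}

#' Evaluate the total sugars threshold
#'
#' A product is exempt from the sugars threshold unless it contains free
#' sugars (naturally occurring lactose or intrinsic fruit sugars do not
#' count). Non-exempt products exceed when total sugars at the basis are
#' above 5 g (compliant at exactly 5 g).
#'
#' @param sugars_g Total sugars in g per serving.
#' @inheritParams evaluate_sodium
#' @return A tibble with `status` and `amount_at_basis` (g).
#' @export
evaluate_sugars <- function(sugars_g, flag, serving_size, basis,
                            params = npm_params()) {
  params <- as_npm_params(params)
  assessed <- flag == "present"
  if (any(assessed & is.na(sugars_g))) {
    stop("total sugars is missing for a product with free sugars", call. = FALSE)
  }
  at_basis <- scale_to_basis(sugars_g, serving_size, basis)
  status <- ifelse(!assessed, "exempt",
                   ifelse(exceeds_max(at_basis, params$sugars_max, params$rel_tol),
                          "exceeds", "compliant"))
  tibble::tibble(status = status, amount_at_basis = at_basis)
}

#' Evaluate the saturated-fat threshold
#'
#' A product is exempt unless it contains added fat. Non-exempt products
#' are evaluated on combined saturated and trans fat against two
#' criteria: at most 2 g at the evaluation basis, and strictly less than
#' 15 % of energy (a product at exactly 15 % exceeds). The energy share
#' `9 kcal/g * (satfat + transfat) / energy * 100` is a per-serving
#' ratio and therefore invariant to the basis. Missing trans fat is
#' imputed as 0 g with a warning. A declaration of zero energy with
#' positive saturated + trans fat is implausible and an error; zero
#' energy with zero fat gives a 0 % share.
#'
#' @param satfat_g,transfat_g Saturated and trans fat in g per serving.
#' @param energy_kcal Energy in kcal per serving.
#' @inheritParams evaluate_sodium
#' @return A tibble with `status`, `amount_at_basis` (combined sat +
#'   trans fat, g) and `energy_pct` (% energy from sat + trans fat).
#' @export
evaluate_satfat <- function(satfat_g, transfat_g, energy_kcal, flag,
                            serving_size, basis, params = npm_params()) {
  params <- as_npm_params(params)
  assessed <- flag == "present"
  if (any(assessed & is.na(satfat_g))) {
    stop("saturated fat is missing for a product with added fat", call. = FALSE)
  }
  n_imputed <- sum(assessed & is.na(transfat_g))
  if (n_imputed > 0) {
    warning(sprintf("trans fat missing for %d assessed product(s); imputed as 0 g",
                    n_imputed), call. = FALSE)
  }
  transfat_g <- ifelse(is.na(transfat_g), 0, transfat_g)
  combined <- satfat_g + transfat_g
  if (any(assessed & is.na(energy_kcal))) {
    stop("energy is missing for a product with added fat", call. = FALSE)
  }
  if (any(assessed & energy_kcal == 0 & combined > 0)) {
    stop("implausible declaration: zero energy with positive saturated/trans fat",
         call. = FALSE)
  }
  at_basis <- scale_to_basis(combined, serving_size, basis)
  energy_pct <- ifelse(is.na(energy_kcal), NA_real_,
                       ifelse(energy_kcal == 0, 0,
                              9 * combined / energy_kcal * 100))
  over <- exceeds_max(at_basis, params$satfat_max, params$rel_tol) |
    at_least(energy_pct, params$satfat_energy_max, params$rel_tol)
  status <- ifelse(!assessed, "exempt", ifelse(over, "exceeds", "compliant"))
  tibble::tibble(status = status, amount_at_basis = at_basis,
                 energy_pct = energy_pct)
}

#' Classify products against the marketing-to-children thresholds
#'
#' The end-to-end per-product evaluation: resolves the added-ingredient
#' flags, looks up the reference amount, computes the evaluation basis,
#' evaluates each non-exempt nutrient independently against its
#' threshold, and assigns the overall status. A product exceeding one or
#' more thresholds is `restricted` from marketing to children; exempt
#' products (no added sodium, free sugars or added fat) and non-exempt
#' products within all thresholds are `permitted`.
#'
#' Expects cleaned products (see [clean_products()]); in particular
#' sugars and saturated fat must be present. Nutrient values are used at
#' their declared basis state: supply as-prepared values (tagged
#' `basis_state = "as_prepared"`) where applicable, e.g. for beverage
#' concentrates; the tag is carried through to the output. Restaurant
#' multi-component meals are expected pre-itemised, one record per
#' component.
#'
#' @param products Cleaned product tibble.
#' @param ra_table Reference-amount table.
#' @param lexicon Ingredient lexicon.
#' @param allow_list Exemption allow-list patterns.
#' @param params [npm_params()].
#' @return A tibble, one row per product: identity columns, the resolved
#'   flags, `basis_g` and `basis_rule`, per-nutrient status and amounts
#'   at basis, `satfat_energy_pct`, `n_exceeded` (0–3), `status`
#'   (`restricted`/`permitted`) and `fully_exempt`.
#' @export
classify_products <- function(products,
                              ra_table = default_reference_amounts(),
                              lexicon = default_lexicon(),
                              allow_list = default_allow_list(),
                              params = npm_params()) {
  params <- as_npm_params(params)
  if (nrow(products) == 0) {
    stop("no products to classify", call. = FALSE)
  }
  flags <- resolve_flags(products, lexicon, allow_list)
  ra <- lookup_reference_amount(products$category_code, ra_table)
  is_main <- ifelse(is.na(products$is_main_dish), ra$is_main_dish_default,
                    products$is_main_dish)
  basis <- compute_evaluation_basis(ra$reference_amount,
                                    products$serving_size, is_main, params)
  with_id <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop(conditionMessage(e), " [while classifying product(s) ",
           paste(utils::head(products$product_id, 3), collapse = ", "), " ...]",
           call. = FALSE)
    })
  }
  sodium <- with_id(evaluate_sodium(products$sodium_mg, flags$added_sodium,
                                    products$serving_size, basis$basis_g, params))
  sugars <- with_id(evaluate_sugars(products$sugars_g, flags$free_sugars,
                                    products$serving_size, basis$basis_g, params))
  satfat <- with_id(evaluate_satfat(products$satfat_g, products$transfat_g,
                                    products$energy_kcal, flags$added_fat,
                                    products$serving_size, basis$basis_g, params))
  n_exceeded <- (sodium$status == "exceeds") + (sugars$status == "exceeds") +
    (satfat$status == "exceeds")
  fully_exempt <- sodium$status == "exempt" & sugars$status == "exempt" &
    satfat$status == "exempt"
  tibble::tibble(
    product_id = products$product_id,
    brand = products$brand,
    name = products$name,
    category_code = products$category_code,
    group = ra$group,
    source = products$source,
    basis_state = products$basis_state,
    basis_g = basis$basis_g,
    basis_rule = basis$rule,
    added_sodium = flags$added_sodium,
    free_sugars = flags$free_sugars,
    added_fat = flags$added_fat,
    sodium_status = sodium$status,
    sugars_status = sugars$status,
    satfat_status = satfat$status,
    sodium_at_basis = sodium$amount_at_basis,
    sugars_at_basis = sugars$amount_at_basis,
    satfat_at_basis = satfat$amount_at_basis,
    satfat_energy_pct = satfat$energy_pct,
    n_exceeded = as.integer(n_exceeded),
    status = ifelse(n_exceeded >= 1, "restricted", "permitted"),
    fully_exempt = fully_exempt
  )
}

#' Write a classification table
#'
#' @param classifications Output of [classify_products()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(classifications, path) {
  readr::write_csv(classifications, path, na = "")
  invisible(path)
}
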