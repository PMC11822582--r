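#' Straight-line reference classification
#'
#' An independent, deliberately naive transcription of the
#' marketing-to-children rule text, written as one plain loop with no
#' shared code with [classify_products()]. It exists as a second route
#' to the same answer: the synthetic-data generator uses it to construct
#' ground truth (from the generator's known true flags, not from
#' ingredient text), and the test suite checks that the engine agrees
#' with it product by product.
#'
#' @param products Product tibble (cleaned; sugars and saturated fat
#'   present).
#' @param flags Tibble with `added_sodium`, `free_sugars`, `added_fat`
#'   (`present`/`absent`), one row per product, in product order.
#' @param ra_table Reference-amount table.
#' @param params [npm_params()].
#' @return A tibble with `product_id`, `basis_g`, the three per-nutrient
#'   statuses, `n_exceeded`, `status` and `fully_exempt`.
#' @export
oracle_classify <- function(products, flags,
                            ra_table = default_reference_amounts(),
                            params = npm_params()) {
  params <- as_npm_params(params)
  stopifnot(nrow(products) == nrow(flags))
  out <- vector("list", nrow(products))
  for (i in seq_len(nrow(products))) {
    p <- products[i, ]
    f <- flags[i, ]
    ra_row <- ra_table[ra_table$category_code == p$category_code, ]
    if (nrow(ra_row) != 1) stop("unknown category code: ", p$category_code)
    ra <- ra_row$reference_amount
    main <- if (is.na(p$is_main_dish)) ra_row$is_main_dish_default else p$is_main_dish

    # Evaluation basis: 30 g or less -> assessed based on 50 g; main
    # dishes with RA >= 200 g -> assessed at 100 g; otherwise the
    # greater of the reference amount and the stated serving size.
    if (ra <= 30) {
      basis <- 50
    } else if (main && ra >= 200) {
      basis <- 100
    } else {
      basis <- max(ra, p$serving_size)
    }

    # Sodium: <= 140 mg per basis, assessed only with added sodium.
    if (f$added_sodium != "present") {
      sodium <- "exempt"
    } else if (p$sodium_mg * basis / p$serving_size > 140 * (1 + 1e-9)) {
      sodium <- "exceeds"
    } else {
      sodium <- "compliant"
    }

    # Total sugars: <= 5 g per basis, assessed only with free sugars.
    if (f$free_sugars != "present") {
      sugars <- "exempt"
    } else if (p$sugars_g * basis / p$serving_size > 5 * (1 + 1e-9)) {
      sugars <- "exceeds"
    } else {
      sugars <- "compliant"
    }

    # Saturated + trans fat: <= 2 g per basis AND < 15 % of energy,
    # assessed only with added fat. Missing trans fat counts as 0.
    if (f$added_fat != "present") {
      satfat <- "exempt"
    } else {
      tr <- if (is.na(p$transfat_g)) 0 else p$transfat_g
      combined <- p$satfat_g + tr
      grams_over <- combined * basis / p$serving_size > 2 * (1 + 1e-9)
      pct <- if (p$energy_kcal == 0) 0 else 9 * combined / p$energy_kcal * 100
      pct_over <- pct >= 15 * (1 - 1e-9)
      satfat <- if (grams_over || pct_over) "exceeds" else "compliant"
    }

    n_ex <- sum(c(sodium, sugars, satfat) == "exceeds")
    out[[i]] <- tibble::tibble(
      product_id = p$product_id,
      basis_g = basis,
      sodium_status = sodium,
      sugars_status = sugars,
      satfat_status = satfat,
      n_exceeded = as.integer(n_ex),
      status = if (n_ex >= 1) "restricted" else "permitted",
      fully_exempt = sodium == "exempt" && sugars == "exempt" &&
        satfat == "exempt")
  }
  dplyr::bind_rows(out)
}
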