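#' Read a reference-amount table
#'
#' A reference amount (RA) is Health Canada's standard consumption
#' amount for a minor food category (Table of Reference Amounts), the
#' basis against which the marketing-to-children thresholds are applied.
#' The table is a CSV with columns `category_code`, `group`,
#' `reference_amount`, `unit` (g or mL), `is_main_dish_default` and an
#' optional free-text `description`. Millilitres are treated as
#' numerically equivalent to grams in basis arithmetic (density 1), as
#' the Table of Reference Amounts itself does for beverages.
#'
#' @param path CSV path; defaults to the table shipped with the package,
#'   which covers the in-scope minor categories (breakfast cereals C1 to
#'   C4, beverages B1 and J11, yogurts D12 and D15) and the restaurant
#'   menu classes (starter, entree, side, dessert, beverage). Values are
#'   editable package defaults, not a reproduction of the full Table of
#'   Reference Amounts.
#' @return A validated tibble.
#' @export
read_reference_amounts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_amounts.csv", package = "m2knpm",
                        mustWork = TRUE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("category_code", "group", "reference_amount", "unit",
                "is_main_dish_default")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("reference-amount table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(tab$reference_amount) | tab$reference_amount <= 0)) {
    stop("all reference amounts must be positive", call. = FALSE)
  }
  if (!all(tab$unit %in% c("g", "mL"))) {
    stop("reference-amount unit must be 'g' or 'mL'", call. = FALSE)
  }
  if (anyDuplicated(tab$category_code)) {
    stop("duplicate category codes in reference-amount table", call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' @rdname read_reference_amounts
#' @export
default_reference_amounts <- function() read_reference_amounts()

#' Look up reference amounts for category codes
#'
#' @param category_code Character vector of minor-category codes or
#'   restaurant menu classes.
#' @param ra_table Reference-amount table from
#'   [read_reference_amounts()].
#' @return A tibble with `category_code`, `group`, `reference_amount`,
#'   `unit`, `is_main_dish_default`, one row per input code. An unknown
#'   code is an error naming the code, never a silent default.
#' @export
lookup_reference_amount <- function(category_code, ra_table = default_reference_amounts()) {
  idx <- match(category_code, ra_table$category_code)
  if (anyNA(idx)) {
    stop("unknown category code(s): ",
         paste(unique(category_code[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  ra_table[idx, c("category_code", "group", "reference_amount", "unit",
                  "is_main_dish_default")]
}

#' Compute the evaluation basis
#'
#' The evaluation basis is the gram amount of food at which nutrient
#' amounts are compared to the thresholds. Exactly one rule fires per
#' product:
#' \itemize{
#'   \item `small_ra` — reference amount of 30 g or less: assessed at
#'     50 g (sauces, dips, condiments, puffed cereals).
#'   \item `main_dish` — main dishes with a reference amount of 200 g or
#'     more: assessed at 100 g (restaurant meals such as burgers and
#'     pizza).
#'   \item `standard_greater_of` — everything else: the greater of the
#'     reference amount and the stated serving size.
#' }
#' Main dishes with a reference amount below 200 g are not covered by
#' the main-dish rule and fall through to the standard greater-of rule.
#' All cutoffs come from `params` so variants of the model can be
#' explored.
#'
#' @param reference_amount Reference amount in g (mL treated as g);
#'   vectorised.
#' @param serving_size Stated serving size in g or mL; vectorised.
#' @param is_main_dish Logical; vectorised.
#' @param params [npm_params()].
#' @return A tibble with `basis_g` and `rule`
#'   (`small_ra`/`main_dish`/`standard_greater_of`).
#' @examples
#' compute_evaluation_basis(30, 40, FALSE)   # 50 g, small_ra
#' compute_evaluation_basis(55, 80, FALSE)   # 80 g, greater-of
#' compute_evaluation_basis(250, 300, TRUE)  # 100 g, main dish
#' @export
compute_evaluation_basis <- function(reference_amount, serving_size,
                                     is_main_dish, params = npm_params()) {
  params <- as_npm_params(params)
  if (anyNA(reference_amount) || anyNA(serving_size) ||
      any(reference_amount <= 0) || any(serving_size <= 0)) {
    stop("reference_amount and serving_size must be positive", call. = FALSE)
  }
  n <- max(length(reference_amount), length(serving_size), length(is_main_dish))
  reference_amount <- rep_len(reference_amount, n)
  serving_size <- rep_len(serving_size, n)
  is_main_dish <- rep_len(as.logical(is_main_dish), n)
  small <- reference_amount <= params$small_ra_cutoff
  main <- !small & is_main_dish & reference_amount >= params$main_dish_ra_cutoff
  basis <- ifelse(small, params$small_ra_basis,
                  ifelse(main, params$main_dish_basis,
                         pmax(reference_amount, serving_size)))
  rule <- ifelse(small, "small_ra",
                 ifelse(main, "main_dish", "standard_greater_of"))
  tibble::tibble(basis_g = basis, rule = rule)
}
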