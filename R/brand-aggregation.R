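round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

brand_summary_one <- function(cls) {
  n <- nrow(cls)
  n_restricted <- sum(cls$status == "restricted")
  n_exempt <- sum(cls$fully_exempt)
  n_permitted_nonexempt <- n - n_restricted - n_exempt
  n_by_exceeded <- vapply(0:3, function(k) sum(cls$n_exceeded == k), integer(1))
  n_exceed <- c(sodium = sum(cls$sodium_status == "exceeds"),
                sugars = sum(cls$sugars_status == "exceeds"),
                satfat = sum(cls$satfat_status == "exceeds"))
  pct <- function(k) 100 * k / n
  tibble::tibble(
    n_products = n,
    n_restricted = n_restricted,
    n_permitted_nonexempt = n_permitted_nonexempt,
    n_exempt = n_exempt,
    pct_restricted = pct(n_restricted),
    pct_permitted_nonexempt = pct(n_permitted_nonexempt),
    pct_exempt = pct(n_exempt),
    n_exceeded_0 = n_by_exceeded[1], n_exceeded_1 = n_by_exceeded[2],
    n_exceeded_2 = n_by_exceeded[3], n_exceeded_3 = n_by_exceeded[4],
    pct_exceeded_0 = pct(n_by_exceeded[1]), pct_exceeded_1 = pct(n_by_exceeded[2]),
    pct_exceeded_2 = pct(n_by_exceeded[3]), pct_exceeded_3 = pct(n_by_exceeded[4]),
    n_exceed_sodium = n_exceed[["sodium"]],
    n_exceed_sugars = n_exceed[["sugars"]],
    n_exceed_satfat = n_exceed[["satfat"]],
    pct_exceed_sodium = pct(n_exceed[["sodium"]]),
    pct_exceed_sugars = pct(n_exceed[["sugars"]]),
    pct_exceed_satfat = pct(n_exceed[["satfat"]])
  )
}

#' Summarise classifications per brand
#'
#' Aggregates product classifications to one row per brand and food
#' category group: counts and proportions of restricted, permitted
#' non-exempt and exempt products; the 0/1/2/3-thresholds-exceeded
#' distribution; and per-nutrient exceedance. Products exceeding zero
#' thresholds include both exempt products and non-exempt products
#' within all thresholds, so `pct_restricted = 100 - pct_exceeded_0`.
#' Percentages are kept at full precision here; rounding to one decimal
#' happens only in [write_brand_summaries()].
#'
#' Brand identity is the brand string after case/whitespace
#' normalisation of comparisons; sub-brands (e.g. a cola and its diet
#' variant sold as distinct brands) are distinct whenever the brand
#' column says so.
#'
#' @param classifications Output of [classify_products()].
#' @return A tibble, one row per (brand, group), plus the columns of the
#'   per-brand summary.
#' @export
summarize_brands <- function(classifications) {
  if (nrow(classifications) == 0) stop("no classifications to summarise", call. = FALSE)
  norm_brand <- gsub("\\s+", " ", trimws(classifications$brand))
  cls <- dplyr::mutate(classifications, .brand = norm_brand)
  out <- cls |>
    dplyr::group_by(brand = .data$.brand, group = .data$group) |>
    dplyr::group_modify(~ brand_summary_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group, .data$brand)
  out
}

#' Flag mostly-unhealthy brands
#'
#' A brand is considered comprised of mostly unhealthy foods when 50 %
#' or more of its products (in that food category) would be restricted
#' from marketing to children. The comparison is inclusive and uses the
#' unrounded percentage.
#'
#' @param brand_summaries Output of [summarize_brands()].
#' @param params [npm_params()] (uses `brand_unhealthy_cutoff`).
#' @return Logical vector, one element per summary row.
#' @export
flag_unhealthy_brand <- function(brand_summaries, params = npm_params()) {
  params <- as_npm_params(params)
  at_least(brand_summaries$pct_restricted, params$brand_unhealthy_cutoff,
           params$rel_tol)
}

study_rollup <- function(bs, params) {
  pooled <- bs |>
    dplyr::group_by(.data$brand) |>
    dplyr::summarise(n_products = sum(.data$n_products),
                     n_restricted = sum(.data$n_restricted),
                     n_exceeded_2 = sum(.data$n_exceeded_2),
                     .groups = "drop")
  pct_restricted <- 100 * pooled$n_restricted / pooled$n_products
  pct_two <- 100 * pooled$n_exceeded_2 / pooled$n_products
  n_brands <- nrow(pooled)
  n_all <- sum(pooled$n_restricted == pooled$n_products)
  n_majority <- sum(at_least(pct_restricted, params$brand_unhealthy_cutoff,
                             params$rel_tol))
  n_majority_two <- sum(at_least(pct_two, params$brand_unhealthy_cutoff,
                                 params$rel_tol))
  tibble::tibble(
    n_brands = n_brands,
    n_brands_all_restricted = n_all,
    n_brands_majority_restricted = n_majority,
    n_brands_majority_two_thresholds = n_majority_two,
    pct_brands_all_restricted = 100 * n_all / n_brands,
    pct_brands_majority_restricted = 100 * n_majority / n_brands
  )
}

#' Study-level brand tallies
#'
#' Rolls brand summaries up to study level: the number of brands for
#' which 100 % of products exceed at least one threshold, the number
#' with a majority (>= the 50 % cutoff) of restricted products, and the
#' number with a majority of products exceeding exactly two thresholds
#' (the reading of the 0/1/2/3 partition). The overall block counts each
#' brand once, pooling its products across categories (a private label
#' present in several categories is one unique brand overall); the
#' `per_category` block tallies brands within each food category group.
#'
#' @param brand_summaries Output of [summarize_brands()].
#' @param params [npm_params()].
#' @return A list with `overall` (one-row tibble) and `per_category`
#'   (one row per group).
#' @export
summarize_study <- function(brand_summaries, params = npm_params()) {
  params <- as_npm_params(params)
  if (nrow(brand_summaries) == 0) stop("no brand summaries", call. = FALSE)
  overall <- study_rollup(brand_summaries, params)
  per_category <- brand_summaries |>
    dplyr::group_by(group = .data$group) |>
    dplyr::group_modify(~ study_rollup(.x, params)) |>
    dplyr::ungroup()
  list(overall = overall, per_category = per_category)
}

#' Write brand summaries
#'
#' Writes one row per (brand, group) with percentages rounded half-up to
#' one decimal place, the convention of published food-policy tables.
#' Counts are written unrounded.
#'
#' @param brand_summaries Output of [summarize_brands()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_brand_summaries <- function(brand_summaries, path) {
  out <- dplyr::mutate(brand_summaries,
                       dplyr::across(dplyr::starts_with("pct_"),
                                     ~ round_half_up(.x, 1)))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write a study summary
#'
#' Emits the study-level tallies as a JSON record (overall and
#' per-category blocks) and prints a small human-readable table.
#'
#' @param study Output of [summarize_study()].
#' @param path Output JSON path.
#' @param quiet Suppress the printed table.
#' @return `path`, invisibly.
#' @export
write_study_summary <- function(study, path, quiet = FALSE) {
  jsonlite::write_json(study, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!quiet) {
    cat("Study summary (overall):\n")
    print(as.data.frame(study$overall), row.names = FALSE)
    cat("Per category:\n")
    print(as.data.frame(study$per_category), row.names = FALSE)
  }
  invisible(path)
}
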