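#' Model parameters for the marketing-to-children nutrient profile model
#'
#' Bundles every numeric constant of Health Canada's proposed
#' marketing-to-kids (M2K) nutrient profile model in one configurable
#' record. The defaults are the values of the proposed regulations:
#' nutrient thresholds equivalent to the "low in" nutrient content claim
#' levels (140 mg sodium, 5 g total sugars, 2 g saturated plus trans fat
#' per evaluation basis, and 15 % of energy from saturated plus trans
#' fat), the small-reference-amount and main-dish evaluation bases, and
#' the 50 % brand-level reporting cutoff.
#'
#' @param sodium_max Sodium threshold in mg at the evaluation basis;
#'   compliant at or below this amount.
#' @param sugars_max Total sugars threshold in g; compliant at or below.
#' @param satfat_max Combined saturated + trans fat threshold in g;
#'   compliant at or below.
#' @param satfat_energy_max Maximum percentage of energy from saturated +
#'   trans fat; compliant strictly below this value.
#' @param small_ra_cutoff Reference amounts at or below this many grams
#'   use `small_ra_basis` as the evaluation basis.
#' @param small_ra_basis Evaluation basis in g for small-reference-amount
#'   foods.
#' @param main_dish_ra_cutoff Main dishes with a reference amount at or
#'   above this many grams use `main_dish_basis`.
#' @param main_dish_basis Evaluation basis in g for qualifying main dishes.
#' @param brand_unhealthy_cutoff Percentage of restricted products at or
#'   above which a brand is considered mostly unhealthy.
#' @param atwater_tolerance Relative tolerance for the Atwater energy
#'   plausibility check (fraction, e.g. 0.20 for 20 %).
#' @param rel_tol Relative tolerance used only to absorb floating-point
#'   noise in threshold comparisons; never softens a boundary.
#'
#' @return A list of class `npm_params`.
#' @examples
#' p <- npm_params()
#' p$sodium_max
#' npm_params(atwater_tolerance = 0.1)
#' @export
npm_params <- function(sodium_max = 140,
                       sugars_max = 5,
                       satfat_max = 2,
                       satfat_energy_max = 15,
                       small_ra_cutoff = 30,
                       small_ra_basis = 50,
                       main_dish_ra_cutoff = 200,
                       main_dish_basis = 100,
                       brand_unhealthy_cutoff = 50,
                       atwater_tolerance = 0.20,
                       rel_tol = 1e-9) {
  p <- list(
    sodium_max = sodium_max,
    sugars_max = sugars_max,
    satfat_max = satfat_max,
    satfat_energy_max = satfat_energy_max,
    small_ra_cutoff = small_ra_cutoff,
    small_ra_basis = small_ra_basis,
    main_dish_ra_cutoff = main_dish_ra_cutoff,
    main_dish_basis = main_dish_basis,
    brand_unhealthy_cutoff = brand_unhealthy_cutoff,
    atwater_tolerance = atwater_tolerance,
    rel_tol = rel_tol
  )
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num)) {
    stop("npm_params: all parameters must be finite numeric scalars: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  pos <- setdiff(names(p), c("rel_tol", "atwater_tolerance"))
  bad <- pos[vapply(p[pos], function(x) x <= 0, logical(1))]
  if (length(bad)) {
    stop("npm_params: parameters must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (p$atwater_tolerance < 0 || p$atwater_tolerance >= 1) {
    stop("npm_params: atwater_tolerance must be in [0, 1)", call. = FALSE)
  }
  if (p$satfat_energy_max > 100 || p$brand_unhealthy_cutoff > 100) {
    stop("npm_params: percentage parameters must be in (0, 100]", call. = FALSE)
  }
  structure(p, class = "npm_params")
}

#' @export
print.npm_params <- function(x, ...) {
  cat("Marketing-to-children NPM parameters\n")
  cat(sprintf("  thresholds : sodium <= %g mg, sugars <= %g g, sat+trans fat <= %g g, < %g%% energy\n",
              x$sodium_max, x$sugars_max, x$satfat_max, x$satfat_energy_max))
  cat(sprintf("  basis rules: RA <= %g g -> %g g; main dish RA >= %g g -> %g g; else max(RA, serving)\n",
              x$small_ra_cutoff, x$small_ra_basis, x$main_dish_ra_cutoff, x$main_dish_basis))
  cat(sprintf("  brand rule : >= %g%% restricted products => mostly-unhealthy brand\n",
              x$brand_unhealthy_cutoff))
  cat(sprintf("  cleaning   : Atwater tolerance %g\n", x$atwater_tolerance))
  invisible(x)
}

as_npm_params <- function(params) {
  if (inherits(params, "npm_params")) return(params)
  if (is.list(params)) return(do.call(npm_params, params))
  stop("params must be an npm_params object or a list of overrides", call. = FALSE)
}
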