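#' Define a synthetic category profile
#'
#' A category profile drives the synthetic branded-food generator: it
#' fixes, for one minor food category or restaurant menu class, the
#' per-serving nutrient distributions (log-normal — non-negative and
#' right-skewed, the shape of real food-composition data), the
#' serving-size distribution, the probabilities that products carry
#' added sodium, free sugars or added fat, and ingredient-phrase pools
#' consistent with those flags (a present flag always emits at least one
#' matching lexicon term).
#'
#' @param category_code Category code present in the reference-amount
#'   table.
#' @param source `"packaged"` or `"restaurant"`.
#' @param brands Character vector of brand names to sample from.
#' @param name_stem Stem for generated product names.
#' @param serving_meanlog,serving_sdlog Log-normal parameters of the
#'   stated serving size (g or mL).
#' @param sodium,sugars,satfat,extra_carb,extra_fat,protein Each a
#'   length-2 numeric `c(meanlog, sdlog)` of the per-serving log-normal
#'   distribution (mg for sodium, g otherwise). Carbohydrate is
#'   `sugars + extra_carb` and total fat `satfat + trans + extra_fat`,
#'   so declarations are internally consistent; energy is computed from
#'   the macronutrients with Atwater factors plus a small declaration
#'   noise, so clean records pass the plausibility check.
#' @param p_trans Probability a product declares non-zero trans fat
#'   (drawn as a small fraction of saturated fat).
#' @param p_added_sodium,p_free_sugars,p_added_fat Flag probabilities
#'   (packaged products).
#' @param p_exempt Probability a restaurant item is a plainly
#'   unprocessed allow-list item (bottled water, apple slices) with all
#'   flags absent; other restaurant items carry no ingredient list and
#'   all flags present.
#' @param is_main_dish Logical, default main-dish status of the
#'   category.
#' @param serving_unit `"g"` or `"mL"`.
#' @return A list of class `npm_profile`.
#' @export
category_profile <- function(category_code, source, brands, name_stem,
                             serving_meanlog, serving_sdlog,
                             sodium, sugars, satfat,
                             extra_carb, extra_fat, protein,
                             p_trans = 0.1,
                             p_added_sodium = 0.9, p_free_sugars = 0.9,
                             p_added_fat = 0.9, p_exempt = 0.05,
                             is_main_dish = FALSE, serving_unit = "g") {
  prof <- list(category_code = category_code, source = source,
               brands = brands, name_stem = name_stem,
               serving_meanlog = serving_meanlog,
               serving_sdlog = serving_sdlog,
               sodium = sodium, sugars = sugars, satfat = satfat,
               extra_carb = extra_carb, extra_fat = extra_fat,
               protein = protein, p_trans = p_trans,
               p_added_sodium = p_added_sodium,
               p_free_sugars = p_free_sugars, p_added_fat = p_added_fat,
               p_exempt = p_exempt, is_main_dish = is_main_dish,
               serving_unit = serving_unit)
  probs <- c(prof$p_trans, prof$p_added_sodium, prof$p_free_sugars,
             prof$p_added_fat, prof$p_exempt)
  if (any(probs < 0 | probs > 1)) {
    stop("profile probabilities must be in [0, 1]", call. = FALSE)
  }
  dists <- c("sodium", "sugars", "satfat", "extra_carb", "extra_fat", "protein")
  for (d in dists) {
    v <- prof[[d]]
    if (!is.numeric(v) || length(v) != 2 || v[2] <= 0) {
      stop("profile distribution '", d,
           "' must be c(meanlog, sdlog) with sdlog > 0", call. = FALSE)
    }
  }
  if (!source %in% c("packaged", "restaurant")) {
    stop("profile source must be 'packaged' or 'restaurant'", call. = FALSE)
  }
  structure(prof, class = "npm_profile")
}

# Ingredient-phrase pools. Flag pools emit lexicon terms; the neutral
# pool is curated to contain none, so text-derived flags always match
# the sampled truth.
phrase_pools <- function() {
  list(
    neutral = c("water", "whole grain oats", "whole grain wheat", "rice",
                "corn", "skim milk", "milk ingredients", "bacterial cultures",
                "natural flavour", "citric acid", "pectin", "vitamin d",
                "calcium carbonate", "dried apples", "raisins", "cocoa",
                "carbonated water"),
    sodium = c("salt", "sea salt", "monosodium glutamate", "baking soda",
               "sodium phosphate"),
    sugars = c("sugar", "glucose-fructose", "honey", "brown sugar",
               "apple juice concentrate"),
    fat = c("canola oil", "palm oil", "butter", "margarine", "sunflower oil"))
}

allow_name_pool <- function() {
  c("Bottled Water", "Sparkling Water", "Apple Slices", "Plain Tea")
}

#' Default synthetic category profiles
#'
#' Profiles emulating the category patterns of Canadian branded-food
#' data: breakfast cereals high in sugars and sodium with little
#' saturated fat; beverages dominated by sugars; yogurts high in sugars
#' with low sodium; restaurant items high in sodium and saturated fat.
#' Directions, not fitted percentages — the generator emulates the
#' structure of proprietary food-composition databases, not their
#' contents.
#'
#' @return A named list of [category_profile()] objects covering the
#'   in-scope packaged categories (C1–C3, B1, J11, D12, D15) and the
#'   restaurant menu classes.
#' @export
default_profiles <- function() {
  cereal_brands <- c("CrunchCo", "MorningMills", "OatWorks", "MapleLeaf Select")
  bev_brands <- c("FizzPop", "JuicyCo", "SparkleBev", "MapleLeaf Select")
  yog_brands <- c("DairyBest", "YogoFresh", "CultureCo")
  resto_brands <- c("BurgerBarn", "PizzaPalace", "ChickenShack", "CoffeeCorner")
  list(
    C1 = category_profile("C1", "packaged", cereal_brands, "Puffed Cereal",
                          log(32), 0.12,
                          sodium = c(log(150), 0.5), sugars = c(log(9), 0.6),
                          satfat = c(log(0.3), 0.7), extra_carb = c(log(16), 0.3),
                          extra_fat = c(log(0.8), 0.5), protein = c(log(2.5), 0.3),
                          p_added_sodium = 0.85, p_free_sugars = 0.9,
                          p_added_fat = 0.6),
    C2 = category_profile("C2", "packaged", cereal_brands, "Flake Cereal",
                          log(42), 0.12,
                          sodium = c(log(180), 0.5), sugars = c(log(11), 0.6),
                          satfat = c(log(0.4), 0.7), extra_carb = c(log(20), 0.3),
                          extra_fat = c(log(1), 0.5), protein = c(log(3), 0.3),
                          p_added_sodium = 0.9, p_free_sugars = 0.9,
                          p_added_fat = 0.65),
    C3 = category_profile("C3", "packaged", cereal_brands, "Granola Cereal",
                          log(55), 0.1,
                          sodium = c(log(120), 0.5), sugars = c(log(13), 0.5),
                          satfat = c(log(1.2), 0.7), extra_carb = c(log(24), 0.3),
                          extra_fat = c(log(3), 0.5), protein = c(log(4.5), 0.3),
                          p_added_sodium = 0.8, p_free_sugars = 0.95,
                          p_added_fat = 0.9),
    B1 = category_profile("B1", "packaged", bev_brands, "Soft Drink",
                          log(355), 0.08,
                          sodium = c(log(40), 0.7), sugars = c(log(32), 0.8),
                          satfat = c(log(0.02), 0.5), extra_carb = c(log(1), 0.5),
                          extra_fat = c(log(0.02), 0.5), protein = c(log(0.2), 0.5),
                          p_added_sodium = 0.6, p_free_sugars = 0.8,
                          p_added_fat = 0.05, serving_unit = "mL"),
    J11 = category_profile("J11", "packaged", bev_brands, "Fruit Juice",
                           log(250), 0.1,
                           sodium = c(log(15), 0.6), sugars = c(log(24), 0.4),
                           satfat = c(log(0.05), 0.5), extra_carb = c(log(2), 0.5),
                           extra_fat = c(log(0.05), 0.5), protein = c(log(0.5), 0.5),
                           p_added_sodium = 0.2, p_free_sugars = 0.95,
                           p_added_fat = 0.05, serving_unit = "mL"),
    D12 = category_profile("D12", "packaged", yog_brands, "Yogurt",
                           log(160), 0.12,
                           sodium = c(log(55), 0.35), sugars = c(log(15), 0.45),
                           satfat = c(log(1.4), 0.7), extra_carb = c(log(4), 0.4),
                           extra_fat = c(log(0.7), 0.5), protein = c(log(6), 0.3),
                           p_added_sodium = 0.25, p_free_sugars = 0.85,
                           p_added_fat = 0.4),
    D15 = category_profile("D15", "packaged", yog_brands, "Drinkable Yogurt",
                           log(200), 0.08,
                           sodium = c(log(70), 0.35), sugars = c(log(18), 0.4),
                           satfat = c(log(1.1), 0.6), extra_carb = c(log(5), 0.4),
                           extra_fat = c(log(0.5), 0.5), protein = c(log(6), 0.3),
                           p_added_sodium = 0.25, p_free_sugars = 0.9,
                           p_added_fat = 0.35),
    starter = category_profile("starter", "restaurant", resto_brands, "Starter",
                               log(160), 0.3,
                               sodium = c(log(650), 0.5), sugars = c(log(3), 0.9),
                               satfat = c(log(4.5), 0.6), extra_carb = c(log(22), 0.4),
                               extra_fat = c(log(8), 0.4), protein = c(log(10), 0.4),
                               p_trans = 0.3, p_exempt = 0.04),
    entree = category_profile("entree", "restaurant", resto_brands, "Entree",
                              log(300), 0.25,
                              sodium = c(log(1100), 0.5), sugars = c(log(7), 0.9),
                              satfat = c(log(9), 0.6), extra_carb = c(log(45), 0.35),
                              extra_fat = c(log(14), 0.4), protein = c(log(28), 0.35),
                              p_trans = 0.4, p_exempt = 0.01, is_main_dish = TRUE),
    side = category_profile("side", "restaurant", resto_brands, "Side",
                            log(110), 0.3,
                            sodium = c(log(450), 0.5), sugars = c(log(2), 0.9),
                            satfat = c(log(3.2), 0.6), extra_carb = c(log(28), 0.4),
                            extra_fat = c(log(8), 0.4), protein = c(log(4), 0.4),
                            p_trans = 0.3, p_exempt = 0.08),
    dessert = category_profile("dessert", "restaurant", resto_brands, "Dessert",
                               log(140), 0.25,
                               sodium = c(log(220), 0.5), sugars = c(log(35), 0.5),
                               satfat = c(log(8), 0.5), extra_carb = c(log(25), 0.4),
                               extra_fat = c(log(7), 0.4), protein = c(log(5), 0.4),
                               p_trans = 0.3, p_exempt = 0.02),
    beverage = category_profile("beverage", "restaurant", resto_brands,
                                "Fountain Drink", log(400), 0.2,
                                sodium = c(log(45), 0.7), sugars = c(log(38), 0.6),
                                satfat = c(log(0.5), 1.2), extra_carb = c(log(2), 0.5),
                                extra_fat = c(log(0.5), 0.8), protein = c(log(1), 0.8),
                                p_exempt = 0.12, serving_unit = "mL"))
}

rlnorm2 <- function(n, par) stats::rlnorm(n, par[1], par[2])

generate_one_profile <- function(prof, n, pools) {
  code <- prof$category_code
  ids <- sprintf("%s-%04d", code, seq_len(n))
  brand <- sample(prof$brands, n, replace = TRUE)
  serving <- round(pmax(rlnorm2(n, c(prof$serving_meanlog, prof$serving_sdlog)), 5))
  sodium <- round(rlnorm2(n, prof$sodium))
  sugars <- round(rlnorm2(n, prof$sugars), 1)
  satfat <- round(rlnorm2(n, prof$satfat), 1)
  trans <- round(ifelse(stats::runif(n) < prof$p_trans,
                        satfat * stats::runif(n, 0.05, 0.3), 0), 1)
  extra_fat <- round(rlnorm2(n, prof$extra_fat), 1)
  extra_carb <- round(rlnorm2(n, prof$extra_carb), 1)
  protein <- round(rlnorm2(n, prof$protein), 1)
  totalfat <- satfat + trans + extra_fat
  carb <- sugars + extra_carb
  energy <- round((4 * (protein + carb) + 9 * totalfat) *
                    stats::runif(n, 0.93, 1.07))

  if (prof$source == "packaged") {
    f_na <- stats::runif(n) < prof$p_added_sodium
    f_su <- stats::runif(n) < prof$p_free_sugars
    f_fa <- stats::runif(n) < prof$p_added_fat
    text <- vapply(seq_len(n), function(i) {
      base <- sample(pools$neutral, sample(2:4, 1))
      if (f_na[i]) base <- c(base, sample(pools$sodium, 1))
      if (f_su[i]) base <- c(base, sample(pools$sugars, 1))
      if (f_fa[i]) base <- c(base, sample(pools$fat, 1))
      paste(sample(base), collapse = ", ")
    }, character(1))
    name <- sprintf("%s %04d", prof$name_stem, seq_len(n))
    store <- sample(c("store_a", "store_b", "store_c"), n, replace = TRUE)
  } else {
    exempt <- stats::runif(n) < prof$p_exempt
    f_na <- f_su <- f_fa <- !exempt
    # Allow-list items are plain water-like products.
    pool <- allow_name_pool()
    name <- sprintf("%s %04d", prof$name_stem, seq_len(n))
    name[exempt] <- sprintf("%s %04d", sample(pool, sum(exempt), replace = TRUE),
                            which(exempt))
    sodium[exempt] <- 0
    sugars[exempt] <- round(stats::runif(sum(exempt), 0, 3), 1)
    satfat[exempt] <- 0
    trans[exempt] <- 0
    totalfat[exempt] <- 0
    extra_carb[exempt] <- 0
    carb[exempt] <- sugars[exempt]
    protein[exempt] <- 0
    energy[exempt] <- round(4 * carb[exempt])
    text <- rep(NA_character_, n)
    store <- rep(NA_character_, n)
  }

  products <- tibble::tibble(
    product_id = ids, brand = brand, name = name, category_code = code,
    source = prof$source, is_main_dish = prof$is_main_dish, store_id = store,
    serving_size = serving, serving_unit = prof$serving_unit,
    basis_state = "as_sold", energy_kcal = energy, sodium_mg = sodium,
    sugars_g = sugars, satfat_g = satfat, transfat_g = trans,
    totalfat_g = totalfat, carb_g = carb, protein_g = protein,
    ingredients_text = text, flag_sodium = NA_character_,
    flag_sugars = NA_character_, flag_fat = NA_character_)
  flags <- tibble::tibble(
    added_sodium = ifelse(f_na, "present", "absent"),
    free_sugars = ifelse(f_su, "present", "absent"),
    added_fat = ifelse(f_fa, "present", "absent"))
  list(products = products, flags = flags)
}

#' Generate synthetic products with known ground truth
#'
#' Draws product records from category profiles and derives their true
#' classification by direct construction: the sampled flags are the true
#' flags, and per-nutrient statuses come from [oracle_classify()], the
#' straight-line transcription of the rules that shares no code with the
#' classification engine under test. Ingredient texts are generated to
#' agree with the sampled flags (a present flag emits a matching lexicon
#' term; absent flags emit none), so the full text-based pipeline can be
#' checked against the ground truth. Output is reproducible for a fixed
#' seed.
#'
#' @param profiles List of [category_profile()] objects.
#' @param n_per_category Products to draw per profile (scalar or vector
#'   recycled along profiles).
#' @param seed Integer seed for the generator's private random stream.
#' @param ra_table Reference-amount table used for the ground-truth
#'   basis computation.
#' @param params [npm_params()] for the ground truth.
#' @return A list with `products` (canonical product tibble) and
#'   `ground_truth` (true flags plus the oracle classification, one row
#'   per product).
#' @export
generate_products <- function(profiles = default_profiles(),
                              n_per_category = 40, seed = 1,
                              ra_table = default_reference_amounts(),
                              params = npm_params()) {
  if (any(n_per_category < 1)) stop("n_per_category must be >= 1", call. = FALSE)
  ok <- vapply(profiles, inherits, logical(1), "npm_profile")
  if (!length(profiles) || !all(ok)) {
    stop("profiles must be a list of category_profile() objects", call. = FALSE)
  }
  n_per_category <- rep_len(as.integer(n_per_category), length(profiles))
  pools <- phrase_pools()
  parts <- withr::with_seed(seed, {
    lapply(seq_along(profiles), function(i) {
      generate_one_profile(profiles[[i]], n_per_category[i], pools)
    })
  })
  products <- dplyr::bind_rows(lapply(parts, `[[`, "products"))
  flags <- dplyr::bind_rows(lapply(parts, `[[`, "flags"))
  truth <- oracle_classify(products, flags, ra_table, params)
  ground_truth <- dplyr::bind_cols(
    tibble::tibble(product_id = products$product_id), flags,
    truth[, setdiff(names(truth), "product_id")])
  list(products = products, ground_truth = ground_truth)
}

#' Inject cleaning artifacts into a product table
#'
#' Exercises the data-cleaning stages by planting known defects:
#' duplicate store listings (exact copies with a new store id), missing
#' sugars or saturated-fat values, and Atwater-implausible energy
#' declarations (energy inflated far beyond the check's tolerance). The
#' three victim sets are disjoint, so each planted record is excluded
#' for exactly one reason; an injection manifest is returned for test
#' assertions.
#'
#' @param products Product tibble.
#' @param dup_rate,missing_rate,atwater_corrupt_rate Fractions in
#'   `[0, 1)` of records to duplicate, blank and corrupt.
#' @param seed Integer seed.
#' @return A list with `products` (modified table, duplicates appended)
#'   and `manifest` (tibble of `product_id`, `artifact`, `detail`).
#' @export
inject_artifacts <- function(products, dup_rate = 0, missing_rate = 0,
                             atwater_corrupt_rate = 0, seed = 1) {
  rates <- c(dup_rate, missing_rate, atwater_corrupt_rate)
  if (any(rates < 0 | rates >= 1)) stop("rates must be in [0, 1)", call. = FALSE)
  n <- nrow(products)
  withr::with_seed(seed, {
    victims <- sample(n, min(n, floor(n * dup_rate) + floor(n * missing_rate) +
                               floor(n * atwater_corrupt_rate)))
    i_miss <- victims[seq_len(floor(n * missing_rate))]
    victims <- setdiff(victims, i_miss)
    i_corrupt <- victims[seq_len(floor(n * atwater_corrupt_rate))]
    i_dup <- setdiff(victims, i_corrupt)

    manifest <- list()
    if (length(i_miss)) {
      blank_sugars <- seq_along(i_miss) %% 2 == 1
      products$sugars_g[i_miss[blank_sugars]] <- NA_real_
      products$satfat_g[i_miss[!blank_sugars]] <- NA_real_
      manifest$missing <- tibble::tibble(
        product_id = products$product_id[i_miss],
        artifact = ifelse(blank_sugars, "missing_sugars", "missing_satfat"),
        detail = "value blanked")
    }
    if (length(i_corrupt)) {
      products$energy_kcal[i_corrupt] <- products$energy_kcal[i_corrupt] * 3 + 100
      manifest$corrupt <- tibble::tibble(
        product_id = products$product_id[i_corrupt],
        artifact = "atwater_fail", detail = "energy inflated x3 + 100 kcal")
    }
    if (length(i_dup)) {
      copies <- products[i_dup, , drop = FALSE]
      copies$store_id <- "store_dup"
      products <- dplyr::bind_rows(products, copies)
      manifest$dup <- tibble::tibble(
        product_id = copies$product_id, artifact = "duplicate",
        detail = "exact copy from another store")
    }
    empty <- tibble::tibble(product_id = character(), artifact = character(),
                            detail = character())
    list(products = products,
         manifest = dplyr::bind_rows(c(list(empty), unname(manifest))))
  })
}
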