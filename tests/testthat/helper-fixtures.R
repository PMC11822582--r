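# Build a small product tibble in the canonical schema; override any
# field per product via ...
make_products <- function(n = 1, ...) {
  base <- tibble::tibble(
    product_id = sprintf("p%03d", seq_len(n)),
    brand = "TestBrand",
    name = sprintf("Test Product %03d", seq_len(n)),
    category_code = "C2",
    source = "packaged",
    is_main_dish = FALSE,
    store_id = "store_a",
    serving_size = 40,
    serving_unit = "g",
    basis_state = "as_sold",
    energy_kcal = 150,
    sodium_mg = 100,
    sugars_g = 8,
    satfat_g = 0.5,
    transfat_g = 0,
    totalfat_g = 1.5,
    carb_g = 30,
    protein_g = 3,
    ingredients_text = "whole grain wheat, sugar, salt, canola oil",
    flag_sodium = NA_character_,
    flag_sugars = NA_character_,
    flag_fat = NA_character_)
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# A tiny reference-amount table with one code per rule branch.
tiny_ra_table <- function() {
  tibble::tibble(
    category_code = c("SMALL", "STD", "MAIN", "C2"),
    group = c("g1", "g1", "g2", "breakfast_cereals"),
    reference_amount = c(30, 55, 250, 40),
    unit = "g",
    is_main_dish_default = c(FALSE, FALSE, TRUE, FALSE))
}
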