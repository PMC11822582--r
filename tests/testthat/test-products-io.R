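test_that("product tables round-trip through CSV, including missing markers", {
  prods <- make_products(3,
                         sugars_g = c(8, NA, 2.5),
                         transfat_g = c(0, 0.1, NA),
                         ingredients_text = c("oats, salt", NA, "water"),
                         store_id = c("store_a", NA, "store_b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_products(prods, path)
  strip <- function(x) {
    attr(x, "row_errors") <- NULL
    as.data.frame(x)
  }
  back <- read_products(path)
  expect_equal(nrow(attr(back, "row_errors")), 0)
  expect_equal(strip(back), as.data.frame(prods))
  # second round trip is also identity
  write_products(back, path)
  expect_equal(strip(read_products(path)), as.data.frame(prods))
})

test_that("invalid rows are skipped and reported, never silently kept", {
  prods <- make_products(4,
                         sodium_mg = c(100, -5, 100, 100),
                         serving_size = c(40, 40, 0, 40),
                         brand = c("A", "B", "C", ""))
  path <- withr::local_tempfile(fileext = ".csv")
  write_products(prods, path)
  expect_warning(back <- read_products(path), "invalid")
  expect_equal(back$product_id, "p001")
  errs <- attr(back, "row_errors")
  expect_setequal(errs$product_id, c("p002", "p003", "p004"))
  expect_match(errs$reason[errs$product_id == "p002"], "negative sodium")
})

test_that("empty nutrient cells are read as missing, not zero", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_products(make_products(1, sugars_g = NA_real_), path)
  back <- read_products(path)
  expect_true(is.na(back$sugars_g))
  expect_false(identical(back$sugars_g, 0))
})

test_that("energy in kJ is converted to kcal on read", {
  prods <- make_products(1, energy_kcal = 150)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(prods)
  df$energy_kj <- df$energy_kcal * 4.184
  df$energy_kcal <- NULL
  readr::write_csv(df, path, na = "")
  back <- read_products(path)
  expect_equal(back$energy_kcal, 150)
})

test_that("deduplication collapses same-store listings but keeps sizes and flavours", {
  prods <- make_products(5,
                         name = c("Corn Flakes", "corn  flakes", "CORN FLAKES",
                                  "Corn Flakes", "Corn Flakes Honey"),
                         serving_size = c(40, 40, 40, 55, 40),
                         store_id = c("s1", "s2", "s3", "s1", "s1"))
  out <- deduplicate_products(prods)
  # three identical listings (case/whitespace-insensitive) collapse to one;
  # the other size and the other flavour are both kept
  expect_equal(out$products$product_id, c("p001", "p004", "p005"))
  expect_equal(out$exclusions$reason, c("duplicate", "duplicate"))
  expect_setequal(out$exclusions$product_id, c("p002", "p003"))
  # first occurrence in input order survives
  expect_equal(out$products$store_id[1], "s1")
})

test_that("deduplication is idempotent and conserves rows", {
  prods <- make_products(6, name = c("A", "A", "B", "B", "B", "C"))
  once <- deduplicate_products(prods)
  twice <- deduplicate_products(once$products)
  expect_equal(twice$products, once$products)
  expect_equal(nrow(twice$exclusions), 0)
  expect_equal(nrow(once$products) + nrow(once$exclusions), nrow(prods))
  empty <- deduplicate_products(prods[0, ])
  expect_equal(nrow(empty$products), 0)
})

test_that("Atwater check matches hand-computed energies", {
  # 4*2 + 4*27 + 9*1 = 125 kcal, agrees with declaration
  chk <- atwater_check(2, 27, 1, 125, tolerance = 0.20)
  expect_equal(chk$computed_kcal, 125)
  expect_equal(chk$verdict, "pass")
  # 4*10 + 4*10 + 9*10 = 170 kcal vs declared 500: relative error far
  # beyond 20 %
  chk <- atwater_check(10, 10, 10, 500, tolerance = 0.20)
  expect_equal(chk$computed_kcal, 170)
  expect_equal(chk$verdict, "fail")
  # all-zero declaration is internally consistent
  expect_equal(atwater_check(0, 0, 0, 0)$verdict, "pass")
  # both energies tiny: relative error is meaningless, treated as pass
  expect_equal(atwater_check(0, 1, 0, 2)$verdict, "pass")
  # a missing macronutrient is not assessable, distinct from failing
  expect_equal(atwater_check(NA, 27, 1, 125)$verdict, "not_assessable")
})

test_that("missing-data filter excludes only sugars/satfat gaps", {
  prods <- make_products(4,
                         sugars_g = c(8, NA, 8, NA),
                         satfat_g = c(0.5, 0.5, NA, NA),
                         transfat_g = c(NA, 0, 0, 0))
  out <- filter_missing(prods)
  expect_equal(out$products$product_id, "p001")  # missing trans fat kept
  expect_equal(
    out$exclusions$reason[match(c("p002", "p003", "p004"),
                                out$exclusions$product_id)],
    c("missing_sugars", "missing_satfat", "missing_sugars"))
  expect_equal(nrow(out$products) + nrow(out$exclusions), nrow(prods))
})

test_that("clean_products assigns each row one fate and one primary reason", {
  prods <- make_products(5,
                         name = c("A", "A", "B", "C", "D"),
                         sugars_g = c(8, 8, NA, 8, 8),
                         energy_kcal = c(150, 150, 150, 900, 150))
  out <- clean_products(prods)
  expect_equal(nrow(out$products) + nrow(out$exclusions), nrow(prods))
  expect_equal(anyDuplicated(out$exclusions$product_id), 0)
  reasons <- out$exclusions$reason[match(c("p002", "p003", "p004"),
                                         out$exclusions$product_id)]
  expect_equal(reasons, c("duplicate", "missing_sugars", "atwater_fail"))
  expect_equal(out$stage_counts[["input"]], 5)
  expect_equal(out$stage_counts[["complete"]], 2)
})
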