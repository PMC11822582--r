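test_that("per-serving amounts rescale linearly to the basis", {
  expect_equal(scale_to_basis(10, 100, 55), 5.5)
  expect_equal(scale_to_basis(7.3, 40, 40), 7.3)   # basis = serving: identity
  expect_equal(scale_to_basis(0, 40, 500), 0)
  expect_error(scale_to_basis(10, 0, 55), "positive")
})

test_that("sodium threshold is inclusive at 140 mg and gated by the flag", {
  ev <- evaluate_sodium(c(141, 140, 900), c("present", "present", "absent"),
                        serving_size = 50, basis = 50)
  expect_equal(ev$status, c("exceeds", "compliant", "exempt"))
  expect_error(evaluate_sodium(NA, "present", 50, 50), "missing")
})

test_that("sugars threshold is inclusive at 5 g and exempts intrinsic sugars", {
  ev <- evaluate_sugars(c(5.1, 5.0, 12), c("present", "present", "absent"),
                        serving_size = 100, basis = 100)
  # 12 g of lactose in a plain yogurt with no free sugars is exempt
  expect_equal(ev$status, c("exceeds", "compliant", "exempt"))
})

test_that("saturated fat applies both the gram and the energy criterion", {
  # 2.5 g > 2 g at basis: the gram criterion alone restricts
  ev <- evaluate_satfat(2.5, 0, 300, "present", 100, 100)
  expect_equal(ev$status, "exceeds")
  # S = 2.0 g passes the gram criterion but 9*2/100*100 = 18 % >= 15 %
  ev <- evaluate_satfat(1.5, 0.5, 100, "present", 100, 100)
  expect_equal(ev$amount_at_basis, 2.0)
  expect_equal(ev$energy_pct, 18)
  expect_equal(ev$status, "exceeds")
  # 9*1/100*100 = 9 % and 1 g: compliant on both
  ev <- evaluate_satfat(1, 0, 100, "present", 100, 100)
  expect_equal(ev$energy_pct, 9)
  expect_equal(ev$status, "compliant")
  # exactly 15 % of energy exceeds (compliance requires strictly less)
  ev <- evaluate_satfat(1, 0, 60, "present", 100, 100)
  expect_equal(ev$energy_pct, 15)
  expect_equal(ev$status, "exceeds")
  # exactly 2 g with low energy share is compliant (inclusive gram bound)
  expect_equal(evaluate_satfat(2, 0, 300, "present", 100, 100)$status,
               "compliant")
})

test_that("saturated fat handles missing trans fat and degenerate energy", {
  expect_warning(ev <- evaluate_satfat(1, NA, 100, "present", 100, 100),
                 "imputed")
  expect_equal(ev$amount_at_basis, 1)
  expect_error(expect_warning(evaluate_satfat(1, NA, 0, "present", 100, 100)),
               "implausible")
  # zero energy with zero fat: share defined as 0, compliant
  expect_equal(evaluate_satfat(0, 0, 0, "present", 100, 100)$status,
               "compliant")
})

test_that("the energy-share criterion is invariant to the basis", {
  for (basis in c(30, 50, 100, 355)) {
    ev <- evaluate_satfat(3, 0.5, 400, "present", 250, basis)
    expect_equal(ev$energy_pct, 9 * 3.5 / 400 * 100)
  }
})

test_that("classification assembles verdicts with consistent invariants", {
  tab <- tiny_ra_table()
  prods <- make_products(3,
    category_code = c("STD", "STD", "STD"),
    serving_size = 55,
    name = c("Bottled Water", "Sweet Cereal", "Diet Fizz"),
    ingredients_text = c("water", "wheat, sugar, salt", "carbonated water, salt"),
    sodium_mg = c(0, 200, 30),
    sugars_g = c(0, 9, 0),
    satfat_g = c(0, 0.3, 0),
    totalfat_g = c(0, 1, 0),
    carb_g = c(0, 30, 0),
    protein_g = c(0, 3, 0),
    energy_kcal = c(0, 220, 1))
  cls <- classify_products(prods, tab)
  # plain water: no added ingredients, exempt from everything, permitted
  expect_true(cls$fully_exempt[1])
  expect_equal(cls$status[1], "permitted")
  expect_equal(cls$n_exceeded[1], 0L)
  # sweetened salted cereal: sodium and sugars exceed, satfat exempt
  expect_equal(cls$sodium_status[2], "exceeds")
  expect_equal(cls$sugars_status[2], "exceeds")
  expect_equal(cls$satfat_status[2], "exempt")
  expect_equal(cls$n_exceeded[2], 2L)
  expect_equal(cls$status[2], "restricted")
  # diet soft drink: added sodium present but low; no free sugars or fat
  expect_equal(cls$n_exceeded[3], 0L)
  expect_equal(cls$status[3], "permitted")
  expect_false(cls$fully_exempt[3])
  # n_exceeded equals the count of 'exceeds' verdicts, status follows it
  counted <- (cls$sodium_status == "exceeds") +
    (cls$sugars_status == "exceeds") + (cls$satfat_status == "exceeds")
  expect_equal(cls$n_exceeded, as.integer(counted))
  expect_equal(cls$status == "restricted", cls$n_exceeded >= 1)
})

test_that("re-expressing the same declaration at another serving size gives identical verdicts", {
  # The evaluation compares concentrations at a basis, so re-expressing a
  # declaration at a different stated serving changes nothing as long as
  # the basis rule is unaffected: within the greater-of regime (serving
  # below the reference amount), at a small reference amount (basis
  # pinned to 50 g) and for a main dish (basis pinned to 100 g).
  tab <- tiny_ra_table()
  cases <- list(
    list(code = "STD", s1 = 40, s2 = 50, main = FALSE),
    list(code = "SMALL", s1 = 25, s2 = 75, main = FALSE),
    list(code = "MAIN", s1 = 250, s2 = 400, main = TRUE))
  for (cs in cases) {
    base <- make_products(1, category_code = cs$code, serving_size = cs$s1,
                          is_main_dish = cs$main,
                          sodium_mg = 110, sugars_g = 4.2, satfat_g = 1.5,
                          transfat_g = 0.3, totalfat_g = 3, carb_g = 20,
                          protein_g = 4, energy_kcal = 123)
    k <- cs$s2 / cs$s1
    rescaled <- base
    rescaled$serving_size <- cs$s2
    for (col in c("energy_kcal", "sodium_mg", "sugars_g", "satfat_g",
                  "transfat_g", "totalfat_g", "carb_g", "protein_g")) {
      rescaled[[col]] <- base[[col]] * k
    }
    a <- classify_products(base, tab)
    b <- classify_products(rescaled, tab)
    for (col in c("sodium_status", "sugars_status", "satfat_status",
                  "n_exceeded", "status", "basis_g")) {
      expect_equal(a[[col]], b[[col]])
    }
    expect_equal(a$sodium_at_basis, b$sodium_at_basis)
    expect_equal(a$satfat_energy_pct, b$satfat_energy_pct)
  }
})

test_that("raising a nutrient can only move verdicts toward restriction", {
  tab <- tiny_ra_table()
  set.seed(11)
  rank_status <- function(s) match(s, c("exempt", "compliant", "exceeds"))
  for (i in 1:60) {
    sod <- runif(1, 0, 300); sug <- runif(1, 0, 12); sat <- runif(1, 0, 4)
    p <- make_products(1, category_code = "STD",
                       serving_size = runif(1, 30, 120),
                       sodium_mg = sod, sugars_g = sug, satfat_g = sat,
                       transfat_g = 0, totalfat_g = sat + 1,
                       carb_g = sug + 5, protein_g = 2,
                       energy_kcal = 4 * (sug + 7) + 9 * (sat + 1))
    a <- classify_products(p, tab)
    bump <- p
    nutrient <- sample(c("sodium_mg", "sugars_g", "satfat_g"), 1)
    bump[[nutrient]] <- bump[[nutrient]] * runif(1, 1.1, 3)
    if (nutrient == "satfat_g") bump$totalfat_g <- bump$satfat_g + 1
    b <- classify_products(bump, tab)
    expect_gte(rank_status(b$sodium_status), rank_status(a$sodium_status))
    expect_gte(rank_status(b$sugars_status), rank_status(a$sugars_status))
    expect_gte(rank_status(b$satfat_status), rank_status(a$satfat_status))
    expect_false(a$status == "restricted" && b$status == "permitted")
  }
})
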