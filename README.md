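# m2knpm

Health Canada's proposed restrictions on food marketing to children would
prohibit advertising any food that *exceeds* specified thresholds for the
three nutrients of public-health concern — provided the food actually
contains the corresponding added ingredient. **m2knpm** implements that
marketing-to-kids nutrient profile model (M2K-NPM) as a tested, reusable
classification pipeline for researchers and policy analysts working with
branded food-composition data (packaged products with Nutrition Facts
declarations, or chain-restaurant menu items).

## The model

Each product is evaluated at an **evaluation basis** derived from the
reference amount (RA) of its minor food category in Health Canada's Table
of Reference Amounts:

| situation | basis |
|---|---|
| RA ≤ 30 g (sauces, dips, puffed cereals) | 50 g |
| main dish with RA ≥ 200 g (burgers, pizza) | 100 g |
| everything else | max(RA, stated serving) |

Each nutrient is then assessed independently, and only when the matching
added ingredient is present (the exemption gate):

- **sodium** — restricted if > 140 mg at the basis; assessed only for
  products containing *added sodium* (salt, MSG, baking soda, cheese, …);
- **total sugars** — restricted if > 5 g at the basis; assessed only for
  products containing *free sugars* (added sugar, honey, syrups, juice
  concentrates — not intrinsic lactose or fruit sugars);
- **saturated fat** — restricted if saturated + trans fat > 2 g at the
  basis **or** ≥ 15 % of energy (9 kcal/g × (SFA + TFA) / energy);
  assessed only for products containing *added fat* (oils, butter,
  margarine, shortening, …).

A product exceeding ≥ 1 threshold is **restricted**; products exceeding
none — including fully **exempt** products with no added sodium, free
sugars or added fat (bottled water, plain yogurt) — are **permitted**.
At the portfolio level, a brand with ≥ 50 % restricted products counts as
a mostly-unhealthy brand.

Because the study-grade databases behind this kind of analysis (FLIP /
Menu-FLIP) are proprietary, the package ships a synthetic branded-food
generator with category profiles (sugary cereals, beverages, yogurts,
salty/fatty restaurant menus) whose ground-truth classification is known
by construction, so every pipeline stage is testable end to end.

## Worked example

```r
library(m2knpm)

gen <- generate_products(n_per_category = 25, seed = 42)  # 300 products
res <- run_classify(gen$products, verbose = TRUE)
#> input products: 300 (plus 0 invalid rows skipped)
#> after cleaning: 300 kept, 0 excluded ()
#> classified: 300 (281 restricted, 19 permitted)

dplyr::select(res$classifications, product_id, basis_g, basis_rule,
              sodium_status, sugars_status, satfat_status, status)[1:3, ]
#>   product_id basis_g basis_rule sodium_status sugars_status satfat_status
#> 1 C1-0001         50 small_ra   exceeds       exceeds       compliant
#> 2 C1-0002         50 small_ra   exceeds       exceeds       compliant
#> 3 C1-0003         50 small_ra   compliant     exempt        compliant
```

The first two puffed cereals (RA 30 g, so assessed at 50 g) exceed both
the sodium and sugars thresholds and are restricted; the third contains
no free sugars, so the sugars threshold does not even apply to it.

```r
summ <- run_summarize(res$classifications)
dplyr::select(summ$brand_summaries, brand, group, n_products,
              pct_restricted, pct_exempt)[1:4, ]
#>   brand            group     n_products pct_restricted pct_exempt
#> 1 FizzPop          beverages         15           86.7       0
#> 2 JuicyCo          beverages         16           87.5      12.5
#> 3 MapleLeaf Select beverages          7           71.4      28.6
#> 4 SparkleBev       beverages         12           91.7       8.33

summ$study$overall
#>   n_brands n_brands_all_restricted n_brands_majority_restricted ...
#> 1       14                       4                           14
```

Here every one of the 14 synthetic brands has ≥ 50 % restricted products
(all would count as mostly-unhealthy brands), and for 4 of them 100 % of
products exceed at least one threshold.

Classification of real data starts from a CSV in the documented schema
(see `?read_products` and `product_template()`); `run_classify()` cleans
it (store-duplicate removal, Atwater energy plausibility, missing
sugars/saturated-fat exclusion) before classifying, and logs every
excluded row with its reason. A thin command-line front-end lives at
`inst/cli/m2knpm.R` with `classify`, `summarize` and `simulate`
subcommands.

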