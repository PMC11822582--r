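---
title: "The marketing-to-children nutrient profile model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The marketing-to-children nutrient profile model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m2knpm)
```

## The model

Health Canada's proposed marketing-to-kids nutrient profile model is a
per-nutrient threshold system with an ingredient-based exemption gate.
For a product with nutrient declaration per stated serving $s$ (g or
mL), category reference amount $R$ and evaluation basis $b$, the amount
of nutrient $x$ compared against its threshold is the linear rescaling
$x \cdot b / s$ — i.e. the comparison is really one of concentrations at
a standard consumption amount. The basis is

$$
b =
\begin{cases}
50\ \mathrm{g} & R \le 30\ \mathrm{g}\\
100\ \mathrm{g} & \text{main dish and } R \ge 200\ \mathrm{g}\\
\max(R, s) & \text{otherwise.}
\end{cases}
$$

The thresholds are 140 mg sodium, 5 g total sugars, and — on the sum of
saturated and trans fatty acids — 2 g together with 15 % of energy,
where the energy share $100 \cdot 9(\mathrm{SFA}+\mathrm{TFA})/E$ is a
per-serving ratio and therefore basis-invariant (the implementation
computes it on per-serving values for exactly that reason). Each
nutrient applies only to products containing the corresponding added
ingredient: added sodium, free sugars, or added fat. A product with none
of the three is exempt from all thresholds and hence always permitted,
whatever its composition — plain yogurt with 12 g of lactose per serving
is the canonical example.

### Boundary semantics

The thresholds are written as "low in" limits, so compliance is
inclusive at the gram limits (exactly 140 mg / 5 g / 2 g complies) but
exclusive at the energy share (compliance requires strictly less than
15 %; exactly 15 % exceeds). The reference-amount cutoffs are inclusive
the other way: an RA of exactly 30 g is a small-RA food, and a main dish
with an RA of exactly 200 g is assessed at 100 g. Comparisons use the
declared values as-is — no rounding before comparison — with a relative
tolerance of $10^{-9}$ whose only purpose is absorbing floating-point
noise from the rescaling arithmetic; it cannot move a declared value
across a boundary at any realistic declaration precision.

### Parameters

All constants live in one `npm_params()` record so that model variants
can be explored without touching the engine:

| parameter | default | unit | role |
|---|---|---|---|
| `sodium_max` | 140 | mg | sodium threshold at basis |
| `sugars_max` | 5 | g | total-sugars threshold at basis |
| `satfat_max` | 2 | g | SFA + TFA threshold at basis |
| `satfat_energy_max` | 15 | % energy | SFA + TFA energy-share limit |
| `small_ra_cutoff` / `small_ra_basis` | 30 / 50 | g | small-RA rule |
| `main_dish_ra_cutoff` / `main_dish_basis` | 200 / 100 | g | main-dish rule |
| `brand_unhealthy_cutoff` | 50 | % | mostly-unhealthy brand rule (inclusive) |
| `atwater_tolerance` | 0.20 | fraction | energy plausibility check |

## Design choices where the rule text is open

Several situations are not pinned down by the published rule text; the
package makes these choices and documents them here:

- **Main dish with RA < 200 g.** The main-dish rule only covers RAs of
  200 g and above; smaller main dishes fall through to the standard
  greater-of rule. This is the least-surprising reading: nothing in the
  text removes such foods from the default rule.
- **Millilitres.** mL reference amounts and servings are treated as
  numerically equivalent to grams (density 1) in basis arithmetic, as
  beverage reference amounts conventionally are. A real-data caller with
  dense syrups can supply gram servings instead.
- **Reference amounts.** The Table of Reference Amounts itself is not
  part of the model's rule text, so the package ships an editable CSV
  covering the in-scope minor categories and restaurant menu classes
  with realistic default values (e.g. 355 mL for carbonated beverages,
  175 g for yogurt, 250 g for a restaurant entree); users can and should
  override it with the official values for their categories.
- **Atwater check.** The plausibility check uses the general 4/4/9
  factors (protein/carbohydrate/fat) without fibre or alcohol
  adjustment, with a 20 % default tolerance; declarations where both
  declared and computed energy are below 5 kcal pass, since relative
  error is meaningless there. Records missing a macronutrient are "not
  assessable" and kept — only a demonstrated mismatch is evidence of
  inaccurate data.
- **Deduplication key.** "The exact same product collected from
  multiple stores" is operationalised as identity on (brand, name,
  serving size, category code), case-insensitive and
  whitespace-normalised. This deliberately keeps different package
  sizes and flavours (they differ in name or serving size) while
  collapsing store-level duplicates; the first listing in input order
  survives, making cleaning deterministic.
- **Missing trans fat** is imputed as 0 g with a warning rather than
  excluding the record; only missing sugars or saturated fat exclude,
  because those are required to apply the model at all. When both are
  missing, missing sugars is recorded as the primary reason.
- **Exemption gate without ingredient lists.** Restaurant items rarely
  carry ingredient lists. The gate is therefore tri-state with a
  conservative default: explicit flag columns win; otherwise lexicon
  detection on the ingredient text; otherwise a name-based allow-list of
  plainly unprocessed items (bottled water, apple slices) marks all
  three flags absent; and everything else defaults to *present* — an
  unlabelled processed item cannot reasonably be assumed free of added
  ingredients.
- **Lexicon mechanism.** Term matching is case-insensitive and
  word-boundary aware within comma-separated phrases, with negation
  handling ("unsalted", "no sugar added", a term preceded by "no"/
  "without" in the same phrase). The shipped term lists are seeded from
  the published example sources of added sodium, free sugars and added
  fat, and are avowedly incomplete: they are a transparent, editable
  mechanism standing in for expert analyst judgement, and will not
  reproduce every manual call on real ingredient lists.
- **Brand tallies.** The "majority exceed two thresholds" study tally
  counts products exceeding exactly two thresholds, reading "exceeded
  0, 1, 2 or 3" as a partition. Percentages are rounded half-up to one
  decimal only when written to disk; the 50 % cutoff is always compared
  against unrounded values. Study-level counts pool a brand's products
  across categories so that a brand present in several categories is
  one unique brand overall, while per-category tallies count it in each
  category it appears in.

## The synthetic-data generator

The generator exists because the branded food-composition databases this
kind of analysis runs on are proprietary. It emulates their *structure*,
not their contents: category profiles draw per-serving nutrient amounts
from log-normal distributions (non-negative and right-skewed, the shape
of real composition data), serving sizes near the category reference
amount, and added-ingredient flags from per-category probabilities.
Macronutrients are generated consistently (carbohydrate = sugars +
other carbohydrate; total fat = SFA + TFA + other fat) and energy is
computed from them with Atwater factors plus a small declaration noise,
so clean synthetic records pass the plausibility check by construction.
Ingredient texts are assembled so that a present flag always emits a
matching lexicon term and an absent flag never does, which is what makes
full-pipeline ground-truth recovery a meaningful test. Restaurant items
carry no ingredient text; a small fraction are allow-list items (bottled
water and similar) and the rest are processed items whose true flags are
all present, matching the conservative default.

The default profiles are calibrated to the qualitative category patterns
reported for Canadian branded foods — cereals frequently exceeding the
sugars and sodium thresholds but rarely saturated fat; beverages and
yogurts dominated by sugars (with sodium never a practical concern for
yogurt); restaurant menus dominated by sodium and saturated fat — and
only to those directions. Matching any published percentage is
explicitly a non-goal: the underlying data are unavailable, and fitting
the generator to headline numbers would only manufacture false
precision. Ground truth is derived at generation time by
`oracle_classify()`, a deliberately naive straight-line transcription of
the rules that shares no code with the engine; engine-vs-oracle
agreement is therefore a genuine two-route check.

What passing tests on synthetic data do **not** show: robustness to the
messiness of real ingredient lists (typography, bilingual lists,
compound ingredients), to serving sizes declared in pieces rather than
mass, or to category-assignment errors. Those failure modes need real
labelled data and are out of scope here.

### Artifact injection

`inject_artifacts()` plants the three defect types the cleaning stage
must catch — exact store duplicates, blanked sugars/saturated-fat
values, and energy declarations inflated far beyond the Atwater
tolerance (×3 + 100 kcal, unambiguous at any plausible energy) — in
disjoint record sets, so each planted record has exactly one expected
exclusion reason and the cleaning log can be compared against the
injection manifest record for record.

## Problem sizes and determinism

The test suite checks engine-oracle equivalence on a ~1000-product
batch, ground-truth recovery over ten generator seeds, and the boundary,
exemption, monotonicity and aggregation properties on randomized batches
of a thousand cases — sizes at which every property has been stable
across seeds while the whole suite runs in well under a minute on one
core. All generator randomness flows through an explicitly passed seed
into a private stream (`withr::with_seed`), so no call disturbs the
caller's RNG state and identical inputs always give byte-identical
outputs.

## Known limitations

- Results are per-product and unweighted; sales-weighting of brand
  portfolios is out of scope.
- The lexicon and allow-list are mechanisms, not authorities: real
  analyses should review and extend them, and can bypass them entirely
  via explicit flag columns.
- As-prepared evaluation uses whatever declaration the record carries
  (tagged `as_sold` / `as_prepared`); reconstructing as-prepared values
  from preparation instructions is the caller's responsibility.
- Multi-component restaurant meals must arrive pre-itemised, one record
  per component; the engine does not split combos.
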