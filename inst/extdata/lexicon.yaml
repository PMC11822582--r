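# Ingredient lexicon for added-sodium / free-sugar / added-fat detection.
# Terms are matched case-insensitively at word boundaries within each
# comma-separated phrase of an ingredient list. The lists are seeded from
# the examples in Health Canada's proposed marketing-to-children
# restrictions and are deliberately extensible: they stand in for expert
# judgement and will not reproduce every manual analyst call.
sodium_terms:
  - salt
  - sea salt
  - sodium
  - monosodium glutamate
  - sodium bicarbonate
  - sodium phosphate
  - sodium citrate
  - baking soda
  - baking powder
  - soy sauce
  - brine
  - cheese
  - salted nuts
  - salted peanuts
free_sugar_terms:
  - sugar
  - sugars
  - brown sugar
  - cane sugar
  - icing sugar
  - glucose
  - dextrose
  - fructose
  - sucrose
  - glucose-fructose
  - corn syrup
  - syrup
  - maple syrup
  - honey
  - molasses
  - fruit juice
  - juice concentrate
  - fruit juice concentrate
  - apple juice concentrate
  - grape juice concentrate
  - fruit puree
  - fruit purée
  - agave nectar
  - caramel
added_fat_terms:
  - oil
  - vegetable oil
  - canola oil
  - sunflower oil
  - soybean oil
  - olive oil
  - palm oil
  - palm kernel oil
  - coconut oil
  - butter
  - cocoa butter
  - margarine
  - shortening
  - lard
  - tallow
  - cream
  - animal fat
  - beef fat
  - chicken fat
# Phrases removed from the text before term matching: a term inside one
# of these never counts as a hit.
negation_exceptions:
  - unsalted
  - unsweetened
  - no salt added
  - no added salt
  - no sugar added
  - no added sugar
  - without added sugar
  - without salt
  - sugar-free
  - fat-free
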