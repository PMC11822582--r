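# Products (typically restaurant items without ingredient lists) that can
# reasonably be assumed to contain no added sodium, free sugars or added
# fat and are therefore exempt from all three thresholds. Patterns are
# matched case-insensitively against the product name.
patterns:
  - bottled water
  - spring water
  - sparkling water
  - carbonated water
  - apple slices
  - orange slices
  - plain milk
  - white milk
  - black coffee
  - plain tea
  - green tea
  - side of fruit
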