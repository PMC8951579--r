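# Report templates. Placeholders in {braces} must be ReportContext fields:
# record_id, location, texture, margin, size_mm, category.
default: findings
templates:
  findings: >-
    A {size_mm} {texture} nodule with {margin} margin in the {location}.
    Lung-RADS {category}.
  structured: |-
    FINDINGS
    Nodule ({record_id}): {texture} nodule, {size_mm}, located in the {location}.
    Margin: {margin}.
    IMPRESSION
    Lung-RADS {category}.
  oneline: >-
    {location}: {size_mm} {texture} nodule, {margin} margin, Lung-RADS {category}.
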