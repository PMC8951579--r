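# Lung-RADS assignment rules: ACR v1.1 baseline size cut-offs arranged in
# a texture/margin branch structure. Intervals are half-open [lo, hi) in mm.
version: "1.1-default"
rules:
  - texture: [Solid]
    margin: "*"
    size: [0, 6]
    category: "2"
  - texture: [Solid]
    margin: "*"
    size: [6, 8]
    category: "3"
  - texture: [Solid]
    margin: "*"
    size: [8, 15]
    category: "4A"
  - texture: [Solid]
    margin: "*"
    size: [15, .inf]
    category: "4B"
  - texture: [PureGGO]
    margin: "*"
    size: [0, 30]
    category: "2"
  - texture: [PureGGO]
    margin: "*"
    size: [30, .inf]
    category: "3"
  - texture: [Subsolid]
    margin: [SharpCircumscribed, Lobulated]
    size: [0, 6]
    category: "2"
  - texture: [Subsolid]
    margin: [SharpCircumscribed, Lobulated]
    size: [6, .inf]
    category: "3"
  - texture: [Subsolid]
    margin: [Spiculated, Indistinct]
    size: [0, 8]
    category: "4A"
  - texture: [Subsolid]
    margin: [Spiculated, Indistinct]
    size: [8, .inf]
    category: "4B"
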