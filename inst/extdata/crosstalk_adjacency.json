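{
  "comment": "anatomically adjacent electrode-site pairs used for the default cross-talk model; same-side pairs apply to both sides, midline pairs couple left and right",
  "same_side": [
    ["OOS", "OOI"],
    ["OOS", "LLSAN"],
    ["OOI", "MEN"],
    ["OOI", "DAO"],
    ["RIS", "ZYG"],
    ["ZYG", "LLSAN"],
    ["RIS", "DAO"],
    ["DAO", "MEN"]
  ],
  "midline": [
    ["OOS", "OOS"],
    ["OOI", "OOI"],
    ["MEN", "MEN"]
  ]
}
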