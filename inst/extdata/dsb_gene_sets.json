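{
  "description": "Curated double-strand break repair pathway gene sets (human reference symbols). Roles: determinant, protection, resection, SSA, add-resection. Aliases are protein names kept as metadata only; they are never used for expression-matrix lookup.",
  "species_reference": "human",
  "mouse_overrides": {
    "TP53BP1": "Trp53bp1",
    "MRE11": "Mre11a"
  },
  "sets": [
    {
      "name": "NHEJ",
      "pathway": "NHEJ",
      "members": [
        { "symbol": "XRCC5", "role": "determinant", "alias": "Ku80" },
        { "symbol": "XRCC6", "role": "determinant", "alias": "Ku70" },
        { "symbol": "TP53BP1", "role": "protection", "alias": null },
        { "symbol": "WRN", "role": "protection", "alias": null }
      ]
    },
    {
      "name": "MMEJ",
      "pathway": "MMEJ",
      "members": [
        { "symbol": "PARP1", "role": "determinant", "alias": null },
        { "symbol": "RBBP8", "role": "resection", "alias": "CtIP" },
        { "symbol": "MRE11", "role": "resection", "alias": null },
        { "symbol": "NBN", "role": "resection", "alias": null },
        { "symbol": "RAD50", "role": "resection", "alias": null }
      ]
    },
    {
      "name": "HDR",
      "pathway": "HDR",
      "members": [
        { "symbol": "BRCA1", "role": "determinant", "alias": null },
        { "symbol": "BRCA2", "role": "determinant", "alias": null },
        { "symbol": "RAD51", "role": "determinant", "alias": null },
        { "symbol": "PALB2", "role": "determinant", "alias": null },
        { "symbol": "RPA1", "role": "SSA", "alias": null },
        { "symbol": "RPA2", "role": "SSA", "alias": null },
        { "symbol": "EXO1", "role": "add-resection", "alias": null },
        { "symbol": "BLM", "role": "add-resection", "alias": null }
      ]
    }
  ]
}
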