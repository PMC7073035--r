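{
  "description": "SYNTHETIC STAND-IN retinal cell-type marker reference (human reference symbols). These are widely used canonical markers of major retinal cell classes, assembled for cluster annotation by marker overlap; they do not reproduce any specific published appendix table and are intended to be replaced by the user's own reference (GMT or JSON).",
  "species_reference": "human",
  "sets": [
    {
      "name": "progenitor",
      "pathway": "MARKER",
      "members": [
        { "symbol": "VSX2", "role": "none", "alias": null },
        { "symbol": "SOX2", "role": "none", "alias": null },
        { "symbol": "SFRP2", "role": "none", "alias": null },
        { "symbol": "LHX2", "role": "none", "alias": null },
        { "symbol": "PAX6", "role": "none", "alias": null },
        { "symbol": "CCND1", "role": "none", "alias": null },
        { "symbol": "HES1", "role": "none", "alias": null },
        { "symbol": "HES5", "role": "none", "alias": null }
      ]
    },
    {
      "name": "neuroblast",
      "pathway": "MARKER",
      "members": [
        { "symbol": "ATOH7", "role": "none", "alias": null },
        { "symbol": "NEUROD1", "role": "none", "alias": null },
        { "symbol": "NEUROG2", "role": "none", "alias": null },
        { "symbol": "HES6", "role": "none", "alias": null },
        { "symbol": "DLL1", "role": "none", "alias": null },
        { "symbol": "DLL3", "role": "none", "alias": null }
      ]
    },
    {
      "name": "rod",
      "pathway": "MARKER",
      "members": [
        { "symbol": "NRL", "role": "none", "alias": null },
        { "symbol": "NR2E3", "role": "none", "alias": null },
        { "symbol": "RHO", "role": "none", "alias": null },
        { "symbol": "GNAT1", "role": "none", "alias": null },
        { "symbol": "PDE6B", "role": "none", "alias": null },
        { "symbol": "CNGA1", "role": "none", "alias": null },
        { "symbol": "ROM1", "role": "none", "alias": null }
      ]
    },
    {
      "name": "cone",
      "pathway": "MARKER",
      "members": [
        { "symbol": "ARR3", "role": "none", "alias": null },
        { "symbol": "GNAT2", "role": "none", "alias": null },
        { "symbol": "PDE6H", "role": "none", "alias": null },
        { "symbol": "OPN1SW", "role": "none", "alias": null },
        { "symbol": "GNGT2", "role": "none", "alias": null }
      ]
    },
    {
      "name": "retinal_ganglion",
      "pathway": "MARKER",
      "members": [
        { "symbol": "POU4F2", "role": "none", "alias": null },
        { "symbol": "ISL1", "role": "none", "alias": null },
        { "symbol": "NEFL", "role": "none", "alias": null },
        { "symbol": "SNCG", "role": "none", "alias": null },
        { "symbol": "RBPMS", "role": "none", "alias": null }
      ]
    },
    {
      "name": "amacrine",
      "pathway": "MARKER",
      "members": [
        { "symbol": "TFAP2A", "role": "none", "alias": null },
        { "symbol": "TFAP2B", "role": "none", "alias": null },
        { "symbol": "GAD1", "role": "none", "alias": null },
        { "symbol": "SLC32A1", "role": "none", "alias": null },
        { "symbol": "CALB1", "role": "none", "alias": null }
      ]
    },
    {
      "name": "bipolar",
      "pathway": "MARKER",
      "members": [
        { "symbol": "VSX1", "role": "none", "alias": null },
        { "symbol": "GRM6", "role": "none", "alias": null },
        { "symbol": "PRKCA", "role": "none", "alias": null },
        { "symbol": "CABP5", "role": "none", "alias": null }
      ]
    },
    {
      "name": "muller",
      "pathway": "MARKER",
      "members": [
        { "symbol": "RLBP1", "role": "none", "alias": null },
        { "symbol": "GLUL", "role": "none", "alias": null },
        { "symbol": "APOE", "role": "none", "alias": null },
        { "symbol": "SLC1A3", "role": "none", "alias": null },
        { "symbol": "CLU", "role": "none", "alias": null }
      ]
    }
  ]
}
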