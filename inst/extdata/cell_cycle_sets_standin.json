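{
  "description": "SYNTHETIC STAND-IN cell-cycle phase gene sets (human reference symbols). The G2/M list approximates a 'top 20 G2/M-associated genes' panel and the S list a replication-machinery panel; both are conventional cell-cycle markers, not a copy of any published ranking, and are intended to be replaced by the user's preferred phase lists (GMT or JSON).",
  "species_reference": "human",
  "sets": [
    {
      "name": "G2M",
      "pathway": "CELL_CYCLE",
      "members": [
        { "symbol": "CCNB1", "role": "none", "alias": null },
        { "symbol": "CCNB2", "role": "none", "alias": null },
        { "symbol": "CDK1", "role": "none", "alias": null },
        { "symbol": "PLK1", "role": "none", "alias": null },
        { "symbol": "AURKA", "role": "none", "alias": null },
        { "symbol": "AURKB", "role": "none", "alias": null },
        { "symbol": "BUB1", "role": "none", "alias": null },
        { "symbol": "BUB1B", "role": "none", "alias": null },
        { "symbol": "CDC20", "role": "none", "alias": null },
        { "symbol": "CDC25C", "role": "none", "alias": null },
        { "symbol": "CENPA", "role": "none", "alias": null },
        { "symbol": "CENPE", "role": "none", "alias": null },
        { "symbol": "TOP2A", "role": "none", "alias": null },
        { "symbol": "KIF11", "role": "none", "alias": null },
        { "symbol": "KIF23", "role": "none", "alias": null },
        { "symbol": "MKI67", "role": "none", "alias": null },
        { "symbol": "NUSAP1", "role": "none", "alias": null },
        { "symbol": "TPX2", "role": "none", "alias": null },
        { "symbol": "UBE2C", "role": "none", "alias": null },
        { "symbol": "BIRC5", "role": "none", "alias": null }
      ]
    },
    {
      "name": "S",
      "pathway": "CELL_CYCLE",
      "members": [
        { "symbol": "MCM2", "role": "none", "alias": null },
        { "symbol": "MCM3", "role": "none", "alias": null },
        { "symbol": "MCM4", "role": "none", "alias": null },
        { "symbol": "MCM5", "role": "none", "alias": null },
        { "symbol": "MCM6", "role": "none", "alias": null },
        { "symbol": "MCM7", "role": "none", "alias": null },
        { "symbol": "PCNA", "role": "none", "alias": null },
        { "symbol": "RRM1", "role": "none", "alias": null },
        { "symbol": "RRM2", "role": "none", "alias": null },
        { "symbol": "CDC6", "role": "none", "alias": null },
        { "symbol": "CDC45", "role": "none", "alias": null },
        { "symbol": "GINS2", "role": "none", "alias": null }
      ]
    }
  ]
}
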