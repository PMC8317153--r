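{
  "version": "1.0",
  "note": "Fixed SMARTS panel of substructures recurrently reported as enriched in growth-inhibiting small molecules, plus generic scaffolds used as controls. Patterns encode the parent scaffolds; substitution is tolerated. Frequencies are per-molecule presence (a molecule counts once regardless of match multiplicity).",
  "patterns": [
    {"name": "naphthalene",     "smarts": "c1ccc2ccccc2c1",            "provenance": "polycyclic aromatic scaffold; derivatives reported to induce apoptosis in tumor cell lines"},
    {"name": "lactone",         "smarts": "[CX3;R](=O)[OX2;R]",        "provenance": "cyclic ester; lactone-bearing natural products with in vitro cytotoxic activity"},
    {"name": "n_methylaniline", "smarts": "c1ccccc1[NX3;H1][CH3]",     "provenance": "N-methyl aniline motif found in kinase-inhibitor chemotypes"},
    {"name": "quinoline",       "smarts": "c1ccc2ncccc2c1",            "provenance": "aromatic N-heterocycle; core of topoisomerase II inhibitors"},
    {"name": "benzene",         "smarts": "c1ccccc1",                  "provenance": "generic aromatic control (superset of naphthalene matches)"},
    {"name": "pyridine",        "smarts": "c1ccncc1",                  "provenance": "azine control; discriminative aromatic N feature"},
    {"name": "amide",           "smarts": "[NX3][CX3](=[OX1])",        "provenance": "carboxamide linkage; discriminative polar feature"}
  ]
}
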