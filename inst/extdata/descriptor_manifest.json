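{
  "version": "1.0",
  "note": "Ordered manifest of the 48 general physicochemical descriptors appended to the 216 distance-signature counts. Order is frozen; descriptor vectors are always emitted in this order.",
  "descriptors": [
    {"name": "mw",                 "unit": "g/mol", "description": "molecular weight (including hydrogens)"},
    {"name": "logp",               "unit": "",      "description": "octanol/water partition coefficient (atom-contribution estimate)"},
    {"name": "mr",                 "unit": "cm^3/mol", "description": "molar refractivity (atom-contribution estimate)"},
    {"name": "tpsa",               "unit": "A^2",   "description": "topological polar surface area"},
    {"name": "hbd",                "unit": "count", "description": "hydrogen-bond donor atoms (N/O with >=1 H)"},
    {"name": "hba",                "unit": "count", "description": "hydrogen-bond acceptor atoms (rule-based N/O)"},
    {"name": "rotatable_bonds",    "unit": "count", "description": "acyclic single bonds between non-terminal heavy atoms"},
    {"name": "ring_count",         "unit": "count", "description": "cyclomatic ring count (bonds - atoms + 1)"},
    {"name": "aromatic_ring_count","unit": "count", "description": "aromatic rings in the smallest set of smallest rings"},
    {"name": "aliphatic_ring_count","unit": "count","description": "non-aromatic rings in the smallest set of smallest rings"},
    {"name": "largest_ring_size",  "unit": "count", "description": "size of the largest SSSR ring (0 if acyclic)"},
    {"name": "heavy_atoms",        "unit": "count", "description": "number of heavy (non-hydrogen) atoms"},
    {"name": "n_carbon",           "unit": "count", "description": "carbon atoms"},
    {"name": "n_nitrogen",         "unit": "count", "description": "nitrogen atoms"},
    {"name": "n_oxygen",           "unit": "count", "description": "oxygen atoms"},
    {"name": "n_sulfur",           "unit": "count", "description": "sulfur atoms"},
    {"name": "n_phosphorus",       "unit": "count", "description": "phosphorus atoms"},
    {"name": "n_fluorine",         "unit": "count", "description": "fluorine atoms"},
    {"name": "n_chlorine",         "unit": "count", "description": "chlorine atoms"},
    {"name": "n_bromine",          "unit": "count", "description": "bromine atoms"},
    {"name": "n_iodine",           "unit": "count", "description": "iodine atoms"},
    {"name": "n_halogen",          "unit": "count", "description": "halogen atoms (F+Cl+Br+I)"},
    {"name": "n_heteroatoms",      "unit": "count", "description": "non-carbon heavy atoms"},
    {"name": "n_bonds",            "unit": "count", "description": "heavy-atom bonds"},
    {"name": "n_single_bonds",     "unit": "count", "description": "single bonds (kekulized)"},
    {"name": "n_double_bonds",     "unit": "count", "description": "double bonds (kekulized)"},
    {"name": "n_triple_bonds",     "unit": "count", "description": "triple bonds"},
    {"name": "n_aromatic_atoms",   "unit": "count", "description": "atoms in aromatic rings"},
    {"name": "frac_aromatic_atoms","unit": "fraction", "description": "aromatic atoms / heavy atoms"},
    {"name": "n_ring_atoms",       "unit": "count", "description": "atoms in any ring"},
    {"name": "frac_ring_atoms",    "unit": "fraction", "description": "ring atoms / heavy atoms"},
    {"name": "n_sp3_carbon",       "unit": "count", "description": "sp3 carbons"},
    {"name": "n_sp2_carbon",       "unit": "count", "description": "sp2 carbons (incl. aromatic)"},
    {"name": "n_sp_carbon",        "unit": "count", "description": "sp carbons"},
    {"name": "fraction_csp3",      "unit": "fraction", "description": "sp3 carbons / all carbons (0 if no carbon)"},
    {"name": "n_degree1",          "unit": "count", "description": "terminal heavy atoms (degree 1)"},
    {"name": "n_degree2",          "unit": "count", "description": "heavy atoms of degree 2"},
    {"name": "n_degree3",          "unit": "count", "description": "heavy atoms of degree 3"},
    {"name": "n_degree4",          "unit": "count", "description": "heavy atoms of degree >= 4"},
    {"name": "mean_degree",        "unit": "",      "description": "mean heavy-atom degree"},
    {"name": "graph_diameter",     "unit": "edges", "description": "largest shortest-path distance between two atoms"},
    {"name": "mean_pair_distance", "unit": "edges", "description": "mean shortest-path distance over all atom pairs (0 for single atom)"},
    {"name": "wiener_index",       "unit": "edges", "description": "sum of shortest-path distances over unordered atom pairs"},
    {"name": "total_h_count",      "unit": "count", "description": "total attached hydrogens (implicit + explicit)"},
    {"name": "formal_charge",      "unit": "e",     "description": "net formal charge"},
    {"name": "abs_charge_sum",     "unit": "e",     "description": "sum of absolute formal charges"},
    {"name": "mw_per_heavy_atom",  "unit": "g/mol", "description": "molecular weight / heavy atom count"},
    {"name": "lipinski_violations","unit": "count", "description": "violations of MW<=500, logP<=5, HBD<=5, HBA<=10"}
  ]
}
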