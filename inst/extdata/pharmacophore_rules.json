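{
  "version": "1.0",
  "note": "Reconstructed 8-class pharmacophore alphabet (pkCSM lineage). Classes are assigned to heavy atoms by the structural rules below, evaluated on the parsed molecular graph (element, aromatic flag, formal charge, attached hydrogen count, neighbor environment). A single atom may carry several classes or none.",
  "alphabet": [
    "Hydrophobe",
    "Aromatic",
    "Donor",
    "Acceptor",
    "PosIonizable",
    "NegIonizable",
    "Halogen",
    "Sulfur"
  ],
  "rules": {
    "Hydrophobe": "carbon atom whose heavy-atom neighbors are all carbon",
    "Aromatic": "atom that is a member of at least one aromatic ring (SSSR aromaticity perception)",
    "Donor": "nitrogen or oxygen bearing at least one attached hydrogen (implicit or explicit)",
    "Acceptor": "oxygen with formal charge <= 0; or nitrogen with no attached hydrogen, formal charge <= 0, no N=O double bond (excludes nitro), and no carbonyl-carbon neighbor (excludes tertiary amide)",
    "PosIonizable": "any atom with formal charge > 0; or a non-aromatic amine nitrogen: all single bonds, no neighbor carbon or sulfur double-bonded to O or S (excludes amide/sulfonamide), no aromatic neighbor (excludes aniline-type N)",
    "NegIonizable": "any atom with formal charge < 0; or an acidic hydroxyl oxygen: O with one hydrogen single-bonded to a C, S or P atom that is double-bonded to another oxygen",
    "Halogen": "fluorine, chlorine, bromine or iodine",
    "Sulfur": "sulfur atom"
  }
}
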