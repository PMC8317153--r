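# Molecular graph construction, pharmacophore typing and descriptors.

test_that("simple molecules parse to the expected heavy-atom graphs", {
  propane <- parse_smiles("CCC", "propane")
  expect_equal(nrow(propane$atoms), 3)
  expect_equal(nrow(propane$bonds), 2)
  expect_equal(sort(propane$atoms$degree), c(1, 1, 2))

  benzene <- parse_smiles("c1ccccc1", "benzene")
  expect_equal(nrow(benzene$atoms), 6)
  expect_equal(nrow(benzene$bonds), 6)
  expect_true(all(benzene$atoms$is_aromatic))
  expect_equal(length(benzene$rings), 1)
})

test_that("largest covalent fragment is kept and counter-ions dropped", {
  g <- parse_smiles("CC.[Na+]", "salt")
  expect_equal(g$atoms$element, c("C", "C"))
  expect_equal(nrow(g$bonds), 1)
  # order of fragments must not matter
  g2 <- parse_smiles("[Na+].CC", "salt2")
  expect_equal(g2$canonical_smiles, g$canonical_smiles)
})

test_that("unparsable and empty inputs are rejected with context", {
  expect_error(parse_smiles("C1CC", "bad"), "bad")
  expect_error(parse_smiles("not_a_smiles", "junk"), "junk")
  expect_error(parse_smiles("", "empty"), "non-empty")
  expect_error(parse_smiles("[H][H]", "h2"), "heavy")
})

test_that("canonical SMILES round-trips to an identical graph", {
  for (smi in c("CC(=O)Oc1ccccc1C(=O)O", "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
                "O=C1CCCO1")) {
    g1 <- parse_smiles(smi, "m")
    g2 <- parse_smiles(g1$canonical_smiles, "m")
    expect_equal(g2$canonical_smiles, g1$canonical_smiles)
    expect_equal(nrow(g2$atoms), nrow(g1$atoms))
    expect_equal(nrow(g2$bonds), nrow(g1$bonds))
  }
})

test_that("pharmacophore rules give the documented assignments", {
  benzene <- assign_pharmacophores(parse_smiles("c1ccccc1", "benzene"))
  for (lab in benzene$labels) {
    expect_setequal(lab, c("Hydrophobe", "Aromatic"))
  }
  methanol <- parse_smiles("CO", "methanol")
  o <- which(methanol$atoms$element == "O")
  expect_setequal(assign_pharmacophores(methanol)$labels[[o]],
                  c("Donor", "Acceptor"))
  ethylamine <- parse_smiles("CCN", "ethylamine")
  n <- which(ethylamine$atoms$element == "N")
  expect_setequal(assign_pharmacophores(ethylamine)$labels[[n]],
                  c("Donor", "PosIonizable"))
  # pyridine N: aromatic acceptor, no H
  pyridine <- parse_smiles("c1ccncc1", "pyridine")
  n <- which(pyridine$atoms$element == "N")
  expect_setequal(assign_pharmacophores(pyridine)$labels[[n]],
                  c("Aromatic", "Acceptor"))
})

test_that("pharmacophore assignment is invariant to SMILES atom ordering", {
  pairs <- list(c("CCO", "OCC"),
                c("c1ccccc1CN", "NCc1ccccc1"),
                c("CC(=O)Oc1ccccc1C(=O)O", "OC(=O)c1ccccc1OC(C)=O"))
  for (p in pairs) {
    l1 <- assign_pharmacophores(parse_smiles(p[1], "a"))$labels
    l2 <- assign_pharmacophores(parse_smiles(p[2], "b"))$labels
    key <- function(l) sort(vapply(l, paste, character(1), collapse = ";"))
    expect_equal(key(l1), key(l2))
  }
})

test_that("descriptor block follows the 48-name manifest and hand counts", {
  benzene <- compute_descriptors(parse_smiles("c1ccccc1", "benzene"))
  expect_length(benzene$values, 48)
  expect_identical(names(benzene$values), descriptor_manifest()$name)
  expect_equal(benzene$values[["ring_count"]], 1)
  expect_equal(benzene$values[["hbd"]], 0)
  expect_equal(benzene$values[["heavy_atoms"]], 6)
  expect_equal(benzene$values[["aromatic_ring_count"]], 1)

  glycine <- compute_descriptors(parse_smiles("NCC(=O)O", "glycine"))
  expect_gte(glycine$values[["hbd"]], 2)
  expect_gte(glycine$values[["hba"]], 2)
  expect_true(all(is.finite(glycine$values)))
})

test_that("descriptors are deterministic across repeated calls", {
  g <- parse_smiles("CC(C)Cc1ccc(cc1)C(C)C(=O)O", "ibuprofen")
  expect_identical(compute_descriptors(g)$values, compute_descriptors(g)$values)
})

test_that("implicit hydrogen counts respect charge-adjusted valence", {
  amm <- parse_smiles("C[NH3+]", "methylammonium")
  n <- which(amm$atoms$element == "N")
  expect_equal(amm$atoms$n_h[n], 3L)
  expect_equal(amm$atoms$formal_charge[n], 1L)
  ace <- parse_smiles("CC(=O)[O-]", "acetate")
  om <- which(ace$atoms$formal_charge == -1L)
  expect_equal(ace$atoms$n_h[om], 0L)
})
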