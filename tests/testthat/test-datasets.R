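# Activity labeling, GI50 curation and non-redundant splitting.

toy_records <- function() {
  tibble::tibble(
    mol_id = c("inact", "act", "mid", "offdose", "neg", "hot"),
    assay = c("one_dose", "dose_response", "one_dose", "one_dose",
              "one_dose", "dose_response"),
    mean_inhibition = c(3, 60, 30, 2, -15, 140),
    dose = c(1e-5, 1e-5, 1e-5, 1e-6, 1e-5, 1e-5))
}

test_that("activity thresholds label the toy table exactly", {
  lab <- label_activity(toy_records())
  expect_equal(lab$label[lab$mol_id == "inact"], "inactive")
  expect_equal(lab$label[lab$mol_id == "act"], "active")
  expect_equal(lab$label[lab$mol_id == "mid"], "unlabeled")
  # evidence at a different dose does not trigger either rule
  expect_equal(lab$label[lab$mol_id == "offdose"], "unlabeled")
  # negative inhibition (growth stimulation) is inactive; >100% is active
  expect_equal(lab$label[lab$mol_id == "neg"], "inactive")
  expect_equal(lab$label[lab$mol_id == "hot"], "active")
})

test_that("threshold boundaries are exclusive", {
  rec <- tibble::tibble(mol_id = c("five", "fifty"),
                        assay = c("one_dose", "dose_response"),
                        mean_inhibition = c(5, 50), dose = 1e-5)
  lab <- label_activity(rec)
  expect_true(all(lab$label == "unlabeled"))
})

test_that("conflicting evidence excludes the molecule with a warning", {
  rec <- tibble::tibble(mol_id = "both",
                        assay = c("one_dose", "dose_response"),
                        mean_inhibition = c(2, 70), dose = 1e-5)
  expect_warning(lab <- label_activity(rec), "conflict")
  expect_false("both" %in% lab$mol_id)
  expect_equal(attr(lab, "conflicts"), "both")
})

test_that("labeling is idempotent and order-invariant", {
  rec <- toy_records()
  l1 <- label_activity(rec)
  l2 <- label_activity(rec[sample(nrow(rec)), ])
  expect_equal(dplyr::arrange(l1, mol_id), dplyr::arrange(l2, mol_id))
})

test_that("GI50 curation averages replicates on the -log scale", {
  rows <- tibble::tibble(mol_id = c("m1", "m1", "m2"),
                         cell_line = c("MCF7", "MCF7", "MCF7"),
                         neglog_gi50 = c(5, 6, 7.2))
  cur <- curate_gi50(rows)
  expect_equal(cur$neglog_gi50[cur$mol_id == "m1"], 5.5)
  expect_equal(cur$neglog_gi50[cur$mol_id == "m2"], 7.2)
  # conservation: one row per distinct (mol_id, cell_line) pair
  expect_equal(nrow(cur), 2)
})

test_that("GI50 curation splits per cell line and buckets unknown names", {
  rows <- tibble::tibble(mol_id = rep(c("a", "b"), 2),
                         cell_line = c("MCF7", "MCF7", "A549", "WEIRD"),
                         neglog_gi50 = c(5, 6, 4, 8))
  expect_warning(cur <- curate_gi50(rows, known_cell_lines = c("MCF7", "A549")),
                 "misc")
  expect_setequal(unique(cur$cell_line), c("MCF7", "A549", "misc"))
  per <- curate_gi50(rows, per_cell_line = TRUE)
  expect_setequal(names(per), c("MCF7", "A549", "WEIRD"))
  expect_equal(sum(vapply(per, nrow, integer(1))), 4)
})

test_that("identical molecules share a cluster and a partition side", {
  tbl <- tibble::tibble(
    smiles = c("CCO", "OCC", "c1ccccc1", "CCCCCCCCCC", "NCCCCN",
               "c1ccc2ccccc2c1", "CC(=O)OC", "ClCCl", "C1CCCCC1", "CC#N"),
    mol_id = sprintf("m%02d", 1:10))
  sp <- cluster_and_split(tbl, seed = 1)
  a <- sp$assignments
  expect_equal(a$cluster_id[a$mol_id == "m01"], a$cluster_id[a$mol_id == "m02"])
  expect_equal(a$partition[a$mol_id == "m01"], a$partition[a$mol_id == "m02"])
})

test_that("mutually dissimilar molecules become singletons split 8/2", {
  tbl <- tibble::tibble(
    smiles = c("CCCCCCCCCC", "c1ccc2ccccc2c1", "OC(=O)CCC(=O)O", "ClC(Cl)(Cl)Cl",
               "NCCCCCCN", "c1ccncc1", "CC(C)(C)C(=O)N", "O=S(=O)(O)c1ccccc1",
               "C1CCOC1", "CC#CC#N"),
    mol_id = sprintf("d%02d", 1:10))
  # oracle: verify pairwise Tanimoto is below threshold before trusting the split
  sdf <- ChemmineR::smiles2sdf(setNames(tbl$smiles, tbl$mol_id))
  fp <- ChemmineR::fingerprintOB(sdf, "ECFP4")
  for (i in 1:9) {
    sims <- ChemmineR::fpSim(fp[i], fp, method = "Tanimoto", sorted = FALSE)
    expect_true(all(sims[-i] < 0.6), label = sprintf("row %d dissimilar", i))
  }
  sp <- cluster_and_split(tbl, seed = 1)
  expect_equal(length(unique(sp$assignments$cluster_id)), 10)
  expect_equal(sum(sp$assignments$partition == "train"), 8)
  expect_equal(sum(sp$assignments$partition == "blind"), 2)
})

test_that("clusters are never divided across partitions", {
  study <- synthetic_study(n = 1000, seed = 42)
  sp <- cluster_and_split(study$molecules[1:300, c("smiles", "mol_id")], seed = 42)
  sides <- tapply(sp$assignments$partition, sp$assignments$cluster_id,
                  function(x) length(unique(x)))
  expect_true(all(sides == 1))
  expect_lt(abs(sp$realized_fraction - 0.8), 0.05)
})

test_that("degenerate all-identical input lands wholly in train with a warning", {
  tbl <- tibble::tibble(smiles = rep("c1ccccc1", 5), mol_id = sprintf("b%d", 1:5))
  expect_warning(sp <- cluster_and_split(tbl, seed = 1), "blind set is empty")
  expect_true(all(sp$assignments$partition == "train"))
  expect_equal(length(unique(sp$assignments$cluster_id)), 1)
})
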