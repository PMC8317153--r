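# molsig

Graph-based molecular signatures for modeling anticancer bioactivity.

Medicinal chemists and cheminformaticians screening small molecules
against tumor cell-line panels (NCI-60-style growth-inhibition data) need
interpretable features that link structure to activity. molsig provides
the full desk-scale workflow: a fixed 264-dimensional, fully named feature
vector per molecule; screening-rule activity labeling; leakage-free
train/blind splitting; greedy feature selection; ensemble-tree
classification and per-cell-line GI50 regression; and substructure /
property enrichment analyses. A synthetic-data generator with a planted
substructure–activity relationship makes the whole pipeline testable
without any external downloads.

## The signature

A molecule is its heavy-atom graph with unit bond weights; the distance
between atoms i and j is the edge count of their shortest path, d(i, j)
(breadth-first search from every atom, the unit-weight special case of
Johnson's algorithm). Each atom carries a subset of the 8-class
pharmacophore alphabet {Hydrophobe, Aromatic, Donor, Acceptor,
PosIonizable, NegIonizable, Halogen, Sulfur}. For every unordered class
pair (A, B) and cutoff k ∈ {1, …, 6},

    Sig:A:B:dk = #{ {i, j} : i ≠ j, d(i, j) ≤ k, A ∈ L(i), B ∈ L(j) (or swapped) }

— the cumulative distribution of class-pair distances. 36 pairs × 6
cutoffs = 216 counts, plus 48 general physicochemical descriptors
(`descriptor_manifest()`), gives 264 features, frozen in order and name.

Activity labels follow the screening rules: mean one-dose growth
inhibition < 5% at 10⁻⁵ mol ⇒ inactive; mean dose-response inhibition
> 50% at 10⁻⁵ mol ⇒ active; in between ⇒ unlabeled. Splits cluster
molecules with the Butina algorithm on circular (ECFP4) fingerprints at
Tanimoto 0.6 and assign whole clusters to train (80%) or blind (20%), so
near-duplicates never straddle the boundary.

## Worked example

```r
library(molsig)
library(dplyr)

cfg   <- generator_config(n_molecules = 200, seed = 7)
mols  <- generate_molecules(cfg)
lab   <- generate_labels(mols, cfg)
feats <- featurize_batch(mols[, c("smiles", "mol_id")])
dim(feats)
#> [1] 200 265          # mol_id + 264 features

sp <- cluster_and_split(mols[, c("smiles", "mol_id")], seed = 7)
glance(sp)
#>   n_molecules n_clusters threshold fraction_train realized_fraction
#> 1         200         94       0.6            0.8               0.8

df    <- left_join(feats, lab$labels[, c("mol_id", "label")], by = "mol_id")
train <- df[df$mol_id %in% tidy(sp)$mol_id[tidy(sp)$partition == "train"], ]
blind <- df[!df$mol_id %in% train$mol_id, ]

sel <- greedy_select(train, "label", "classification", cv_folds = 3,
                     patience = 2, max_features = 5, num_trees = 50, seed = 7)
tidy(sel)
#>    step feature                  metric
#> 1     1 n_sp2_carbon              0.935
#> 2     2 graph_diameter            0.943
#> 3     3 Sig:Aromatic:Aromatic:d3  0.953
#> 4     4 Sig:Aromatic:Acceptor:d2  0.961
#> 5     5 logp                      0.962

fit <- train_model(train, "label", "classification",
                   features = sel$best_set, seed = 7)
evaluate_metrics(as.integer(blind$label == "active"),
                 predict(fit, blind)$.pred, "classification")
#>    n accuracy precision sensitivity    fpr   mcc   auc
#> 1 40     0.85     0.778       0.636 0.0690 0.607 0.890
```

The selection trace is readable chemistry: sp2-carbon and diameter terms
capture overall aromatic bulk, and the `Sig:Aromatic:Aromatic:d3` /
`Sig:Aromatic:Acceptor:d2` counts are exactly the fused-aromatic and
aromatic-nitrogen patterns of the planted naphthalene/quinoline signal.
On the held-out blind set the 5-feature random forest reaches AUC 0.89.

The enrichment view of the same data ranks the planted scaffolds first:

```r
fragment_frequencies(mols$smiles[lab$labels$active],
                     mols$smiles[!lab$labels$active])
#>   pattern     freq_active freq_inactive
#> 1 quinoline          57.3          3.60
#> 2 naphthalene        55.1          9.91
#> 3 benzene            97.8          37.8
#> 4 pyridine           60.7          29.7
```

A command-line interface wrapping the same functions ships in
`inst/cli/molsig` (subcommands: simulate, featurize, label, split,
select, train, predict, evaluate, enrich).

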