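# Synthetic molecule tables with a planted, tunable substructure-activity
# relationship. Molecules are assembled by hanging 1-4 vocabulary fragments
# off a saturated carbon backbone (single C-C bonds at sp3/aryl carbons),
# which keeps every assembly valence-valid; activity follows a logistic
# model in the number of planted "active" fragments, and per-cell-line
# GI50 values follow a linear model with Gaussian noise on the
# -log10(molar) scale.

# Vocabulary fragments are written so that "C(<fragment>)" is always a valid
# branch: the first atom of each fragment can accept one extra single bond.
.DEFAULT_VOCAB <- c(
  naphthalene     = "c1ccc2ccccc2c1",
  quinoline       = "c1ccc2ncccc2c1",
  lactone         = "C1CC(=O)OC1",
  n_methylaniline = "CNc1ccccc1",
  amide           = "C(N)=O",
  benzene         = "c1ccccc1",
  pyridine        = "c1ccncc1",
  hydroxymethyl   = "CO",
  isopropyl       = "CC(C)C",
  trifluoromethyl = "C(F)(F)F",
  chloro          = "Cl",
  dimethylamino   = "CN(C)C"
)

#' Generator configuration
#'
#' Defines the study conditions for the synthetic dataset: the fragment
#' vocabulary, which fragments carry the planted activity signal, the
#' strength of that signal on the logistic (classification) and linear
#' (GI50 regression) scales, and the noise level. Active fragments are
#' sampled with twice the weight of decorations so that the planted signal
#' is well represented.
#'
#' @param n_molecules Number of molecules (>= 10).
#' @param fragment_vocab Named character vector of attachable fragment
#'   SMILES.
#' @param active_fragments Names of vocabulary entries that carry the
#'   planted effect.
#' @param active_weight Sampling weight of active fragments relative to 1
#'   for the rest.
#' @param base_active_prob Baseline P(active) for a molecule with no active
#'   fragment.
#' @param fragment_effect Log-odds increment per planted fragment.
#' @param gi50_base Baseline -log10(molar) GI50.
#' @param gi50_effect GI50 increment per planted fragment.
#' @param noise_sd Gaussian noise SD on the GI50 scale.
#' @param cell_lines Cell-line names for which GI50 values are emitted.
#' @param seed Random seed.
#' @return A list of class `molsig_genconfig`.
#' @export
generator_config <- function(n_molecules = 500,
                             fragment_vocab = .DEFAULT_VOCAB,
                             active_fragments = c("naphthalene", "quinoline"),
                             active_weight = 2,
                             base_active_prob = 0.05,
                             fragment_effect = 4.0,
                             gi50_base = 5.0,
                             gi50_effect = 0.5,
                             noise_sd = 0.3,
                             cell_lines = c("MCF7", "A549", "HCT116"),
                             seed = 42) {
  stopifnot(n_molecules >= 10,
            base_active_prob >= 0, base_active_prob <= 1,
            all(active_fragments %in% names(fragment_vocab)),
            noise_sd >= 0, active_weight > 0)
  structure(list(
    n_molecules = as.integer(n_molecules), fragment_vocab = fragment_vocab,
    active_fragments = active_fragments, active_weight = active_weight,
    base_active_prob = base_active_prob, fragment_effect = fragment_effect,
    gi50_base = gi50_base, gi50_effect = gi50_effect, noise_sd = noise_sd,
    cell_lines = cell_lines, seed = as.integer(seed)
  ), class = "molsig_genconfig")
}

#' Generate synthetic molecules
#'
#' Each molecule joins 1-4 vocabulary fragments, each hung off a backbone
#' sp3 carbon by a single bond. Every emitted SMILES is checked to
#' re-parse; the rare invalid assembly is resampled (bounded retries).
#' Output is deterministic for a given seed.
#'
#' @param config A [generator_config()].
#' @return Tibble: `mol_id`, `smiles`, `n_fragments`, `fragments`
#'   (list-column of fragment names) and `n_active_fragments` (the planted
#'   ground truth used by [generate_labels()]).
#' @export
generate_molecules <- function(config) {
  stopifnot(inherits(config, "molsig_genconfig"))
  vocab <- config$fragment_vocab
  w <- ifelse(names(vocab) %in% config$active_fragments,
              config$active_weight, 1)
  set.seed(config$seed)
  rows <- vector("list", config$n_molecules)
  for (i in seq_len(config$n_molecules)) {
    smiles <- NULL
    for (try_i in 1:5) {
      nf <- sample(1:4, 1)
      frags <- sample(names(vocab), nf, replace = TRUE, prob = w)
      cand <- paste0(vapply(vocab[frags], function(f) paste0("C(", f, ")"),
                            character(1)), collapse = "")
      ok <- tryCatch({.ob_sdfset(cand, sprintf("syn%05d", i)); TRUE},
                     error = function(e) FALSE)
      if (ok) { smiles <- cand; break }
    }
    if (is.null(smiles)) {
      abort(sprintf("could not assemble a valid molecule at index %d", i))
    }
    rows[[i]] <- tibble(
      mol_id = sprintf("syn%05d", i), smiles = smiles,
      n_fragments = length(frags), fragments = list(frags),
      n_active_fragments = sum(frags %in% config$active_fragments))
  }
  bind_rows(rows)
}

#' Generate activity labels and per-cell-line GI50 values
#'
#' Plants the signal: P(active) = logistic(logit(base_active_prob) +
#' fragment_effect * n_active_fragments), and per cell line
#' neglog_gi50 = gi50_base + gi50_effect * n_active_fragments +
#' Normal(0, noise_sd). Also emits growth-inhibition activity records in
#' the schema [label_activity()] reads (dose-response evidence above the
#' activity threshold for actives, one-dose evidence below the inactivity
#' threshold for inactives), so synthetic fixtures and real exports are
#' interchangeable.
#'
#' @param table Output of [generate_molecules()].
#' @param config The same [generator_config()].
#' @return A list of tibbles: `labels` (`mol_id`, `active`, `label`,
#'   `p_active`, `n_active_fragments`), `gi50` (`mol_id`, `cell_line`,
#'   `neglog_gi50`), `activity_records` (`mol_id`, `assay`,
#'   `mean_inhibition`, `dose`).
#' @export
generate_labels <- function(table, config) {
  stopifnot(inherits(config, "molsig_genconfig"),
            is.data.frame(table), "n_active_fragments" %in% names(table))
  set.seed(config$seed + 1L)
  k <- table$n_active_fragments
  p <- plogis(qlogis(config$base_active_prob) + config$fragment_effect * k)
  active <- rbinom(nrow(table), 1, p) == 1
  labels <- tibble(mol_id = table$mol_id, active = active,
                   label = ifelse(active, "active", "inactive"),
                   p_active = p, n_active_fragments = k)
  gi50 <- tidyr::expand_grid(mol_id = table$mol_id,
                             cell_line = config$cell_lines) |>
    left_join(tibble(mol_id = table$mol_id, k = k), by = "mol_id") |>
    mutate(neglog_gi50 = config$gi50_base + config$gi50_effect * .data$k +
             rnorm(n(), 0, config$noise_sd)) |>
    select("mol_id", "cell_line", "neglog_gi50")
  activity_records <- tibble(
    mol_id = table$mol_id,
    assay = ifelse(active, "dose_response", "one_dose"),
    mean_inhibition = ifelse(active, runif(nrow(table), 55, 98),
                             runif(nrow(table), -10, 4.5)),
    dose = 1e-5)
  list(labels = labels, gi50 = gi50, activity_records = activity_records)
}
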