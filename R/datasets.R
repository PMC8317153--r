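# Activity labeling from growth-inhibition evidence, GI50 curation, and
# non-redundant train/blind splitting via Butina clustering on circular
# (ECFP4) fingerprints.

#' Label molecules active/inactive from growth-inhibition records
#'
#' Applies the two NCI-60-style screening rules at the target dose
#' (default 1e-5 mol): a molecule is *inactive* when its mean one-dose
#' growth inhibition is below 5%, and *active* when its mean dose-response
#' growth inhibition is above 50%. Boundary values are exclusive. Molecules
#' matched by neither rule are *unlabeled*; molecules matched by both are
#' conflicts, excluded with a warning. Labeling is idempotent and invariant
#' to record order.
#'
#' @param records Data frame with columns `mol_id`, `assay` (`"one_dose"` or
#'   `"dose_response"`), `mean_inhibition` (percent; may be negative or
#'   exceed 100) and `dose` (mol).
#' @param dose_target Dose at which the rules apply, in mol.
#' @param inactive_below One-dose inactivity threshold (percent).
#' @param active_above Dose-response activity threshold (percent).
#' @return Tibble with columns `mol_id`, `label`
#'   (`"active"`/`"inactive"`/`"unlabeled"`). Conflicted molecules are
#'   dropped; their ids are attached as attribute `"conflicts"`.
#' @export
#' @examples
#' label_activity(tibble::tibble(
#'   mol_id = c("a", "b", "c"),
#'   assay = c("one_dose", "dose_response", "one_dose"),
#'   mean_inhibition = c(3, 60, 30), dose = 1e-5))
label_activity <- function(records, dose_target = 1e-5,
                           inactive_below = 5, active_above = 50) {
  stopifnot(is.data.frame(records))
  needed <- c("mol_id", "assay", "mean_inhibition", "dose")
  if (!all(needed %in% names(records))) {
    abort(sprintf("`records` must have columns %s", paste(needed, collapse = ", ")))
  }
  bad <- setdiff(unique(records$assay), c("one_dose", "dose_response"))
  if (length(bad) > 0) {
    abort(sprintf("unknown assay type(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(records$dose <= 0)) abort("doses must be positive")

  at_dose <- records |>
    filter(abs(.data$dose - dose_target) <= 1e-12 * max(dose_target, 1))
  per <- at_dose |>
    group_by(.data$mol_id, .data$assay) |>
    summarise(mean_inh = mean(.data$mean_inhibition), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "assay", values_from = "mean_inh")
  if (!"one_dose" %in% names(per)) per$one_dose <- NA_real_
  if (!"dose_response" %in% names(per)) per$dose_response <- NA_real_

  per <- per |>
    mutate(
      is_inactive = !is.na(.data$one_dose) & .data$one_dose < inactive_below,
      is_active = !is.na(.data$dose_response) & .data$dose_response > active_above)
  conflicts <- per$mol_id[per$is_inactive & per$is_active]
  if (length(conflicts) > 0) {
    warn(sprintf("conflicting activity evidence; excluded: %s",
                 paste(conflicts, collapse = ", ")))
  }
  out <- per |>
    filter(!(.data$is_inactive & .data$is_active)) |>
    mutate(label = dplyr::case_when(
      .data$is_active ~ "active",
      .data$is_inactive ~ "inactive",
      TRUE ~ "unlabeled")) |>
    select("mol_id", "label")
  # molecules with records only at other doses stay unlabeled
  missing <- setdiff(unique(records$mol_id), c(out$mol_id, conflicts))
  if (length(missing) > 0) {
    out <- bind_rows(out, tibble(mol_id = missing, label = "unlabeled"))
  }
  out <- arrange(out, match(.data$mol_id, unique(records$mol_id)))
  attr(out, "conflicts") <- conflicts
  out
}

#' Curate per-cell-line GI50 tables
#'
#' Combines replicate (molecule, cell line) measurements by arithmetic mean
#' on the -log10(molar) scale. Optionally routes unrecognized cell-line
#' names into a `"misc"` bucket.
#'
#' @param rows Data frame with columns `mol_id`, `cell_line`, `neglog_gi50`.
#' @param known_cell_lines Optional character vector of accepted cell-line
#'   names; anything else is relabeled `"misc"` with a warning.
#' @param per_cell_line If `TRUE`, return a named list of per-cell-line
#'   tibbles instead of one long tibble.
#' @return Tibble (`mol_id`, `cell_line`, `neglog_gi50`, `n_obs`) with one
#'   row per (molecule, cell line) pair, or a named list of such tibbles.
#' @export
curate_gi50 <- function(rows, known_cell_lines = NULL, per_cell_line = FALSE) {
  stopifnot(is.data.frame(rows))
  needed <- c("mol_id", "cell_line", "neglog_gi50")
  if (!all(needed %in% names(rows))) {
    abort(sprintf("`rows` must have columns %s", paste(needed, collapse = ", ")))
  }
  if (any(!is.finite(rows$neglog_gi50))) abort("neglog_gi50 must be finite")
  if (!is.null(known_cell_lines)) {
    unknown <- setdiff(unique(rows$cell_line), known_cell_lines)
    if (length(unknown) > 0) {
      warn(sprintf("unknown cell line(s) routed to 'misc': %s",
                   paste(unknown, collapse = ", ")))
      rows <- mutate(rows, cell_line = ifelse(
        .data$cell_line %in% known_cell_lines, .data$cell_line, "misc"))
    }
  }
  out <- rows |>
    group_by(.data$mol_id, .data$cell_line) |>
    summarise(neglog_gi50 = mean(.data$neglog_gi50), n_obs = n(),
              .groups = "drop") |>
    arrange(.data$cell_line, .data$mol_id)
  if (per_cell_line) {
    return(split(out, out$cell_line))
  }
  out
}

# ECFP4 fingerprints for a vector of SMILES (already parsed/validated);
# returns a ChemmineR FPset.
.fingerprints <- function(smiles, mol_id) {
  sdfset <- ChemmineR::smiles2sdf(setNames(smiles, mol_id))
  ChemmineR::fingerprintOB(sdfset, "ECFP4")
}

# Pairwise Tanimoto similarity matrix from an FPset.
.tanimoto_matrix <- function(fpset) {
  n <- length(ChemmineR::cid(fpset))
  sim <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sim[i, ] <- ChemmineR::fpSim(fpset[i], fpset, method = "Tanimoto",
                                 sorted = FALSE)
  }
  diag(sim) <- 1
  (sim + t(sim)) / 2  # guard against asymmetric rounding
}

# Butina leader clustering: candidate centroids ordered by descending
# neighbor count (ties: lexicographic mol_id); each centroid claims its
# still-unassigned neighbors.
.butina <- function(sim, mol_id, threshold) {
  n <- nrow(sim)
  nbrs <- lapply(seq_len(n), function(i) {
    setdiff(which(sim[i, ] >= threshold), i)
  })
  ord <- order(-lengths(nbrs), mol_id)
  cluster <- rep(NA_integer_, n)
  k <- 0L
  for (c0 in ord) {
    if (!is.na(cluster[c0])) next
    k <- k + 1L
    members <- c(c0, nbrs[[c0]][is.na(cluster[nbrs[[c0]]])])
    cluster[members] <- k
  }
  cluster
}

#' Cluster molecules and split into non-redundant train/blind partitions
#'
#' Clusters molecules with the Butina leader algorithm on circular (ECFP4)
#' fingerprints at the given Tanimoto similarity threshold, then assigns
#' whole clusters greedily (largest first) to whichever partition is
#' furthest below its quota. Similar molecules therefore never straddle the
#' train/blind boundary.
#'
#' @param data Data frame with columns `smiles`, `mol_id`.
#' @param threshold Tanimoto similarity at/above which molecules are
#'   considered redundant (default 0.6).
#' @param fraction_train Target train fraction (default 0.8).
#' @param seed Recorded for provenance; the procedure itself is
#'   deterministic (centroid and cluster orderings are fully tie-broken).
#' @return An object of class `molsig_split`: list with `assignments`
#'   (tibble: `mol_id`, `cluster_id`, `partition`), `threshold`,
#'   `fraction_train`, `realized_fraction`, `seed`.
#' @export
cluster_and_split <- function(data, threshold = 0.6, fraction_train = 0.8,
                              seed = 42) {
  stopifnot(is.data.frame(data))
  if (!all(c("smiles", "mol_id") %in% names(data))) {
    abort("`data` must have columns `smiles` and `mol_id`")
  }
  if (nrow(data) < 2) abort("need at least 2 molecules to split")
  if (anyDuplicated(data$mol_id)) abort("mol_id values must be unique")

  parsed <- map_chr(seq_len(nrow(data)), function(i) {
    parse_smiles(data$smiles[i], data$mol_id[i])$canonical_smiles
  })
  fpset <- .fingerprints(parsed, data$mol_id)
  sim <- .tanimoto_matrix(fpset)
  cluster <- .butina(sim, data$mol_id, threshold)

  sizes <- table(cluster)
  ord <- order(-as.integer(sizes),
               vapply(names(sizes), function(k) {
                 min(data$mol_id[cluster == as.integer(k)])
               }, character(1)))
  n <- nrow(data)
  quota <- c(train = fraction_train * n, blind = (1 - fraction_train) * n)
  assigned <- c(train = 0, blind = 0)
  side <- setNames(character(length(sizes)), names(sizes))
  for (k in names(sizes)[ord]) {
    deficit <- quota - assigned
    pick <- if (deficit["train"] >= deficit["blind"]) "train" else "blind"
    side[k] <- pick
    assigned[pick] <- assigned[pick] + as.integer(sizes[k])
  }
  partition <- unname(side[as.character(cluster)])
  if (all(partition == "train")) {
    warn("all molecules fell in one partition; blind set is empty")
  }
  realized <- mean(partition == "train")

  structure(list(
    assignments = tibble(mol_id = data$mol_id, cluster_id = cluster,
                         partition = partition),
    threshold = threshold, fraction_train = fraction_train,
    realized_fraction = realized, seed = seed,
    fingerprint = "ECFP4 (OpenBabel, 4096 bits)"
  ), class = "molsig_split")
}

#' @export
print.molsig_split <- function(x, ...) {
  cat(sprintf(paste0("<molsig_split> %d molecules, %d clusters | train %.1f%%",
                     " (target %.0f%%) | Tanimoto >= %.2f on %s\n"),
              nrow(x$assignments), length(unique(x$assignments$cluster_id)),
              100 * x$realized_fraction, 100 * x$fraction_train,
              x$threshold, x$fingerprint))
  invisible(x)
}

#' @method tidy molsig_split
#' @export
tidy.molsig_split <- function(x, ...) x$assignments

#' @method glance molsig_split
#' @export
glance.molsig_split <- function(x, ...) {
  tibble(n_molecules = nrow(x$assignments),
         n_clusters = length(unique(x$assignments$cluster_id)),
         threshold = x$threshold,
         fraction_train = x$fraction_train,
         realized_fraction = x$realized_fraction)
}

#' Cluster-size plot for a dataset split
#'
#' @param object A `molsig_split`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot molsig_split
#' @export
autoplot.molsig_split <- function(object, ...) {
  sizes <- object$assignments |>
    count(.data$cluster_id, .data$partition, name = "size")
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size, fill = .data$partition)) +
    ggplot2::geom_histogram(binwidth = 1, position = "stack") +
    ggplot2::labs(x = "cluster size", y = "clusters",
                  title = "Butina cluster sizes by partition") +
    ggplot2::theme_minimal()
}
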