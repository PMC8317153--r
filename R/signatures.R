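# Graph-based signatures: cumulative counts of pharmacophore-class atom
# pairs within increasing shortest-path distance cutoffs, concatenated with
# the 48-descriptor block into the frozen 264-long feature vector.

.CUTOFFS <- 1:6

#' All-pairs shortest-path distance matrix of a molecular graph
#'
#' Edge-count distances on the heavy-atom graph. All edges carry unit
#' weight, so Johnson's algorithm reduces to a breadth-first search from
#' every atom; distances are exact integers.
#'
#' @param graph A `molsig_graph` (single connected fragment; enforced at
#'   parse time).
#' @return Integer matrix `n_atoms x n_atoms`, zero diagonal, symmetric.
#' @export
#' @examples
#' shortest_path_matrix(parse_smiles("CCC"))[1, 3]
shortest_path_matrix <- function(graph) {
  stopifnot(inherits(graph, "molsig_graph"))
  if (igraph::components(graph$graph)$no != 1) {
    abort(sprintf("disconnected graph for '%s'; largest-fragment selection must run first",
                  graph$mol_id))
  }
  d <- igraph::distances(graph$graph, algorithm = "unweighted")
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

#' Cumulative pharmacophore-pair distance counts
#'
#' The 216-entry signature block. Entry (A, B, k) counts unordered pairs of
#' distinct atoms \{i, j\} such that one atom carries class A, the other
#' class B, and their shortest-path distance is at most k edges. A pair of
#' atoms is counted once per class pair however many of their class
#' combinations map to it, and an atom never pairs with itself. Entries are
#' non-decreasing in k by construction.
#'
#' @param dist Distance matrix from [shortest_path_matrix()].
#' @param labels A `molsig_pharm` from [assign_pharmacophores()].
#' @return Named numeric vector of length 216 (36 class pairs x 6 cutoffs),
#'   in frozen feature order.
#' @export
signature_counts <- function(dist, labels) {
  stopifnot(inherits(labels, "molsig_pharm"))
  m <- labels$class_matrix
  n <- nrow(m)
  if (n != nrow(dist)) {
    abort("distance matrix and pharmacophore assignment disagree on atom count")
  }
  cls <- colnames(m)
  ncut <- length(.CUTOFFS)
  out <- numeric(0)
  upper <- upper.tri(dist)
  for (a in seq_along(cls)) {
    for (b in a:length(cls)) {
      # unordered pairs {i, j}: class a on one end, class b on the other
      pair_ok <- (outer(m[, a], m[, b], "&") | outer(m[, b], m[, a], "&")) & upper
      dd <- dist[pair_ok]
      counts <- vapply(.CUTOFFS, function(k) sum(dd <= k), numeric(1))
      names(counts) <- sprintf("Sig:%s:%s:d%d", cls[a], cls[b], .CUTOFFS)
      out <- c(out, counts)
    }
  }
  out
}

#' Assemble the full 264-dimensional feature vector for one molecule
#'
#' Concatenates the 216 signature counts and the 48 descriptors in the
#' frozen manifest order. Missing intermediate results are computed on the
#' fly. The result is deterministic and invariant to the atom ordering of
#' the input SMILES.
#'
#' @param graph A `molsig_graph`.
#' @param labels Optional `molsig_pharm`; computed if `NULL`.
#' @param descriptors Optional `molsig_desc`; computed if `NULL`.
#' @return A one-row tibble: `mol_id` followed by the 264 feature columns.
#' @export
#' @examples
#' ncol(featurize(parse_smiles("c1ccccc1"))) - 1
featurize <- function(graph, labels = NULL, descriptors = NULL) {
  stopifnot(inherits(graph, "molsig_graph"))
  labels <- labels %||% assign_pharmacophores(graph)
  descriptors <- descriptors %||% compute_descriptors(graph)
  if (!identical(labels$mol_id, graph$mol_id) ||
      !identical(descriptors$mol_id, graph$mol_id)) {
    abort("mol_id mismatch between graph, labels and descriptors")
  }
  sig <- signature_counts(shortest_path_matrix(graph), labels)
  v <- c(sig, descriptors$values)
  expected <- feature_names()
  if (length(v) != length(expected) || !identical(names(v), expected)) {
    abort("internal: assembled feature vector does not match the frozen layout")
  }
  bind_cols(tibble(mol_id = graph$mol_id), as_tibble(as.list(v)))
}

#' Featurize a table of molecules
#'
#' Maps [featurize()] over a SMILES table. Molecules that fail to parse or
#' featurize are collected into a failure report instead of aborting the
#' batch; successful rows keep the input order.
#'
#' @param data A data frame with columns `smiles` and `mol_id`.
#' @return A tibble with `mol_id` plus 264 feature columns, one row per
#'   successful molecule. The failure report (tibble: `mol_id`, `smiles`,
#'   `error`) is attached as attribute `"failures"`.
#' @export
#' @examples
#' res <- featurize_batch(tibble::tibble(smiles = c("CCO", "c1ccccc1"),
#'                                       mol_id = c("a", "b")))
#' dim(res)
featurize_batch <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("smiles", "mol_id") %in% names(data))) {
    abort("`data` must have columns `smiles` and `mol_id`")
  }
  dup <- unique(data$mol_id[duplicated(data$mol_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate mol_id(s): %s", paste(head(dup, 10), collapse = ", ")))
  }
  rows <- vector("list", nrow(data))
  fails <- list()
  for (i in seq_len(nrow(data))) {
    res <- tryCatch(
      featurize(parse_smiles(data$smiles[i], data$mol_id[i])),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <- tibble(
        mol_id = data$mol_id[i], smiles = data$smiles[i],
        error = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- as_tibble(setNames(
      c(list(character(0)), rep(list(numeric(0)), length(feature_names()))),
      c("mol_id", feature_names())))
  }
  failures <- if (length(fails)) bind_rows(fails) else
    tibble(mol_id = character(0), smiles = character(0), error = character(0))
  if (nrow(failures) > 0) {
    warn(sprintf("%d molecule(s) failed featurization; see attr(., \"failures\")",
                 nrow(failures)))
  }
  attr(out, "failures") <- failures
  out
}

#' Failure report of a featurized batch
#'
#' @param x Result of [featurize_batch()].
#' @return Tibble with columns `mol_id`, `smiles`, `error`.
#' @export
featurize_failures <- function(x) {
  attr(x, "failures") %||%
    tibble(mol_id = character(0), smiles = character(0), error = character(0))
}

#' Signature heatmap for one molecule
#'
#' Displays the 216 signature counts as a class-pair by distance-cutoff
#' heatmap.
#'
#' @param features One row of a feature table from [featurize()] /
#'   [featurize_batch()].
#' @return A ggplot object.
#' @export
plot_signature <- function(features) {
  stopifnot(is.data.frame(features), nrow(features) == 1)
  sig_cols <- grep("^Sig:", names(features), value = TRUE)
  long <- tibble(name = sig_cols,
                 value = as.numeric(features[1, sig_cols])) |>
    tidyr::separate_wider_delim("name", ":", names = c("tag", "class_a", "class_b", "cutoff")) |>
    mutate(pair = paste(.data$class_a, .data$class_b, sep = ":"),
           cutoff = as.integer(sub("^d", "", .data$cutoff)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$pair,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "pairs") +
    ggplot2::labs(x = "distance cutoff (edges)", y = "class pair",
                  title = features$mol_id[1]) +
    ggplot2::theme_minimal(base_size = 9)
}
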