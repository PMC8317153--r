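# Heavy-atom molecular graphs from SMILES, pharmacophore atom typing, and
# general physicochemical descriptors. Parsing and canonicalization go through
# ChemmineR/ChemmineOB (OpenBabel); everything downstream operates on the
# plain atoms/bonds tables built here.

# MDL ctab charge codes -> formal charge
.MDL_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# standard valences used to infer implicit hydrogen counts
.VALENCE <- list(C = 4L, N = 3L, O = 2L, F = 1L, Cl = 1L, Br = 1L, I = 1L,
                 S = c(2L, 4L, 6L), P = c(3L, 5L), B = 3L, Si = 4L,
                 Se = c(2L, 4L, 6L), As = c(3L, 5L))

.ob_sdfset <- function(smiles, mol_id = "mol") {
  res <- try(suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, mol_id))),
             silent = TRUE)
  if (inherits(res, "try-error")) {
    abort(sprintf("unparsable SMILES for '%s': \"%s\" (%s)",
                  mol_id, smiles, trimws(attr(res, "condition")$message)))
  }
  res
}

.sdf_heavy_count <- function(sdf) {
  el <- sub("_\\d+$", "", rownames(ChemmineR::atomblock(sdf)))
  sum(el != "H")
}

# implicit hydrogens from standard valence, charge-adjusted
.implicit_h <- function(element, charge, bond_order_sum) {
  val <- .VALENCE[[element]]
  if (is.null(val)) return(0L)
  val <- switch(element,
    C = val - abs(charge),
    N = , P = , O = , S = , Se = , As = val + charge,
    val)
  val <- val[val >= bond_order_sum]
  if (length(val) == 0) return(0L)
  as.integer(min(val) - bond_order_sum)
}

# Largest covalent fragment of a (possibly dotted) SMILES, by heavy-atom
# count; ties broken by lexicographically smallest canonical SMILES.
# Returns list(smiles = kept fragment SMILES, sdfset = its SDFset).
.select_fragment <- function(smiles, mol_id) {
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) abort(sprintf("empty SMILES for '%s'", mol_id))
  if (length(parts) == 1) {
    return(list(smiles = parts, sdfset = .ob_sdfset(parts, mol_id)))
  }
  sdfs <- lapply(parts, .ob_sdfset, mol_id = mol_id)
  heavy <- vapply(sdfs, function(s) .sdf_heavy_count(s[[1]]), integer(1))
  if (max(heavy) == 0) {
    abort(sprintf("no heavy atoms left after fragment selection for '%s'", mol_id))
  }
  ties <- which(heavy == max(heavy))
  if (length(ties) > 1) {
    cans <- vapply(ties, function(i) {
      as.character(ChemmineOB::prop_OB(
        ChemmineOB::forEachMol("SMILES", parts[i], identity))$cansmiNS)
    }, character(1))
    ties <- ties[order(cans)][1]
  }
  list(smiles = parts[ties[1]], sdfset = sdfs[[ties[1]]])
}

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Sanitizes the input with OpenBabel, keeps the largest covalent fragment
#' (ties broken by lexicographically smallest canonical SMILES), strips
#' hydrogens into per-atom attached-H counts, perceives rings and
#' aromaticity, and returns the molecule as plain atoms/bonds tables plus an
#' igraph handle. All bonds carry unit weight for distance purposes;
#' stereochemistry is ignored (shortest-path topology is stereo-blind).
#'
#' @param smiles A single SMILES string.
#' @param mol_id Identifier carried through all downstream tables.
#' @return An object of class `molsig_graph`: a list with `mol_id`,
#'   `canonical_smiles`, `atoms` (tibble: `index` (1-based), `element`,
#'   `formal_charge`, `is_aromatic`, `in_ring`, `n_h`, `degree`), `bonds`
#'   (tibble: `i`, `j` with `i < j`, `order`, `in_ring`), `rings` (list of
#'   atom-index vectors for the smallest set of smallest rings, with a
#'   logical `aromatic` attribute), `ob` (OpenBabel-derived scalar
#'   properties) and `graph` (igraph).
#' @export
#' @examples
#' g <- parse_smiles("c1ccccc1", "benzene")
#' nrow(g$atoms)
parse_smiles <- function(smiles, mol_id = "mol") {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(trimws(smiles))) {
    abort("`smiles` must be a single non-empty string")
  }
  smiles <- trimws(smiles)
  frag <- .select_fragment(smiles, mol_id)
  sdf <- frag$sdfset[[1]]

  ab <- ChemmineR::atomblock(sdf)
  elements <- sub("_\\d+$", "", rownames(ab))
  n_all <- length(elements)
  charge_code <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else integer(n_all)
  charges <- unname(.MDL_CHARGE[as.character(pmin(pmax(charge_code, 0L), 7L))])
  charges[is.na(charges)] <- 0L

  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1, dimnames = list(NULL, names(bb)))
  ok_rows <- ncol(bb) >= 3 & nrow(bb) > 0
  if (ok_rows) {
    keep <- bb[, 1] >= 1 & bb[, 2] >= 1
    bb <- bb[keep, , drop = FALSE]
  }
  has_bonds <- ok_rows && nrow(bb) > 0
  bi <- if (has_bonds) as.integer(bb[, 1]) else integer(0)
  bj <- if (has_bonds) as.integer(bb[, 2]) else integer(0)
  border <- if (has_bonds) as.integer(bb[, 3]) else integer(0)

  # fold explicit hydrogens into attached-H counts of their heavy neighbor
  is_h <- elements == "H"
  explicit_h <- integer(n_all)
  keep_bond <- rep(TRUE, length(bi))
  for (b in seq_along(bi)) {
    hi <- is_h[bi[b]]; hj <- is_h[bj[b]]
    if (hi || hj) {
      keep_bond[b] <- FALSE
      heavy <- if (hi) bj[b] else bi[b]
      if (!is_h[heavy]) explicit_h[heavy] <- explicit_h[heavy] + 1L
    }
  }
  keep_atom <- which(!is_h)
  if (length(keep_atom) == 0) {
    abort(sprintf("no heavy atoms in '%s' (\"%s\")", mol_id, smiles))
  }
  new_index <- match(seq_len(n_all), keep_atom)
  bi2 <- new_index[bi[keep_bond]]; bj2 <- new_index[bj[keep_bond]]
  border2 <- border[keep_bond]
  swap <- bi2 > bj2
  tmp <- bi2[swap]; bi2[swap] <- bj2[swap]; bj2[swap] <- tmp

  n <- length(keep_atom)
  bond_sum <- numeric(n)
  deg <- integer(n)
  for (b in seq_along(bi2)) {
    bond_sum[bi2[b]] <- bond_sum[bi2[b]] + border2[b]
    bond_sum[bj2[b]] <- bond_sum[bj2[b]] + border2[b]
    deg[bi2[b]] <- deg[bi2[b]] + 1L
    deg[bj2[b]] <- deg[bj2[b]] + 1L
  }
  el <- elements[keep_atom]
  chg <- charges[keep_atom]
  exp_h <- explicit_h[keep_atom]
  n_h <- vapply(seq_len(n), function(i) {
    .implicit_h(el[i], chg[i], bond_sum[i] + exp_h[i]) + exp_h[i]
  }, integer(1))

  # ring perception (SSSR) + aromaticity on the original SDF numbering
  ring_atoms_new <- list()
  ring_arom <- logical(0)
  has_cycle <- length(bi2) - n + 1L >= 1L
  if (has_cycle) {
    rr <- try(suppressWarnings(
      ChemmineR::rings(sdf, type = "all", arom = TRUE, inner = TRUE)),
      silent = TRUE)
    if (!inherits(rr, "try-error") && length(rr$RINGS) > 0) {
      orig_idx <- function(nm) as.integer(sub("^.*_", "", nm))
      ring_atoms_new <- lapply(rr$RINGS, function(r) sort(new_index[orig_idx(r)]))
      ring_arom <- as.logical(rr$AROMATIC)
    }
  }
  is_aromatic <- rep(FALSE, n)
  in_ring <- rep(FALSE, n)
  for (k in seq_along(ring_atoms_new)) {
    in_ring[ring_atoms_new[[k]]] <- TRUE
    if (isTRUE(ring_arom[k])) is_aromatic[ring_atoms_new[[k]]] <- TRUE
  }
  ring_sets <- lapply(ring_atoms_new, as.integer)
  bond_in_ring <- vapply(seq_along(bi2), function(b) {
    any(vapply(ring_sets, function(r) bi2[b] %in% r && bj2[b] %in% r, logical(1)))
  }, logical(1))

  props <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", frag$smiles, identity))

  atoms <- tibble(index = seq_len(n), element = el, formal_charge = chg,
                  is_aromatic = is_aromatic, in_ring = in_ring,
                  n_h = as.integer(n_h), degree = deg)
  bonds <- tibble(i = bi2, j = bj2, order = border2,
                  in_ring = if (length(bi2)) bond_in_ring else logical(0))

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0) {
    g <- igraph::add_edges(g, rbind(bonds$i, bonds$j))
  }
  if (igraph::components(g)$no != 1) {
    abort(sprintf("internal: fragment selection left a disconnected graph for '%s'", mol_id))
  }

  structure(list(
    mol_id = mol_id,
    canonical_smiles = as.character(props$cansmi),
    atoms = atoms,
    bonds = bonds,
    rings = structure(ring_sets, aromatic = ring_arom),
    ob = list(mw = props$MW, logp = props$logP, mr = props$MR,
              tpsa = props$TPSA, formula = as.character(props$formula)),
    graph = g
  ), class = "molsig_graph")
}

#' @export
print.molsig_graph <- function(x, ...) {
  cat(sprintf("<molsig_graph> %s: %d atoms, %d bonds, %d rings | %s\n",
              x$mol_id, nrow(x$atoms), nrow(x$bonds), length(x$rings),
              x$canonical_smiles))
  invisible(x)
}

#' @method tidy molsig_graph
#' @export
tidy.molsig_graph <- function(x, ...) x$atoms

# Per-atom logical class matrix (n_atoms x 8), shared by pharmacophore
# assignment and the hbd/hba descriptors.
.atom_class_matrix <- function(graph) {
  at <- graph$atoms
  bd <- graph$bonds
  n <- nrow(at)
  cls <- pharmacophore_classes()
  m <- matrix(FALSE, n, length(cls), dimnames = list(NULL, cls))
  if (n == 0) return(m)

  nbrs <- vector("list", n)
  nbr_order <- vector("list", n)
  if (nrow(bd) > 0) {
    for (b in seq_len(nrow(bd))) {
      nbrs[[bd$i[b]]] <- c(nbrs[[bd$i[b]]], bd$j[b])
      nbrs[[bd$j[b]]] <- c(nbrs[[bd$j[b]]], bd$i[b])
      nbr_order[[bd$i[b]]] <- c(nbr_order[[bd$i[b]]], bd$order[b])
      nbr_order[[bd$j[b]]] <- c(nbr_order[[bd$j[b]]], bd$order[b])
    }
  }
  el <- at$element
  has_double_to <- function(i, elems) {
    k <- which(nbr_order[[i]] == 2L)
    length(k) > 0 && any(el[nbrs[[i]][k]] %in% elems)
  }
  # neighbor that is a carbonyl/thiocarbonyl carbon or S/P bearing =O
  has_acyl_neighbor <- function(i) {
    for (jj in nbrs[[i]]) {
      if (el[jj] %in% c("C", "S", "P") && has_double_to(jj, c("O", "S"))) return(TRUE)
    }
    FALSE
  }

  for (i in seq_len(n)) {
    e <- el[i]; q <- at$formal_charge[i]; h <- at$n_h[i]
    nb <- nbrs[[i]]
    all_single <- length(nbr_order[[i]]) == 0 || all(nbr_order[[i]] == 1L)

    if (e == "C" && (length(nb) == 0 || all(el[nb] == "C"))) m[i, "Hydrophobe"] <- TRUE
    if (at$is_aromatic[i]) m[i, "Aromatic"] <- TRUE
    if (e %in% c("N", "O") && h >= 1) m[i, "Donor"] <- TRUE
    if (e == "O" && q <= 0) m[i, "Acceptor"] <- TRUE
    if (e == "N" && h == 0 && q <= 0 && !has_double_to(i, "O") &&
        !has_acyl_neighbor(i)) m[i, "Acceptor"] <- TRUE
    if (q > 0) m[i, "PosIonizable"] <- TRUE
    if (e == "N" && !at$is_aromatic[i] && all_single && q == 0 &&
        !has_acyl_neighbor(i) &&
        (length(nb) == 0 || !any(at$is_aromatic[nb]))) m[i, "PosIonizable"] <- TRUE
    if (q < 0) m[i, "NegIonizable"] <- TRUE
    if (e == "O" && h == 1 && q == 0 && has_acyl_neighbor(i)) m[i, "NegIonizable"] <- TRUE
    if (e %in% c("F", "Cl", "Br", "I")) m[i, "Halogen"] <- TRUE
    if (e == "S") m[i, "Sulfur"] <- TRUE
  }
  m
}

#' Assign pharmacophore classes to the atoms of a molecular graph
#'
#' Labels every heavy atom with a (possibly empty) subset of the fixed
#' 8-class alphabet (see [pharmacophore_classes()]), using the structural
#' rule table shipped in the package configuration. Assignment is
#' deterministic and invariant to the atom ordering of the input SMILES.
#'
#' @param graph A `molsig_graph` from [parse_smiles()].
#' @return An object of class `molsig_pharm`: list with `mol_id`, `labels`
#'   (list of character vectors, one per atom, in alphabet order) and
#'   `class_matrix` (atoms x classes logical matrix).
#' @export
#' @examples
#' assign_pharmacophores(parse_smiles("c1ccccc1"))$labels[[1]]
assign_pharmacophores <- function(graph) {
  stopifnot(inherits(graph, "molsig_graph"))
  m <- .atom_class_matrix(graph)
  labels <- lapply(seq_len(nrow(m)), function(i) colnames(m)[m[i, ]])
  structure(list(mol_id = graph$mol_id, labels = labels, class_matrix = m),
            class = "molsig_pharm")
}

#' @export
print.molsig_pharm <- function(x, ...) {
  cat(sprintf("<molsig_pharm> %s: %d atoms, %d class assignments\n",
              x$mol_id, length(x$labels), sum(x$class_matrix)))
  invisible(x)
}

#' @method tidy molsig_pharm
#' @export
tidy.molsig_pharm <- function(x, ...) {
  tibble(index = seq_along(x$labels),
         labels = map_chr(x$labels, paste, collapse = ";"))
}

#' Compute the general physicochemical descriptor block
#'
#' Evaluates the 48 descriptors of the frozen manifest (see
#' [descriptor_manifest()]): OpenBabel contribution-based estimates (MW,
#' logP, molar refractivity, TPSA) plus graph-derived counts and topology
#' terms. Values are returned in manifest order; repeated calls on the same
#' graph are byte-identical.
#'
#' @param graph A `molsig_graph`.
#' @return An object of class `molsig_desc`: list with `mol_id` and `values`
#'   (named numeric vector of length 48).
#' @export
#' @examples
#' compute_descriptors(parse_smiles("c1ccccc1"))$values[["ring_count"]]
compute_descriptors <- function(graph) {
  stopifnot(inherits(graph, "molsig_graph"))
  at <- graph$atoms
  bd <- graph$bonds
  n <- nrow(at)
  cm <- .atom_class_matrix(graph)

  hbd <- sum(at$element %in% c("N", "O") & at$n_h >= 1)
  hba <- sum(cm[, "Acceptor"])

  # carbon hybridization from kekulized bond orders
  csp <- function(i) {
    ords <- c(bd$order[bd$i == i], bd$order[bd$j == i])
    if (at$is_aromatic[i]) return("sp2")
    if (any(ords == 3L) || sum(ords == 2L) >= 2) return("sp")
    if (any(ords == 2L)) return("sp2")
    "sp3"
  }
  carb <- which(at$element == "C")
  hyb <- vapply(carb, csp, character(1))

  rot <- if (nrow(bd)) sum(bd$order == 1L & !bd$in_ring &
                           at$degree[bd$i] > 1 & at$degree[bd$j] > 1) else 0L
  ring_count <- nrow(bd) - n + 1L
  arom_rings <- sum(attr(graph$rings, "aromatic") %||% logical(0))
  d <- igraph::distances(graph$graph)
  pair_d <- d[upper.tri(d)]
  wiener <- sum(pair_d)

  mw <- as.numeric(graph$ob$mw)
  logp <- as.numeric(graph$ob$logp)
  lip <- sum(mw > 500, logp > 5, hbd > 5, hba > 10)

  v <- c(
    mw = mw,
    logp = logp,
    mr = as.numeric(graph$ob$mr),
    tpsa = as.numeric(graph$ob$tpsa),
    hbd = hbd,
    hba = hba,
    rotatable_bonds = rot,
    ring_count = ring_count,
    aromatic_ring_count = arom_rings,
    aliphatic_ring_count = max(ring_count - arom_rings, 0),
    largest_ring_size = if (length(graph$rings)) max(lengths(graph$rings)) else 0,
    heavy_atoms = n,
    n_carbon = sum(at$element == "C"),
    n_nitrogen = sum(at$element == "N"),
    n_oxygen = sum(at$element == "O"),
    n_sulfur = sum(at$element == "S"),
    n_phosphorus = sum(at$element == "P"),
    n_fluorine = sum(at$element == "F"),
    n_chlorine = sum(at$element == "Cl"),
    n_bromine = sum(at$element == "Br"),
    n_iodine = sum(at$element == "I"),
    n_halogen = sum(at$element %in% c("F", "Cl", "Br", "I")),
    n_heteroatoms = sum(at$element != "C"),
    n_bonds = nrow(bd),
    n_single_bonds = sum(bd$order == 1L),
    n_double_bonds = sum(bd$order == 2L),
    n_triple_bonds = sum(bd$order == 3L),
    n_aromatic_atoms = sum(at$is_aromatic),
    frac_aromatic_atoms = sum(at$is_aromatic) / n,
    n_ring_atoms = sum(at$in_ring),
    frac_ring_atoms = sum(at$in_ring) / n,
    n_sp3_carbon = sum(hyb == "sp3"),
    n_sp2_carbon = sum(hyb == "sp2"),
    n_sp_carbon = sum(hyb == "sp"),
    fraction_csp3 = if (length(carb)) sum(hyb == "sp3") / length(carb) else 0,
    n_degree1 = sum(at$degree == 1L),
    n_degree2 = sum(at$degree == 2L),
    n_degree3 = sum(at$degree == 3L),
    n_degree4 = sum(at$degree >= 4L),
    mean_degree = mean(at$degree),
    graph_diameter = if (length(pair_d)) max(pair_d) else 0,
    mean_pair_distance = if (length(pair_d)) mean(pair_d) else 0,
    wiener_index = wiener,
    total_h_count = sum(at$n_h),
    formal_charge = sum(at$formal_charge),
    abs_charge_sum = sum(abs(at$formal_charge)),
    mw_per_heavy_atom = mw / n,
    lipinski_violations = lip
  )
  manifest <- descriptor_manifest()$name
  if (!identical(names(v), manifest)) {
    abort("internal: descriptor values do not match the manifest order")
  }
  if (any(!is.finite(v))) {
    abort(sprintf("non-finite descriptor(s) for '%s': %s", graph$mol_id,
                  paste(names(v)[!is.finite(v)], collapse = ", ")))
  }
  structure(list(mol_id = graph$mol_id, values = v), class = "molsig_desc")
}

#' @export
print.molsig_desc <- function(x, ...) {
  cat(sprintf("<molsig_desc> %s: %d descriptors\n", x$mol_id, length(x$values)))
  invisible(x)
}

#' @method tidy molsig_desc
#' @export
tidy.molsig_desc <- function(x, ...) {
  tibble(name = names(x$values), value = unname(x$values))
}
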