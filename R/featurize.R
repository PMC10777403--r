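# Graph featurization: SMILES -> directed multigraph with fixed-width
# one-hot atom and bond feature blocks, the condensed graph of reaction
# (CGR) union construction for atom-mapped reactions, and graph batching.

ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Na = 22.990, Mg = 24.305, Si = 28.086,
                 P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078,
                 Fe = 55.845, Zn = 65.38, Se = 78.971, Br = 79.904,
                 Sn = 118.71, I = 126.904)

#' Featurization vocabulary
#'
#' Fixed one-hot vocabularies for the atom and bond feature blocks. Every
#' block carries a trailing "other" slot so out-of-vocabulary values map to
#' a valid encoding instead of raising. The resulting widths are exposed as
#' `atom_width` and `bond_width`; the directed-edge feature width is their
#' sum.
#'
#' Atom blocks (in order): element one-hot, degree (number of bonds) one-hot,
#' formal charge one-hot, chirality tag one-hot, total-hydrogen-count
#' one-hot, hybridization one-hot, aromaticity bit, atomic mass / 100.
#' Bond blocks: null-bond bit (used by the CGR for bonds absent on one
#' side), bond-type one-hot (single/double/triple/aromatic), conjugation
#' bit, in-ring bit, stereo one-hot (none/cis/trans plus "other").
#'
#' @param elements element vocabulary.
#' @param max_degree largest explicitly encoded heavy-atom degree.
#' @param charges encoded formal charges.
#' @param max_h largest explicitly encoded hydrogen count.
#' @param hybridizations encoded hybridization states.
#' @return a `feature_config` list with vocabularies and derived widths.
#' @export
#' @examples
#' cfg <- feature_config()
#' cfg$atom_width
feature_config <- function(elements = c("B", "C", "N", "O", "F", "Si", "P",
                                        "S", "Cl", "Br", "I"),
                           max_degree = 5L,
                           charges = -2:2,
                           max_h = 4L,
                           hybridizations = c("sp", "sp2", "sp3")) {
  cfg <- list(
    elements = elements,
    degrees = 0:max_degree,
    charges = charges,
    chirality = c("none", "cw", "ccw"),
    h_counts = 0:max_h,
    hybridizations = hybridizations,
    bond_types = c("single", "double", "triple", "aromatic"),
    stereo = c("none", "cis", "trans"))
  cfg$atom_width <- length(elements) + 1L + length(cfg$degrees) + 1L +
    length(charges) + 1L + length(cfg$chirality) + 1L +
    length(cfg$h_counts) + 1L + length(hybridizations) + 1L + 2L
  cfg$bond_width <- 1L + length(cfg$bond_types) + 1L + 2L +
    length(cfg$stereo) + 1L
  class(cfg) <- "feature_config"
  cfg
}

one_hot <- function(value, vocab) {
  v <- numeric(length(vocab) + 1L)
  i <- match(value, vocab)
  v[if (is.na(i)) length(v) else i] <- 1
  v
}

#' Featurize one atom
#'
#' @param atom one row of a `parsed_mol` atom table (element symbol, degree,
#'   formal charge, chirality tag, hydrogen count, hybridization,
#'   aromaticity).
#' @param config a [feature_config()].
#' @return numeric vector of length `config$atom_width`.
#' @export
featurize_atom <- function(atom, config = feature_config()) {
  mass <- unname(ATOMIC_MASS[atom$symbol])
  if (is.na(mass)) mass <- 0
  c(one_hot(atom$symbol, config$elements),
    one_hot(atom$degree, config$degrees),
    one_hot(atom$charge, config$charges),
    one_hot(atom$chiral, config$chirality),
    one_hot(atom$h_count, config$h_counts),
    one_hot(atom$hybridization, config$hybridizations),
    as.numeric(atom$aromatic),
    mass / 100)
}

#' Featurize one bond
#'
#' @param bond one row of a `parsed_mol` bond table, or `NULL` for the
#'   null-bond encoding used by the CGR for bonds absent on one side.
#' @param config a [feature_config()].
#' @return numeric vector of length `config$bond_width`.
#' @export
featurize_bond <- function(bond, config = feature_config()) {
  if (is.null(bond)) {
    v <- numeric(config$bond_width)
    v[1] <- 1
    return(v)
  }
  type <- if (bond$aromatic) "aromatic"
    else c("single", "double", "triple")[bond$order]
  c(0,
    one_hot(type, config$bond_types),
    as.numeric(bond$conjugated),
    as.numeric(bond$in_ring),
    one_hot(bond$stereo, config$stereo))
}

atom_feature_matrix <- function(atoms, config) {
  m <- t(vapply(seq_len(nrow(atoms)),
                function(i) featurize_atom(atoms[i, , drop = FALSE], config),
                numeric(config$atom_width)))
  dimnames(m) <- NULL
  m
}

# assemble the directed-graph container from atom features and a bond table
assemble_graph <- function(atom_feats, bond_pairs, bond_feats, smiles) {
  n_atoms <- nrow(atom_feats)
  nb <- nrow(bond_pairs)
  if (nb > 0L) {
    src <- as.vector(rbind(bond_pairs[, 1], bond_pairs[, 2]))
    dst <- as.vector(rbind(bond_pairs[, 2], bond_pairs[, 1]))
    rev_index <- as.vector(rbind(seq_len(nb) * 2L, seq_len(nb) * 2L - 1L))
    # directed edge v->w: cat(x_v, bond features)
    edge_feats <- cbind(atom_feats[src, , drop = FALSE],
                        bond_feats[rep(seq_len(nb), each = 2L), , drop = FALSE])
    dimnames(edge_feats) <- NULL
  } else {
    src <- dst <- rev_index <- integer(0)
    edge_feats <- matrix(0, nrow = 0,
                         ncol = ncol(atom_feats) +
                           (if (is.null(bond_feats)) 0L else ncol(bond_feats)))
  }
  incoming <- split(seq_along(dst), factor(dst, levels = seq_len(n_atoms)))
  structure(list(
    n_atoms = n_atoms,
    n_edges = length(src),
    atom_features = atom_feats,
    edge_src = src,
    edge_dst = dst,
    edge_features = edge_feats,
    rev_index = rev_index,
    incoming = incoming,
    smiles = smiles), class = "mol_graph")
}

apply_extra <- function(base, extra, mode, what, smiles) {
  if (is.null(extra)) return(base)
  extra <- as.matrix(extra)
  if (nrow(extra) != nrow(base)) {
    stop("extra ", what, " features for '", smiles, "' have ", nrow(extra),
         " rows but the molecule has ", nrow(base), " ", what, "s",
         call. = FALSE)
  }
  out <- switch(mode, extend = cbind(base, extra), replace = extra,
                stop("unknown extra-feature mode: ", mode, call. = FALSE))
  dimnames(out) <- NULL
  out
}

#' Build the featurized directed graph of one molecule
#'
#' Each bond becomes two directed edges; the feature vector of directed edge
#' v->w is the concatenation of the atom features of v and the undirected
#' bond features, so the two directions differ only in the chosen first atom.
#'
#' @param smiles a SMILES string.
#' @param config a [feature_config()].
#' @param extra_atom_features optional numeric matrix (one row per atom)
#'   appended to (or replacing) the default atom block.
#' @param extra_bond_features optional numeric matrix (one row per bond).
#' @param extra_mode `"extend"` (append, default) or `"replace"`.
#' @return a `mol_graph`: atom features, directed edge list and features,
#'   `rev_index` (index of each directed edge's opposite twin), and
#'   per-atom incoming edge lists.
#' @export
#' @examples
#' g <- mol_graph("CC")
#' g$n_atoms     # 2
#' g$rev_index   # c(2, 1)
mol_graph <- function(smiles, config = feature_config(),
                      extra_atom_features = NULL,
                      extra_bond_features = NULL,
                      extra_mode = c("extend", "replace")) {
  extra_mode <- match.arg(extra_mode)
  mol <- tryCatch(parse_smiles(smiles), error = function(e) {
    stop("cannot parse SMILES '", smiles, "': ", conditionMessage(e),
         call. = FALSE)
  })
  atom_feats <- atom_feature_matrix(mol$atoms, config)
  atom_feats <- apply_extra(atom_feats, extra_atom_features, extra_mode,
                            "atom", smiles)
  nb <- nrow(mol$bonds)
  bond_feats <- if (nb > 0L) {
    t(vapply(seq_len(nb),
             function(k) featurize_bond(mol$bonds[k, , drop = FALSE], config),
             numeric(config$bond_width)))
  } else matrix(0, 0, config$bond_width)
  bond_feats <- apply_extra(bond_feats, extra_bond_features, extra_mode,
                            "bond", smiles)
  pairs <- if (nb > 0L) cbind(mol$bonds$a1, mol$bonds$a2) else
    matrix(0L, 0, 2)
  g <- assemble_graph(atom_feats, pairs, bond_feats, smiles)
  g$mol <- mol
  g
}

split_reaction <- function(rxn_smiles) {
  parts <- strsplit(rxn_smiles, "≫|>>", perl = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  if (length(parts) != 2L) {
    stop("reaction SMILES must contain exactly one '≫' (or '>>') ",
         "separator: ", rxn_smiles, call. = FALSE)
  }
  trimws(parts)
}

check_maps <- function(mol, side, rxn, lenient) {
  maps <- mol$atoms$map
  dup <- unique(maps[maps > 0L][duplicated(maps[maps > 0L])])
  if (length(dup) > 0L) {
    stop("duplicate atom-map number(s) ", paste(dup, collapse = ", "),
         " on the ", side, " side of reaction: ", rxn, call. = FALSE)
  }
  if (any(maps == 0L) && !lenient) {
    stop("unmapped atom(s) on the ", side, " side of reaction: ", rxn,
         " (use lenient = TRUE to map leftovers by position)", call. = FALSE)
  }
  maps
}

#' Build the condensed graph of reaction (CGR) for an atom-mapped reaction
#'
#' Atoms and bonds are the unions of the reactant-side and product-side
#' sets, keyed by atom-map number. Atom and bond feature vectors combine the
#' two sides according to `mode`; bonds present on only one side take the
#' null-bond encoding on the missing side, and atoms present on only one
#' side impute the missing side's features from the present side (so an
#' identity reaction has an all-zero difference block).
#'
#' @param rxn_smiles atom-mapped reaction SMILES, sides joined by
#'   the ≫ symbol or `">>"`.
#' @param config a [feature_config()].
#' @param mode feature combination: `"reac_diff"` (reactant features then
#'   product-minus-reactant difference, the default), `"reac_prod"`, or
#'   `"prod_diff"`.
#' @param lenient if `TRUE`, unmapped atoms are paired across sides by
#'   position instead of raising.
#' @return a `mol_graph` whose atom/bond feature widths are doubled.
#' @export
#' @examples
#' g <- reaction_graph("[CH3:1][CH3:2]>>[CH3:1][CH3:2]")
#' g$n_atoms  # 2
reaction_graph <- function(rxn_smiles, config = feature_config(),
                           mode = c("reac_diff", "reac_prod", "prod_diff"),
                           lenient = FALSE) {
  mode <- match.arg(mode)
  sides <- split_reaction(rxn_smiles)
  reac <- tryCatch(parse_smiles(sides[1]), error = function(e)
    stop("cannot parse reactant side of '", rxn_smiles, "': ",
         conditionMessage(e), call. = FALSE))
  prod <- tryCatch(parse_smiles(sides[2]), error = function(e)
    stop("cannot parse product side of '", rxn_smiles, "': ",
         conditionMessage(e), call. = FALSE))
  rmap <- check_maps(reac, "reactant", rxn_smiles, lenient)
  pmap <- check_maps(prod, "product", rxn_smiles, lenient)
  if (lenient) {
    # pair unmapped leftovers by position using fresh map numbers
    fresh <- max(c(rmap, pmap, 0L))
    nr <- which(rmap == 0L); np <- which(pmap == 0L)
    for (i in seq_len(max(length(nr), length(np)))) {
      fresh <- fresh + 1L
      if (i <= length(nr)) rmap[nr[i]] <- fresh
      if (i <= length(np)) pmap[np[i]] <- fresh
    }
  }
  keys <- c(rmap, setdiff(pmap, rmap))   # reactant order first
  n <- length(keys)
  r_idx <- match(keys, rmap)   # union position -> reactant atom (or NA)
  p_idx <- match(keys, pmap)

  fr <- atom_feature_matrix(reac$atoms, config)
  fp <- atom_feature_matrix(prod$atoms, config)
  A_r <- matrix(0, n, config$atom_width)
  A_p <- matrix(0, n, config$atom_width)
  for (i in seq_len(n)) {
    a_r <- if (!is.na(r_idx[i])) fr[r_idx[i], ] else fp[p_idx[i], ]
    a_p <- if (!is.na(p_idx[i])) fp[p_idx[i], ] else fr[r_idx[i], ]
    A_r[i, ] <- a_r; A_p[i, ] <- a_p
  }
  atom_feats <- combine_sides(A_r, A_p, mode)

  bond_key <- function(maps, bonds) {
    if (nrow(bonds) == 0L) return(character(0))
    k1 <- pmin(maps[bonds$a1], maps[bonds$a2])
    k2 <- pmax(maps[bonds$a1], maps[bonds$a2])
    paste(k1, k2, sep = "-")
  }
  rb_keys <- bond_key(rmap, reac$bonds)
  pb_keys <- bond_key(pmap, prod$bonds)
  all_keys <- c(rb_keys, setdiff(pb_keys, rb_keys))
  nb <- length(all_keys)
  pairs <- matrix(0L, nb, 2)
  B_r <- matrix(0, nb, config$bond_width)
  B_p <- matrix(0, nb, config$bond_width)
  null_b <- featurize_bond(NULL, config)
  for (k in seq_len(nb)) {
    key <- all_keys[k]
    ends <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
    pairs[k, ] <- match(ends, keys)
    ri <- match(key, rb_keys); pi <- match(key, pb_keys)
    B_r[k, ] <- if (!is.na(ri))
      featurize_bond(reac$bonds[ri, , drop = FALSE], config) else null_b
    B_p[k, ] <- if (!is.na(pi))
      featurize_bond(prod$bonds[pi, , drop = FALSE], config) else null_b
  }
  bond_feats <- combine_sides(B_r, B_p, mode)
  g <- assemble_graph(atom_feats, pairs, bond_feats, rxn_smiles)
  g$is_reaction <- TRUE
  g$mode <- mode
  g
}

combine_sides <- function(f_reac, f_prod, mode) {
  switch(mode,
         reac_diff = cbind(f_reac, f_prod - f_reac),
         reac_prod = cbind(f_reac, f_prod),
         prod_diff = cbind(f_prod, f_prod - f_reac))
}

#' Batch several molecular graphs into one index-shifted graph
#'
#' @param graphs non-empty list of `mol_graph` objects with identical atom
#'   and edge feature widths.
#' @return a `batched_graph` with concatenated features, shifted edge
#'   indices and a `scope` matrix (`start`, `size` per molecule) from which
#'   [unbatch_graphs()] recovers the inputs.
#' @export
batch_graphs <- function(graphs) {
  if (length(graphs) == 0L) stop("cannot batch an empty graph list",
                                 call. = FALSE)
  aw <- vapply(graphs, function(g) ncol(g$atom_features), 0L)
  ew <- vapply(graphs, function(g) ncol(g$edge_features), 0L)
  if (length(unique(aw)) != 1L || length(unique(ew)) != 1L) {
    stop("graphs have mixed feature widths (atom: ",
         paste(unique(aw), collapse = "/"), ", edge: ",
         paste(unique(ew), collapse = "/"), ")", call. = FALSE)
  }
  n_atoms <- vapply(graphs, `[[`, 0L, "n_atoms")
  n_edges <- vapply(graphs, `[[`, 0L, "n_edges")
  atom_off <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  edge_off <- cumsum(c(0L, n_edges[-length(n_edges)]))
  src <- dst <- rev_index <- integer(sum(n_edges))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (g$n_edges > 0L) {
      at <- edge_off[i] + seq_len(g$n_edges)
      src[at] <- g$edge_src + atom_off[i]
      dst[at] <- g$edge_dst + atom_off[i]
      rev_index[at] <- g$rev_index + edge_off[i]
    }
  }
  total_atoms <- sum(n_atoms)
  structure(list(
    n_mols = length(graphs),
    n_atoms = total_atoms,
    n_edges = sum(n_edges),
    atom_features = do.call(rbind, lapply(graphs, `[[`, "atom_features")),
    edge_features = do.call(rbind, lapply(graphs, `[[`, "edge_features")),
    edge_src = src,
    edge_dst = dst,
    rev_index = rev_index,
    incoming = split(seq_along(dst), factor(dst, levels = seq_len(total_atoms))),
    scope = cbind(start = atom_off, size = n_atoms),
    edge_scope = cbind(start = edge_off, size = n_edges),
    smiles = vapply(graphs, function(g)
      if (is.null(g$smiles)) NA_character_ else g$smiles, "")),
    class = "batched_graph")
}

#' Recover the individual graphs from a batch
#'
#' @param batch a `batched_graph`.
#' @return list of `mol_graph` objects equal to the batched inputs.
#' @export
unbatch_graphs <- function(batch) {
  lapply(seq_len(batch$n_mols), function(i) {
    a0 <- batch$scope[i, "start"]; na <- batch$scope[i, "size"]
    e0 <- batch$edge_scope[i, "start"]; ne <- batch$edge_scope[i, "size"]
    at <- e0 + seq_len(ne)
    assemble_graph(
      batch$atom_features[a0 + seq_len(na), , drop = FALSE],
      # reconstruct bond pairs from odd-indexed directed edges
      if (ne > 0L) cbind(batch$edge_src[at][c(TRUE, FALSE)] - a0,
                         batch$edge_dst[at][c(TRUE, FALSE)] - a0)
      else matrix(0L, 0, 2),
      matrix(0, max(1L, ne %/% 2L), 0)[seq_len(ne %/% 2L), , drop = FALSE],
      batch$smiles[i]) -> g
    # edge features carried over verbatim (assemble_graph would rebuild
    # them from bond features, which we no longer have separately)
    g$edge_features <- batch$edge_features[at, , drop = FALSE]
    g
  })
}
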