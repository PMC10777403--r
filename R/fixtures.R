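# Deterministic synthetic fixtures: a small molecular grammar (alkanes,
# alcohols, substituted benzenes, capped at 12 heavy atoms), targets with
# stated closed-form rules, atom-mapped toy reactions, and alternative
# SMILES renderings for atom-order-invariance checks. Fixtures exercise the
# computation; they make no claim to chemical realism.

# build a parsed_mol-like object directly (for rendering)
make_mol_object <- function(symbols, aromatic, bonds) {
  atoms <- data.frame(symbol = symbols, aromatic = aromatic,
                      charge = 0L, h_explicit = NA_integer_, map = 0L,
                      chiral = "none", stringsAsFactors = FALSE)
  deg <- integer(length(symbols))
  if (nrow(bonds) > 0L) for (k in seq_len(nrow(bonds))) {
    deg[bonds$a1[k]] <- deg[bonds$a1[k]] + 1L
    deg[bonds$a2[k]] <- deg[bonds$a2[k]] + 1L
  }
  atoms$degree <- deg
  atoms$h_count <- 0L
  list(atoms = atoms, bonds = bonds)
}

random_tree_molecule <- function(max_atoms = 10L) {
  k <- sample(1:max_atoms, 1L)
  symbols <- rep("C", k)
  if (k >= 2L) {
    parent <- c(NA_integer_, vapply(2:k, function(i)
      sample.int(i - 1L, 1L), 0L))
    bonds <- data.frame(a1 = parent[-1], a2 = 2:k, order = 1,
                        aromatic = FALSE, dir = "",
                        stringsAsFactors = FALSE)
    deg <- tabulate(c(bonds$a1, bonds$a2), k)
    # alcohols/ethers: turn up to two degree-1 carbons into oxygens
    leaves <- which(deg == 1L)
    n_o <- sample(0:min(2L, length(leaves)), 1L, prob = c(5, 3, 1)[
      seq_len(min(2L, length(leaves)) + 1L)])
    if (n_o > 0L) symbols[sample(leaves, n_o)] <- "O"
    # occasionally promote one C-C bond to a double bond (kept away from
    # crowded atoms so valences stay sensible)
    if (stats::runif(1) < 0.35) {
      ok <- which(deg[bonds$a1] <= 2L & deg[bonds$a2] <= 2L &
                    symbols[bonds$a1] == "C" & symbols[bonds$a2] == "C")
      if (length(ok) > 0L) bonds$order[ok[sample.int(length(ok), 1L)]] <- 2
    }
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0),
                        aromatic = logical(0), dir = character(0),
                        stringsAsFactors = FALSE)
  }
  make_mol_object(symbols, rep(FALSE, k), bonds)
}

random_benzene_molecule <- function() {
  n_sub <- sample(0:3, 1L)
  symbols <- rep("C", 6L)
  aromatic <- rep(TRUE, 6L)
  bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1L), order = 1,
                      aromatic = TRUE, dir = "", stringsAsFactors = FALSE)
  if (n_sub > 0L) {
    sites <- sample(1:6, n_sub)
    budget <- 6L   # heavy-atom cap of 12 in total
    for (s in sites) {
      len <- sample(1:min(2L, budget), 1L)
      budget <- budget - len
      chain_syms <- rep("C", len)
      if (stats::runif(1) < 0.3) chain_syms[len] <- "O"
      base <- length(symbols)
      symbols <- c(symbols, chain_syms)
      aromatic <- c(aromatic, rep(FALSE, len))
      prev <- s
      for (j in seq_len(len)) {
        bonds <- rbind(bonds, data.frame(a1 = prev, a2 = base + j, order = 1,
                                         aromatic = FALSE, dir = "",
                                         stringsAsFactors = FALSE))
        prev <- base + j
      }
    }
  }
  make_mol_object(symbols, aromatic, bonds)
}

#' Generate a deterministic set of unique fixture molecules
#'
#' Samples SMILES from a combinatorial alkane/alcohol/substituted-benzene
#' grammar (at most 12 heavy atoms). Regeneration with the same seed is
#' byte-identical; all outputs parse and are pairwise non-isomorphic.
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @return character vector of `n` SMILES.
#' @export
#' @examples
#' make_molecule_set(5, seed = 1)
make_molecule_set <- function(n, seed = 0L) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    out <- character(0)
    seen <- character(0)
    attempts <- 0L
    while (length(out) < n) {
      attempts <- attempts + 1L
      if (attempts > 200L * n)
        stop("fixture grammar capacity exceeded at n = ", n, call. = FALSE)
      mol <- if (stats::runif(1) < 0.35) random_benzene_molecule()
             else random_tree_molecule()
      key <- graph_hash(mol$atoms, mol$bonds)
      if (key %in% seen) next
      smi <- render_smiles(mol)
      seen <- c(seen, key)
      out <- c(out, smi)
    }
    out
  })
}

#' Alternative SMILES renderings of one molecule
#'
#' Re-renders a molecule from random start atoms with random neighbor
#' orders; every rendering parses to a graph isomorphic to the input. Used
#' to test atom-order invariance of embeddings.
#'
#' @param smiles input SMILES.
#' @param n number of renderings.
#' @param seed RNG seed.
#' @return character vector of `n` SMILES (possibly with duplicates for
#'   tiny molecules).
#' @export
shuffle_smiles <- function(smiles, n = 10L, seed = 0L) {
  mol <- parse_smiles(smiles)
  k <- nrow(mol$atoms)
  with_seed(seed, vapply(seq_len(n), function(i) {
    render_smiles(mol, root = sample.int(k, 1L), perm = sample.int(k))
  }, ""))
}

#' Closed-form fixture targets
#'
#' Computes targets from molecules by stated rules: `atom_count` = number of
#' heavy atoms + N(0, sd); `ring_flag` = 1 if the molecule has a ring;
#' `element_class` = 1 for pure alkanes/alcohol-free carbon skeletons, 2 if
#' oxygen is present, 3 if aromatic; `gaussian_spectrum` = normalized
#' mixture of two Gaussians over `bins` bins whose centers are
#' (carbon count)/12 and 0.75 (the latter only when oxygen is present);
#' `per_atom_degree` = each atom's heavy-atom bond count (summing to twice
#' the bond count, usable as an exact constraint); `heteroscedastic` =
#' heavy-atom count + noise with sd = `het_coef` x heavy-atom count.
#'
#' @param smiles character vector of molecules.
#' @param task one of `"atom_count"`, `"ring_flag"`, `"element_class"`,
#'   `"gaussian_spectrum"`, `"per_atom_degree"`, `"heteroscedastic"`.
#' @param seed RNG seed for the noise.
#' @param noise_sd Gaussian noise sd for `atom_count` (default 0.1).
#' @param bins number of spectrum bins (default 40).
#' @param het_coef noise-scale coefficient for `heteroscedastic`
#'   (default 0.05).
#' @return numeric vector, matrix (spectra), or list of vectors (atom level);
#'   `heteroscedastic` returns a data.frame with the true noise sd attached.
#' @export
make_targets <- function(smiles, task, seed = 0L, noise_sd = 0.1,
                         bins = 40L, het_coef = 0.05) {
  mols <- lapply(smiles, parse_smiles)
  n_heavy <- vapply(mols, function(m) nrow(m$atoms), 0L)
  switch(task,
    atom_count = with_seed(seed,
      n_heavy + stats::rnorm(length(smiles), 0, noise_sd)),
    ring_flag = vapply(mols, function(m)
      as.numeric(any(m$bonds$in_ring)), 0),
    element_class = vapply(mols, function(m) {
      if (any(m$atoms$aromatic)) 3
      else if (any(m$atoms$symbol == "O")) 2
      else 1
    }, 0),
    gaussian_spectrum = {
      grid <- seq(0, 1, length.out = bins)
      t(vapply(mols, function(m) {
        nC <- sum(m$atoms$symbol == "C")
        mu1 <- nC / 12
        y <- exp(-(grid - mu1)^2 / (2 * 0.08^2))
        if (any(m$atoms$symbol == "O"))
          y <- y + 0.6 * exp(-(grid - 0.75)^2 / (2 * 0.05^2))
        y / sum(y)
      }, numeric(bins)))
    },
    per_atom_degree = lapply(mols, function(m) {
      deg <- integer(nrow(m$atoms))
      if (nrow(m$bonds) > 0L) {
        t <- tabulate(c(m$bonds$a1, m$bonds$a2), nrow(m$atoms))
        deg <- t
      }
      as.numeric(deg)
    }),
    heteroscedastic = {
      sds <- het_coef * n_heavy
      y <- with_seed(seed, n_heavy + stats::rnorm(length(smiles), 0, sds))
      out <- data.frame(y = y, true_sd = sds)
      out
    },
    stop("unknown fixture task: ", task, call. = FALSE))
}

#' Ready-to-train fixture data frames
#'
#' Convenience wrapper combining [make_molecule_set()] and [make_targets()]
#' into the exact table layout the fitting function and CSV readers expect.
#'
#' @param n number of molecules.
#' @param task fixture task, see [make_targets()]; additionally
#'   `"reaction"` gives atom-mapped reactions with the number of changed
#'   bonds as target.
#' @param seed RNG seed.
#' @param ... passed to [make_targets()].
#' @return a data.frame: `smiles` plus `y` (scalar tasks), `bin_*` columns
#'   (spectra), a list column `y` plus `constraint` (atom level), or `rxn`
#'   plus `y` (reactions).
#' @export
fixture_dataset <- function(n, task = "atom_count", seed = 0L, ...) {
  if (task == "reaction") {
    rs <- make_reaction_set(n, seed)
    return(data.frame(rxn = rs$rxn, y = rs$n_changed,
                      stringsAsFactors = FALSE))
  }
  if (task == "heteroscedastic") {
    # repeated measurements: molecules drawn with replacement from a unique
    # pool, each row with its own noise realization
    pool <- make_molecule_set(min(n, 300L), seed)
    smiles <- with_seed(seed + 2L, sample(pool, n, replace = n > length(pool)))
  } else {
    smiles <- make_molecule_set(n, seed)
  }
  tg <- make_targets(smiles, task, seed = seed + 1L, ...)
  if (task == "gaussian_spectrum") {
    df <- data.frame(smiles = smiles, stringsAsFactors = FALSE)
    colnames(tg) <- sprintf("bin_%04d", seq_len(ncol(tg)))
    return(cbind(df, as.data.frame(tg)))
  }
  if (task == "per_atom_degree") {
    df <- data.frame(smiles = smiles, stringsAsFactors = FALSE)
    df$y <- tg
    df$constraint <- vapply(tg, sum, 0)
    return(df)
  }
  if (task == "heteroscedastic") {
    return(data.frame(smiles = smiles, y = tg$y, true_sd = tg$true_sd,
                      stringsAsFactors = FALSE))
  }
  data.frame(smiles = smiles, y = as.numeric(tg), stringsAsFactors = FALSE)
}

# mapped linear-alkane SMILES with correct bracket H counts
chain_smiles <- function(ids, orders = rep(1, length(ids) - 1L)) {
  k <- length(ids)
  if (k == 1L) return(paste0("[CH4:", ids, "]"))
  toks <- character(k)
  for (i in seq_len(k)) {
    val <- 0
    if (i > 1L) val <- val + orders[i - 1L]
    if (i < k) val <- val + orders[i]
    h <- 4L - val
    toks[i] <- paste0("[CH", if (h != 1L) h else "", ":", ids[i], "]")
  }
  bsym <- ifelse(orders == 2, "=", ifelse(orders == 3, "#", ""))
  paste0(toks[1], paste0(bsym, toks[-1], collapse = ""))
}

#' Atom-mapped toy reaction fixtures
#'
#' Linear-alkane reactions of three kinds: identity (no change), homolytic
#' single-bond cleavage (one broken bond), and single-to-double bond order
#' change (one changed bond). The target is the number of changed bonds,
#' computable by comparing the mapped bond sets of the two sides.
#'
#' @param n number of reactions.
#' @param seed RNG seed.
#' @return list with `rxn` (reaction SMILES), `n_changed`, and `kind`.
#' @export
make_reaction_set <- function(n, seed = 0L) {
  with_seed(seed, {
    rxn <- character(n)
    changed <- numeric(n)
    kind <- character(n)
    for (i in seq_len(n)) {
      k <- sample(2:8, 1L)
      ids <- sample(1:9, k)   # scrambled map numbers
      lhs <- chain_smiles(ids)
      kd <- sample(c("identity", "cleavage", "order_change"), 1L)
      if (kd == "identity") {
        rhs <- lhs
        nc <- 0
      } else if (kd == "cleavage") {
        j <- sample(k - 1L, 1L)
        rhs <- paste0(chain_smiles(ids[seq_len(j)]), ".",
                      chain_smiles(ids[(j + 1L):k]))
        nc <- 1
      } else {
        j <- sample(k - 1L, 1L)
        orders <- rep(1, k - 1L)
        orders[j] <- 2
        rhs <- chain_smiles(ids, orders)
        nc <- 1
      }
      rxn[i] <- paste0(lhs, ">>", rhs)
      changed[i] <- nc
      kind[i] <- kd
    }
    list(rxn = rxn, n_changed = changed, kind = kind)
  })
}

#' The mapped Diels-Alder fixture reaction
#'
#' Butadiene + ethene to cyclohexene, fully atom-mapped: the condensed graph
#' of reaction has 6 atoms and a 6-bond union edge set of which 2 bonds are
#' product-only (the newly formed sigma bonds) and none are reactant-only.
#'
#' @return a reaction SMILES string.
#' @export
diels_alder_reaction <- function() {
  paste0("[CH2:1]=[CH:2][CH:3]=[CH2:4].[CH2:5]=[CH2:6]",
         ">>",
         "[CH2:1]1[CH:2]=[CH:3][CH2:4][CH2:5][CH2:6]1")
}

#' Count changed bonds between the two sides of a mapped reaction
#'
#' A bond counts as changed if it exists on only one side or if its order
#' (including aromaticity) differs between sides.
#'
#' @param rxn_smiles atom-mapped reaction SMILES.
#' @return integer count.
#' @export
count_changed_bonds <- function(rxn_smiles) {
  sides <- split_reaction(rxn_smiles)
  key_orders <- function(s) {
    m <- parse_smiles(s)
    if (nrow(m$bonds) == 0L) return(stats::setNames(numeric(0), character(0)))
    maps <- m$atoms$map
    k <- paste(pmin(maps[m$bonds$a1], maps[m$bonds$a2]),
               pmax(maps[m$bonds$a1], maps[m$bonds$a2]), sep = "-")
    stats::setNames(ifelse(m$bonds$aromatic, 1.5, m$bonds$order), k)
  }
  r <- key_orders(sides[1]); p <- key_orders(sides[2])
  keys <- union(names(r), names(p))
  sum(vapply(keys, function(k) {
    ro <- r[k]; po <- p[k]
    is.na(ro) || is.na(po) || ro != po
  }, TRUE))
}
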