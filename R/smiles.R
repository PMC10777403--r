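# Minimal SMILES machinery: tokenizer, parser, perception (implicit H,
# hybridization, rings, conjugation, cis/trans), a renderer used to produce
# alternative atom orderings, and a canonical graph hash for scaffold splits.
#
# Supported dialect: organic subset (B C N O P S F Cl Br I and aromatic
# b c n o p s), bracket atoms with isotope/chirality/H-count/charge/atom-map,
# bond symbols - = # : / \, ring closures (digits and %nn), branches, and
# dot-separated components. Hydrogens are implicit: graphs contain heavy
# atoms only, H counts become atom features.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                     F = 1, Cl = 1, Br = 1, I = 1)

#' Parse a SMILES string into an annotated molecular graph
#'
#' Internal workhorse behind [mol_graph()]. Returns heavy atoms, bonds and
#' perceived properties (implicit hydrogen counts, hybridization, ring and
#' conjugation flags, double-bond cis/trans tags, chirality tags, atom maps).
#'
#' @param smiles a single SMILES string.
#' @return a list of class `parsed_mol` with `atoms` and `bonds` data frames.
#' @keywords internal
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("SMILES must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  atoms <- list()   # each: symbol, aromatic, charge, h_explicit, map, chiral
  bonds <- list()   # each: a1, a2, order, aromatic, dir ("", "/", "\\")
  prev_stack <- integer(0)
  prev <- NA_integer_
  pending_bond <- NULL  # list(order, aromatic, dir) or NULL
  ring_open <- list()   # key: closure label -> list(atom, bond)

  add_atom <- function(symbol, aromatic, charge = 0L, h_explicit = NA_integer_,
                       map = 0L, chiral = "none") {
    atoms[[length(atoms) + 1L]] <<- list(
      symbol = symbol, aromatic = aromatic, charge = as.integer(charge),
      h_explicit = h_explicit, map = as.integer(map), chiral = chiral)
    length(atoms)
  }
  take_bond <- function() {
    b <- pending_bond
    pending_bond <<- NULL
    b
  }
  connect <- function(a1, a2, spec) {
    if (is.null(spec)) {
      arom <- atoms[[a1]]$aromatic && atoms[[a2]]$aromatic
      spec <- list(order = 1, aromatic = arom, dir = "")
    }
    bonds[[length(bonds) + 1L]] <<- list(
      a1 = a1, a2 = a2, order = spec$order, aromatic = spec$aromatic,
      dir = spec$dir)
  }
  close_ring <- function(label) {
    spec <- take_bond()
    if (!is.null(ring_open[[label]])) {
      op <- ring_open[[label]]
      if (is.null(spec)) spec <- op$bond
      connect(op$atom, prev, spec)
      ring_open[[label]] <<- NULL
    } else {
      ring_open[[label]] <<- list(atom = prev, bond = spec)
    }
  }
  on_new_atom <- function(idx) {
    if (!is.na(prev)) connect(prev, idx, take_bond())
    prev <<- idx
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", smiles, call. = FALSE)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, smiles)
      idx <- add_atom(at$symbol, at$aromatic, at$charge, at$h_explicit,
                      at$map, at$chiral)
      on_new_atom(idx)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      idx <- add_atom(paste0(ch, chars[i + 1L]), FALSE)
      on_new_atom(idx)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      idx <- add_atom(ch, FALSE)
      on_new_atom(idx)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), TRUE)
      on_new_atom(idx)
      i <- i + 1L
    } else if (ch == "-") {
      pending_bond <- list(order = 1, aromatic = FALSE, dir = ""); i <- i + 1L
    } else if (ch == "=") {
      pending_bond <- list(order = 2, aromatic = FALSE, dir = ""); i <- i + 1L
    } else if (ch == "#") {
      pending_bond <- list(order = 3, aromatic = FALSE, dir = ""); i <- i + 1L
    } else if (ch == ":") {
      pending_bond <- list(order = 1, aromatic = TRUE, dir = ""); i <- i + 1L
    } else if (ch == "/" || ch == "\\") {
      pending_bond <- list(order = 1, aromatic = FALSE, dir = ch); i <- i + 1L
    } else if (ch == "(") {
      prev_stack <- c(prev_stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(prev_stack) == 0L)
        stop("unbalanced parenthesis in SMILES: ", smiles, call. = FALSE)
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("bad %% ring closure in SMILES: ", smiles, call. = FALSE)
      close_ring(paste(chars[(i + 1L):(i + 2L)], collapse = "")); i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pending_bond <- NULL; i <- i + 1L
    } else {
      stop("unsupported SMILES token '", ch, "' in: ", smiles, call. = FALSE)
    }
  }
  if (length(ring_open) > 0L && any(!vapply(ring_open, is.null, logical(1))))
    stop("unclosed ring bond in SMILES: ", smiles, call. = FALSE)
  if (length(prev_stack) > 0L)
    stop("unbalanced parenthesis in SMILES: ", smiles, call. = FALSE)
  if (length(atoms) == 0L) stop("SMILES contains no atoms: ", smiles, call. = FALSE)

  a <- data.frame(
    symbol = vapply(atoms, `[[`, "", "symbol"),
    aromatic = vapply(atoms, `[[`, TRUE, "aromatic"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    h_explicit = vapply(atoms, `[[`, NA_integer_, "h_explicit"),
    map = vapply(atoms, `[[`, 0L, "map"),
    chiral = vapply(atoms, `[[`, "", "chiral"),
    stringsAsFactors = FALSE)
  if (length(bonds) > 0L) {
    b <- data.frame(
      a1 = vapply(bonds, `[[`, 0L, "a1"),
      a2 = vapply(bonds, `[[`, 0L, "a2"),
      order = vapply(bonds, `[[`, 0, "order"),
      aromatic = vapply(bonds, `[[`, TRUE, "aromatic"),
      dir = vapply(bonds, `[[`, "", "dir"),
      stringsAsFactors = FALSE)
  } else {
    b <- data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0),
                    aromatic = logical(0), dir = character(0),
                    stringsAsFactors = FALSE)
  }
  perceive(a, b, smiles)
}

parse_bracket_atom <- function(body, smiles) {
  orig <- body
  # isotope (ignored beyond parsing)
  body <- sub("^[0-9]+", "", body)
  m <- regmatches(body, regexpr("^([A-Z][a-z]?|[bcnops])", body))
  if (length(m) == 0L)
    stop("cannot parse bracket atom [", orig, "] in SMILES: ", smiles,
         call. = FALSE)
  aromatic <- m %in% c("b", "c", "n", "o", "p", "s")
  symbol <- if (aromatic) toupper(m) else m
  body <- substring(body, nchar(m) + 1L)

  chiral <- "none"
  if (startsWith(body, "@@")) { chiral <- "cw"; body <- substring(body, 3L) }
  else if (startsWith(body, "@")) { chiral <- "ccw"; body <- substring(body, 2L) }

  h_explicit <- 0L
  if (startsWith(body, "H")) {
    body <- substring(body, 2L)
    hm <- regmatches(body, regexpr("^[0-9]+", body))
    if (length(hm) == 1L) {
      h_explicit <- as.integer(hm); body <- substring(body, nchar(hm) + 1L)
    } else h_explicit <- 1L
  }

  charge <- 0L
  cm <- regmatches(body, regexpr("^(\\+[0-9]+|-[0-9]+|\\++|-+)", body))
  if (length(cm) == 1L) {
    charge <- if (grepl("[0-9]", cm)) as.integer(cm)
      else (if (startsWith(cm, "+")) 1L else -1L) * nchar(cm)
    body <- substring(body, nchar(cm) + 1L)
  }

  map <- 0L
  if (startsWith(body, ":")) {
    mm <- regmatches(body, regexpr("^:[0-9]+", body))
    if (length(mm) == 0L)
      stop("bad atom map in [", orig, "]: ", smiles, call. = FALSE)
    map <- as.integer(substring(mm, 2L))
    body <- substring(body, nchar(mm) + 1L)
  }
  if (nzchar(body))
    stop("unparsed bracket atom content '", body, "' in [", orig, "]: ",
         smiles, call. = FALSE)
  list(symbol = symbol, aromatic = aromatic, charge = charge,
       h_explicit = h_explicit, map = map, chiral = chiral)
}

# Perception: degrees, implicit H, hybridization, ring membership
# (bridge detection), conjugation, double-bond stereo.
perceive <- function(atoms, bonds, smiles) {
  n <- nrow(atoms)
  nb <- nrow(bonds)
  deg <- integer(n)
  order_sum <- numeric(n)
  n_double <- integer(n)
  n_triple <- integer(n)
  n_arom <- integer(n)
  if (nb > 0L) {
    for (k in seq_len(nb)) {
      for (v in c(bonds$a1[k], bonds$a2[k])) {
        deg[v] <- deg[v] + 1L
        o <- if (bonds$aromatic[k]) 1.5 else bonds$order[k]
        order_sum[v] <- order_sum[v] + o
        if (bonds$aromatic[k]) n_arom[v] <- n_arom[v] + 1L
        else if (bonds$order[k] == 2) n_double[v] <- n_double[v] + 1L
        else if (bonds$order[k] == 3) n_triple[v] <- n_triple[v] + 1L
      }
    }
  }
  atoms$degree <- deg

  h_count <- integer(n)
  for (v in seq_len(n)) {
    if (!is.na(atoms$h_explicit[v])) {
      h_count[v] <- atoms$h_explicit[v]
    } else {
      val <- DEFAULT_VALENCE[atoms$symbol[v]]
      if (is.na(val)) val <- 0
      val <- max(0, val + atoms$charge[v])
      h_count[v] <- max(0L, as.integer(floor(val - order_sum[v] + 1e-9)))
    }
  }
  atoms$h_count <- h_count

  hyb <- character(n)
  for (v in seq_len(n)) {
    hyb[v] <- if (atoms$aromatic[v] || n_arom[v] > 0L) "sp2"
      else if (n_triple[v] >= 1L || n_double[v] >= 2L) "sp"
      else if (n_double[v] == 1L) "sp2"
      else if (atoms$symbol[v] %in% names(DEFAULT_VALENCE)) "sp3"
      else "other"
  }
  atoms$hybridization <- hyb

  bonds$in_ring <- if (nb > 0L) !find_bridges(n, bonds) else logical(0)
  atoms$in_ring <- rep(FALSE, n)
  if (nb > 0L) {
    ring_atoms <- unique(c(bonds$a1[bonds$in_ring], bonds$a2[bonds$in_ring]))
    atoms$in_ring[ring_atoms] <- TRUE
  }

  # conjugation: "pi atom" = carries a multiple or aromatic bond; a single
  # bond between two pi atoms is conjugated, and a multiple bond is
  # conjugated when at least one endpoint touches a further pi atom.
  pi_atom <- n_arom > 0L | n_double > 0L | n_triple > 0L | atoms$aromatic
  conj <- logical(nb)
  if (nb > 0L) {
    adj <- vector("list", n)
    for (k in seq_len(nb)) {
      adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], k)
      adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], k)
    }
    other_end <- function(k, v) if (bonds$a1[k] == v) bonds$a2[k] else bonds$a1[k]
    for (k in seq_len(nb)) {
      if (bonds$aromatic[k]) { conj[k] <- TRUE; next }
      v <- bonds$a1[k]; w <- bonds$a2[k]
      if (bonds$order[k] == 1) {
        conj[k] <- pi_atom[v] && pi_atom[w]
      } else {
        nbrs <- c(vapply(setdiff(adj[[v]], k), other_end, 0L, v = v),
                  vapply(setdiff(adj[[w]], k), other_end, 0L, v = w))
        conj[k] <- length(nbrs) > 0L && any(pi_atom[nbrs])
      }
    }
  }
  bonds$conjugated <- conj
  bonds$stereo <- perceive_cis_trans(atoms, bonds)

  structure(list(atoms = atoms, bonds = bonds, smiles = smiles),
            class = "parsed_mol")
}

# bridge bonds via iterative Tarjan low-link; a bond is in a ring iff it is
# not a bridge (multigraph-safe enough for chemistry: parallel bonds absent)
find_bridges <- function(n, bonds) {
  nb <- nrow(bonds)
  adj <- vector("list", n)
  for (k in seq_len(nb)) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], k)
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], k)
  }
  disc <- integer(n); low <- integer(n); timer <- 0L
  is_bridge <- logical(nb)
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    # stack frames: (vertex, parent-bond, next-adj-position)
    stack <- list(list(v = root, pb = 0L, i = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack) > 0L) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$i <= length(adj[[v]])) {
        k <- adj[[v]][fr$i]
        stack[[length(stack)]]$i <- fr$i + 1L
        if (k == fr$pb) next
        w <- if (bonds$a1[k] == v) bonds$a2[k] else bonds$a1[k]
        if (disc[w] == 0L) {
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          stack[[length(stack) + 1L]] <- list(v = w, pb = k, i = 1L)
        } else {
          low[v] <- min(low[v], disc[w])
          stack[[length(stack)]]$vlow <- low[v]
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack) > 0L) {
          p <- stack[[length(stack)]]$v
          low[p] <- min(low[p], low[v])
          if (low[v] > disc[p]) is_bridge[fr$pb] <- TRUE
        }
      }
    }
  }
  is_bridge
}

# cis/trans tags for double bonds flanked by directional single bonds.
# "/" and "\" encode up/down from the first to the second written atom;
# normalizing both sides to point away from the double bond, equal symbols
# mean cis, unequal mean trans.
perceive_cis_trans <- function(atoms, bonds) {
  nb <- nrow(bonds)
  stereo <- rep("none", nb)
  if (nb == 0L) return(stereo)
  flip <- function(d) if (d == "/") "\\" else "/"
  side_dir <- function(db, v) {
    for (k in seq_len(nb)) {
      if (k == db || bonds$dir[k] == "") next
      if (bonds$a1[k] == v) return(flip(bonds$dir[k]))  # v -> substituent
      if (bonds$a2[k] == v) return(bonds$dir[k])        # substituent -> v
    }
    NA_character_
  }
  for (k in seq_len(nb)) {
    if (bonds$order[k] != 2 || bonds$aromatic[k]) next
    d1 <- side_dir(k, bonds$a1[k])
    d2 <- side_dir(k, bonds$a2[k])
    if (is.na(d1) || is.na(d2)) next
    # both sides normalized to the direction written into the double-bond
    # atom; matching symbols put the two substituents on the same side
    # (C/C=C\C is cis, F/C=C/F is trans)
    stereo[k] <- if (d1 == d2) "cis" else "trans"
  }
  stereo
}

#' Render a parsed molecule back to SMILES with a chosen atom order
#'
#' Produces an alternative, non-canonical SMILES of the same molecule by
#' depth-first traversal from `root`, visiting neighbors in the order induced
#' by `perm`. Used by the fixture generator to exercise atom-order invariance.
#' Stereo and chirality annotations are not emitted.
#'
#' @param mol a `parsed_mol`.
#' @param root starting atom index.
#' @param perm a permutation of atom indices controlling neighbor priority.
#' @return a SMILES string that reparses to an isomorphic graph.
#' @keywords internal
render_smiles <- function(mol, root = 1L, perm = seq_len(nrow(mol$atoms))) {
  atoms <- mol$atoms; bonds <- mol$bonds
  n <- nrow(atoms); nb <- nrow(bonds)
  adj <- vector("list", n)
  if (nb > 0L) for (k in seq_len(nb)) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], k)
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], k)
  }
  prio <- order(perm)
  atom_token <- function(v) {
    sym <- atoms$symbol[v]
    tok <- if (atoms$aromatic[v]) tolower(sym) else sym
    needs_bracket <- atoms$charge[v] != 0L || !is.na(atoms$h_explicit[v]) ||
      !(sym %in% ORGANIC_SUBSET) || atoms$map[v] > 0L ||
      (atoms$aromatic[v] && !sym %in% c("B", "C", "N", "O", "P", "S"))
    if (!needs_bracket) return(tok)
    h <- atoms$h_count[v]
    paste0("[", tok,
           if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
           if (atoms$charge[v] > 0L) paste0("+", if (atoms$charge[v] > 1L) atoms$charge[v] else ""),
           if (atoms$charge[v] < 0L) paste0("-", if (atoms$charge[v] < -1L) -atoms$charge[v] else ""),
           if (atoms$map[v] > 0L) paste0(":", atoms$map[v]) else "", "]")
  }
  bond_token <- function(k) {
    if (bonds$aromatic[k]) "" else if (bonds$order[k] == 2) "="
    else if (bonds$order[k] == 3) "#" else ""
  }
  sorted_adj <- function(v) {
    ks <- adj[[v]]
    if (length(ks) == 0L) return(integer(0))
    ks[order(prio[vapply(ks, function(k) {
      if (bonds$a1[k] == v) bonds$a2[k] else bonds$a1[k]}, 0L)])]
  }
  start_order <- order(prio)
  starts <- c(root, setdiff(start_order, root))

  # pass 1: classify bonds into tree edges and back edges along the same
  # deterministic traversal, assigning ring-closure labels to back edges
  visited <- logical(n); kind <- integer(nb)   # 0 unseen, 1 tree, 2 back
  closure_at <- vector("list", n)              # per atom: closure strings
  next_digit <- 0L
  walk <- function(v, from_bond) {
    visited[v] <<- TRUE
    for (k in sorted_adj(v)) {
      if (!is.na(from_bond) && k == from_bond) next
      if (kind[k] != 0L) next
      w <- if (bonds$a1[k] == v) bonds$a2[k] else bonds$a1[k]
      if (visited[w]) {
        kind[k] <<- 2L
        next_digit <<- next_digit + 1L
        lbl <- if (next_digit < 10L) as.character(next_digit)
               else paste0("%", sprintf("%02d", next_digit))
        tok <- paste0(bond_token(k), lbl)
        closure_at[[v]] <<- c(closure_at[[v]], tok)
        closure_at[[w]] <<- c(closure_at[[w]], tok)
      } else {
        kind[k] <<- 1L
        walk(w, k)
      }
    }
  }
  for (v in starts) if (!visited[v]) walk(v, NA_integer_)

  # pass 2: emit along the tree edges found in pass 1 (each tree edge is
  # reached exactly once from its parent, so no visited bookkeeping needed
  # beyond the root loop)
  emitted <- logical(n)
  emit <- function(v, from_bond) {
    emitted[v] <<- TRUE
    piece <- paste0(atom_token(v), paste(closure_at[[v]], collapse = ""))
    children <- integer(0)
    for (k in sorted_adj(v)) {
      if (!is.na(from_bond) && k == from_bond) next
      if (kind[k] == 1L) children <- c(children, k)
    }
    segs <- character(0)
    for (j in seq_along(children)) {
      k <- children[j]
      w <- if (bonds$a1[k] == v) bonds$a2[k] else bonds$a1[k]
      sub <- paste0(bond_token(k), emit(w, k))
      segs <- c(segs, if (j < length(children)) paste0("(", sub, ")") else sub)
    }
    paste0(piece, paste(segs, collapse = ""))
  }
  pieces <- character(0)
  for (v in starts) if (!emitted[v]) pieces <- c(pieces, emit(v, NA_integer_))
  paste(pieces, collapse = ".")
}

# Canonical hash of the heavy-atom graph via Morgan-style label refinement;
# used to key Bemis-Murcko scaffolds for the scaffold split.
graph_hash <- function(atoms, bonds, rounds = 4L) {
  n <- nrow(atoms)
  if (n == 0L) return("")
  nb <- nrow(bonds)
  # per-atom incident bond-order multiset keeps single/double/aromatic
  # distinctions in the key even after label compression
  ords <- vector("list", n)
  if (nb > 0L) for (k in seq_len(nb)) {
    o <- if (bonds$aromatic[k]) "a" else as.character(bonds$order[k])
    ords[[bonds$a1[k]]] <- c(ords[[bonds$a1[k]]], o)
    ords[[bonds$a2[k]]] <- c(ords[[bonds$a2[k]]], o)
  }
  lab0 <- vapply(seq_len(n), function(v)
    paste(atoms$symbol[v], atoms$aromatic[v], atoms$charge[v],
          atoms$degree[v], paste(sort(ords[[v]]), collapse = ""),
          sep = "|"), "")
  lab <- as.integer(factor(lab0, levels = sort(unique(lab0))))
  for (r in seq_len(rounds)) {
    nbr <- vector("list", n)
    if (nb > 0L) for (k in seq_len(nb)) {
      o <- if (bonds$aromatic[k]) "a" else as.character(bonds$order[k])
      nbr[[bonds$a1[k]]] <- c(nbr[[bonds$a1[k]]], paste0(o, ":", lab[bonds$a2[k]]))
      nbr[[bonds$a2[k]]] <- c(nbr[[bonds$a2[k]]], paste0(o, ":", lab[bonds$a1[k]]))
    }
    newlab <- vapply(seq_len(n), function(v) {
      paste(lab[v], paste(sort(nbr[[v]]), collapse = ","), sep = ";")
    }, "")
    lab <- as.integer(factor(newlab, levels = sort(unique(newlab))))
  }
  paste(sort(paste0(lab0, "~", lab)), collapse = ".")
}

#' Bemis-Murcko style scaffold key of a molecule
#'
#' Iteratively prunes degree-1 atoms until only ring systems and linkers
#' remain, then hashes the remaining graph canonically. Acyclic molecules
#' share the empty scaffold.
#'
#' @param smiles a SMILES string.
#' @return a character scaffold key.
#' @export
#' @examples
#' scaffold_key("c1ccccc1CCO") == scaffold_key("c1ccccc1C")
scaffold_key <- function(smiles) {
  mol <- parse_smiles(smiles)
  atoms <- mol$atoms; bonds <- mol$bonds
  keep <- rep(TRUE, nrow(atoms))
  repeat {
    deg <- integer(nrow(atoms))
    if (nrow(bonds) > 0L) for (k in seq_len(nrow(bonds))) {
      if (keep[bonds$a1[k]] && keep[bonds$a2[k]]) {
        deg[bonds$a1[k]] <- deg[bonds$a1[k]] + 1L
        deg[bonds$a2[k]] <- deg[bonds$a2[k]] + 1L
      }
    }
    prune <- keep & deg <= 1L
    if (!any(prune)) break
    keep[prune] <- FALSE
    if (!any(keep)) break
  }
  if (!any(keep)) return("")
  idx <- which(keep)
  remap <- integer(nrow(atoms)); remap[idx] <- seq_along(idx)
  sub_atoms <- atoms[idx, , drop = FALSE]
  kb <- bonds[keep[bonds$a1] & keep[bonds$a2], , drop = FALSE]
  if (nrow(kb) > 0L) { kb$a1 <- remap[kb$a1]; kb$a2 <- remap[kb$a2] }
  deg <- integer(nrow(sub_atoms))
  if (nrow(kb) > 0L) for (k in seq_len(nrow(kb))) {
    deg[kb$a1[k]] <- deg[kb$a1[k]] + 1L; deg[kb$a2[k]] <- deg[kb$a2[k]] + 1L
  }
  sub_atoms$degree <- deg
  graph_hash(sub_atoms, kb)
}
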