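# Covalent connectivity: bond graphs for ligands (distance + template/heuristic
# bond orders) and proteins (amino-acid templates).

# Side-chain bond templates for the standard amino acids.  Each row:
# atom1, atom2, bond order.  Backbone bonds (N-CA, CA-C, C=O) are added for
# every residue.  Kekule orders are used for His/Trp five-rings so that
# donor/acceptor nitrogens keep their conventional protonation; six-membered
# carbocycles are marked aromatic (order 1.5).
.AA_SIDECHAIN <- list(
  ALA = list(c("CA", "CB", 1)),
  ARG = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "CD", 1),
             c("CD", "NE", 1), c("NE", "CZ", 1), c("CZ", "NH1", 2),
             c("CZ", "NH2", 1)),
  ASN = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "OD1", 2),
             c("CG", "ND2", 1)),
  ASP = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "OD1", 2),
             c("CG", "OD2", 1)),
  CYS = list(c("CA", "CB", 1), c("CB", "SG", 1)),
  GLN = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "CD", 1),
             c("CD", "OE1", 2), c("CD", "NE2", 1)),
  GLU = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "CD", 1),
             c("CD", "OE1", 2), c("CD", "OE2", 1)),
  GLY = list(),
  HIS = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "ND1", 1),
             c("CG", "CD2", 2), c("ND1", "CE1", 2), c("CD2", "NE2", 1),
             c("CE1", "NE2", 1)),
  ILE = list(c("CA", "CB", 1), c("CB", "CG1", 1), c("CB", "CG2", 1),
             c("CG1", "CD1", 1)),
  LEU = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "CD1", 1),
             c("CG", "CD2", 1)),
  LYS = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "CD", 1),
             c("CD", "CE", 1), c("CE", "NZ", 1)),
  MET = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "SD", 1),
             c("SD", "CE", 1)),
  MSE = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "SE", 1),
             c("SE", "CE", 1)),
  PHE = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "CD1", 1.5),
             c("CG", "CD2", 1.5), c("CD1", "CE1", 1.5), c("CD2", "CE2", 1.5),
             c("CE1", "CZ", 1.5), c("CE2", "CZ", 1.5)),
  PRO = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "CD", 1),
             c("CD", "N", 1)),
  SER = list(c("CA", "CB", 1), c("CB", "OG", 1)),
  THR = list(c("CA", "CB", 1), c("CB", "OG1", 1), c("CB", "CG2", 1)),
  TRP = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "CD1", 2),
             c("CG", "CD2", 1), c("CD1", "NE1", 1), c("NE1", "CE2", 1),
             c("CD2", "CE2", 1.5), c("CD2", "CE3", 1.5), c("CE3", "CZ3", 1.5),
             c("CZ3", "CH2", 1.5), c("CH2", "CZ2", 1.5), c("CZ2", "CE2", 1.5)),
  TYR = list(c("CA", "CB", 1), c("CB", "CG", 1), c("CG", "CD1", 1.5),
             c("CG", "CD2", 1.5), c("CD1", "CE1", 1.5), c("CD2", "CE2", 1.5),
             c("CE1", "CZ", 1.5), c("CE2", "CZ", 1.5), c("CZ", "OH", 1)),
  VAL = list(c("CA", "CB", 1), c("CB", "CG1", 1), c("CB", "CG2", 1))
)

# Formal charges at pH 7 conventions: Lys/Arg/N-terminus protonated,
# Asp/Glu/C-terminus deprotonated, His neutral (H on NE2).
.AA_FORMAL <- list(
  LYS = c(NZ = 1L), ARG = c(NH1 = 1L), ASP = c(OD2 = -1L), GLU = c(OE2 = -1L)
)

.new_bondgraph <- function(atoms, edges, formal) {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, edges = edges, formal = formal),
            class = "lig_bondgraph")
}

.empty_edges <- function() {
  data.frame(i = integer(), j = integer(), order = numeric())
}

.add_edge <- function(edges, i, j, order = 1) {
  if (i == j) return(edges)
  a <- min(i, j); b <- max(i, j)
  hit <- edges$i == a & edges$j == b
  if (any(hit)) { edges$order[hit] <- order; return(edges) }
  rbind(edges, data.frame(i = a, j = b, order = order))
}

# Per-atom sum of bond orders.
.order_sums <- function(g) {
  s <- numeric(nrow(g$atoms))
  if (nrow(g$edges)) {
    for (k in seq_len(nrow(g$edges))) {
      s[g$edges$i[k]] <- s[g$edges$i[k]] + g$edges$order[k]
      s[g$edges$j[k]] <- s[g$edges$j[k]] + g$edges$order[k]
    }
  }
  s
}

.degree <- function(g) {
  d <- integer(nrow(g$atoms))
  if (nrow(g$edges)) {
    t1 <- table(factor(g$edges$i, levels = seq_len(nrow(g$atoms))))
    t2 <- table(factor(g$edges$j, levels = seq_len(nrow(g$atoms))))
    d <- as.integer(t1 + t2)
  }
  d
}

.neighbors <- function(g, i) {
  c(g$edges$j[g$edges$i == i], g$edges$i[g$edges$j == i])
}

#' Infer the covalent bond graph of a ligand
#'
#' Heavy-atom bonds are detected by distance (covalent-radius sum plus a
#' 0.45 Angstrom tolerance).  Bond orders and formal charges come from a
#' chemical-component template when the het code is known to the bundled (or
#' a user-supplied) CCD-style dictionary, otherwise from a geometric
#' valence-satisfaction heuristic: short terminal C-O / P-O contacts become
#' carbonyl or phosphoryl double bonds, remaining short terminal oxygens on
#' carboxylate/phosphate groups are deprotonated (formal charge -1, the pH-7
#' convention), short C-C contacts become double/triple bonds, and planarly
#' spaced 5-6-membered rings with bond lengths in the aromatic window are
#' marked aromatic.
#'
#' @param lig A \code{lig_ligand}.
#' @param template_dir Optional directory of CCD-style mmCIF component
#'   definitions (\code{<HET>.cif}); defaults to the dictionary bundled with
#'   the package.
#' @param tol Distance tolerance added to the covalent-radius sum (default
#'   0.45 Angstrom).
#' @return A \code{lig_bondgraph}.
#' @export
infer_ligand_bonds <- function(lig, template_dir = NULL, tol = 0.45) {
  stopifnot(inherits(lig, "lig_ligand"))
  atoms <- lig$atoms
  n <- nrow(atoms)
  el <- atoms$element
  bad <- !is_known_element(el)
  if (any(bad))
    stop("unsupported element(s) in ligand: ",
         paste(unique(el[bad]), collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  edges <- .empty_edges()
  if (n > 1) {
    d2 <- .cross_dist2(xyz, xyz)
    rsum <- outer(.COV_RADII[el], .COV_RADII[el], "+") + tol
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (d2[i, j] < rsum[i, j]^2 && d2[i, j] > 0.16)
        edges <- .add_edge(edges, i, j)
    }
  }
  g <- .new_bondgraph(atoms, edges, numeric(n))

  tpl <- .load_component_template(lig$het_code, template_dir)
  if (!is.null(tpl)) {
    g <- .apply_component_template(g, tpl)
  } else {
    g <- .assign_orders_heuristic(g)
  }

  vmax <- .STD_VALENCE[g$atoms$element] + pmax(g$formal, 0)
  over <- .order_sums(g) > vmax + 1e-9
  if (any(over))
    warning("atom(s) exceed element valence after bond perception: ",
            paste(g$atoms$name[over], collapse = ", "))
  g
}

# ---- CCD-style component templates -----------------------------------------

.load_component_template <- function(het, template_dir = NULL) {
  if (is.null(template_dir))
    template_dir <- system.file("extdata", "components", package = "ligenergy")
  if (!nzchar(template_dir) || !dir.exists(template_dir)) return(NULL)
  f <- file.path(template_dir, paste0(toupper(het), ".cif"))
  if (!file.exists(f)) return(NULL)
  lines <- readLines(f, warn = FALSE)
  bonds <- .cif_loop(lines, "_chem_comp_bond.")
  atoms <- .cif_loop(lines, "_chem_comp_atom.")
  if (is.null(bonds)) return(NULL)
  ord <- c(SING = 1, DOUB = 2, TRIP = 3, AROM = 1.5)
  list(
    bonds = data.frame(
      a1 = bonds[, "atom_id_1"], a2 = bonds[, "atom_id_2"],
      order = unname(ord[toupper(bonds[, "value_order"])]),
      stringsAsFactors = FALSE),
    charges = if (!is.null(atoms) && "charge" %in% colnames(atoms))
      stats::setNames(suppressWarnings(as.numeric(atoms[, "charge"])),
                      atoms[, "atom_id"]) else NULL
  )
}

# Generic single-loop extractor: returns a character matrix with the category
# keys (prefix stripped) as column names, or NULL.
.cif_loop <- function(lines, prefix) {
  idx <- grep("^\\s*loop_\\s*$", lines)
  for (i in idx) {
    j <- i + 1L
    keys <- character()
    while (j <= length(lines) && grepl("^_", trimws(lines[j]))) {
      keys <- c(keys, trimws(lines[j])); j <- j + 1L
    }
    if (!length(keys) || !all(startsWith(keys, prefix))) next
    keys <- sub(paste0("^", prefix), "", keys, fixed = FALSE)
    rows <- list()
    while (j <= length(lines)) {
      tl <- trimws(lines[j])
      if (tl == "" || startsWith(tl, "_") || startsWith(tl, "loop_") ||
          startsWith(tl, "#") || startsWith(tl, "data_")) break
      tok <- scan(text = tl, what = character(), quiet = TRUE)
      if (length(tok) == length(keys)) rows[[length(rows) + 1L]] <- tok
      j <- j + 1L
    }
    if (!length(rows)) return(NULL)
    m <- do.call(rbind, rows)
    colnames(m) <- keys
    return(m)
  }
  NULL
}

.apply_component_template <- function(g, tpl) {
  nm <- g$atoms$name
  for (k in seq_len(nrow(tpl$bonds))) {
    i <- match(tpl$bonds$a1[k], nm); j <- match(tpl$bonds$a2[k], nm)
    if (!is.na(i) && !is.na(j))
      g$edges <- .add_edge(g$edges, i, j, tpl$bonds$order[k])
  }
  if (!is.null(tpl$charges)) {
    hit <- match(nm, names(tpl$charges))
    ch <- tpl$charges[hit]
    ch[is.na(ch)] <- 0
    g$formal <- as.numeric(ch)
  }
  g
}

# ---- heuristic bond orders -------------------------------------------------

.edge_len <- function(g, k) {
  i <- g$edges$i[k]; j <- g$edges$j[k]
  sqrt(sum((unlist(g$atoms[i, c("x", "y", "z")]) -
              unlist(g$atoms[j, c("x", "y", "z")]))^2))
}

.assign_orders_heuristic <- function(g) {
  if (!nrow(g$edges)) return(g)
  len <- vapply(seq_len(nrow(g$edges)), function(k) .edge_len(g, k), 0)
  deg <- .degree(g)
  el <- g$atoms$element

  # aromatic rings (size 5-6, C/N members, bond lengths in aromatic window)
  rings <- .find_small_rings(g, max_size = 6L)
  for (ring in rings) {
    ek <- .ring_edges(g, ring)
    if (!length(ek)) next
    members_ok <- all(el[ring] %in% c("C", "N"))
    len_ok <- all(len[ek] > 1.28 & len[ek] < 1.45)
    if (members_ok && len_ok && .ring_planar(g, ring))
      g$edges$order[ek] <- 1.5
  }

  # carbonyl / carboxylate on carbon
  for (i in which(el == "C")) {
    nb <- .neighbors(g, i)
    termO <- nb[el[nb] == "O" & deg[nb] == 1L]
    if (!length(termO)) next
    dts <- vapply(termO, function(j) .pair_len(g, i, j), 0)
    if (length(termO) >= 2L && all(dts < 1.32)) {
      # carboxylate: shortest O double-bonded, the rest deprotonated
      o <- termO[order(dts)]
      g$edges <- .add_edge(g$edges, i, o[1], 2)
      for (j in o[-1]) g$formal[j] <- -1
    } else if (min(dts) < 1.28) {
      g$edges <- .add_edge(g$edges, i, termO[which.min(dts)], 2)
    }
  }

  # phosphoryl / phosphate (and sulfate-like S)
  for (i in which(el %in% c("P", "S") & deg >= 3L)) {
    nb <- .neighbors(g, i)
    termO <- nb[el[nb] == "O" & deg[nb] == 1L]
    if (!length(termO)) next
    dts <- vapply(termO, function(j) .pair_len(g, i, j), 0)
    o <- termO[order(dts)]
    g$edges <- .add_edge(g$edges, i, o[1], 2)
    for (j in o[-1]) if (.pair_len(g, i, j) < 1.60) g$formal[j] <- -1
  }

  # short C-C / C-N multiple bonds outside rings already handled
  len <- vapply(seq_len(nrow(g$edges)), function(k) .edge_len(g, k), 0)
  for (k in seq_len(nrow(g$edges))) {
    if (g$edges$order[k] != 1) next
    i <- g$edges$i[k]; j <- g$edges$j[k]
    pair <- sort(c(el[i], el[j]))
    if (identical(pair, c("C", "C"))) {
      if (len[k] < 1.22) g$edges$order[k] <- 3
      else if (len[k] < 1.35) g$edges$order[k] <- 2
    } else if (identical(pair, c("C", "N"))) {
      if (len[k] < 1.20) g$edges$order[k] <- 3
      else if (len[k] < 1.30) g$edges$order[k] <- 2
    }
  }
  g
}

.pair_len <- function(g, i, j) {
  sqrt(sum((unlist(g$atoms[i, c("x", "y", "z")]) -
              unlist(g$atoms[j, c("x", "y", "z")]))^2))
}

# Enumerate simple cycles of size 3..max_size (small molecules only).
.find_small_rings <- function(g, max_size = 6L) {
  n <- nrow(g$atoms)
  adj <- lapply(seq_len(n), function(i) sort(.neighbors(g, i)))
  rings <- list()
  seen <- character()
  walk <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == path[1] && length(path) >= 3L) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (!(nb %in% path) && length(path) < max_size && nb > path[1]) {
        walk(c(path, nb))
      }
    }
  }
  for (i in seq_len(n)) walk(i)
  rings
}

.ring_edges <- function(g, ring) {
  ek <- integer()
  m <- length(ring)
  for (t in seq_len(m)) {
    i <- ring[t]; j <- ring[if (t == m) 1L else t + 1L]
    a <- min(i, j); b <- max(i, j)
    k <- which(g$edges$i == a & g$edges$j == b)
    if (length(k)) ek <- c(ek, k[1])
  }
  ek
}

.ring_planar <- function(g, ring, tol = 0.15) {
  P <- as.matrix(g$atoms[ring, c("x", "y", "z")])
  P <- sweep(P, 2, colMeans(P))
  sv <- svd(P)
  sv$d[3] / sqrt(length(ring)) < tol
}

#' Build the covalent bond graph of the protein component
#'
#' Intra-residue bonds come from amino-acid templates (Kekule orders for
#' His/Trp rings, aromatic orders for six-membered carbocycles); peptide
#' bonds C(i)-N(i+1) are added when the distance is below 1.8 Angstrom (chain
#' breaks simply omit the edge), and disulfides when two SG atoms are closer
#' than 2.3 Angstrom.  Nonstandard residues fall back to distance-based
#' inference.  Formal charges follow pH-7 conventions: protonated Lys/Arg and
#' N-termini, deprotonated Asp/Glu and C-terminal OXT, neutral His with the
#' proton on NE2.
#'
#' @param s A \code{lig_structure} (altlocs should be collapsed first).
#' @return A \code{lig_bondgraph} over the polymer heavy atoms.
#' @export
protein_connectivity <- function(s) {
  stopifnot(inherits(s, "lig_structure"))
  a <- s$atoms
  keep <- a$is_polymer & !(a$element %in% c("H", "D"))
  if (!any(keep)) stop("structure has no polymer atoms")
  atoms <- a[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  n <- nrow(atoms)
  edges <- .empty_edges()
  formal <- numeric(n)

  rkey <- paste(atoms$chain, atoms$resseq, atoms$inscode, sep = "|")
  resids <- unique(rkey)
  for (rk in resids) {
    rows <- which(rkey == rk)
    resname <- atoms$resname[rows[1]]
    tpl <- .AA_SIDECHAIN[[resname]]
    if (is.null(tpl)) {
      # nonstandard residue: distance-based fallback
      xyz <- as.matrix(atoms[rows, c("x", "y", "z")])
      if (length(rows) > 1) {
        d2 <- .cross_dist2(xyz, xyz)
        rs <- outer(.COV_RADII[atoms$element[rows]],
                    .COV_RADII[atoms$element[rows]], "+") + 0.45
        for (u in seq_along(rows)[-length(rows)])
          for (v in (u + 1):length(rows))
            if (!is.na(d2[u, v]) && d2[u, v] < rs[u, v]^2 && d2[u, v] > 0.16)
              edges <- .add_edge(edges, rows[u], rows[v])
      }
      next
    }
    bb <- list(c("N", "CA", 1), c("CA", "C", 1), c("C", "O", 2),
               c("C", "OXT", 1))
    for (bnd in c(bb, tpl)) {
      i <- rows[match(bnd[1], atoms$name[rows])]
      j <- rows[match(bnd[2], atoms$name[rows])]
      if (!is.na(i) && !is.na(j))
        edges <- .add_edge(edges, i, j, as.numeric(bnd[3]))
    }
    fc <- .AA_FORMAL[[resname]]
    if (!is.null(fc)) {
      for (nm in names(fc)) {
        i <- rows[match(nm, atoms$name[rows])]
        if (!is.na(i)) formal[i] <- fc[[nm]]
      }
    }
    oxt <- rows[match("OXT", atoms$name[rows])]
    if (!is.na(oxt)) formal[oxt] <- -1
  }

  # peptide bonds between consecutive residues of the same chain
  for (ch in unique(atoms$chain)) {
    rres <- unique(rkey[atoms$chain == ch])
    if (length(rres) < 2) next
    for (t in seq_len(length(rres) - 1L)) {
      ci <- which(rkey == rres[t] & atoms$name == "C")
      ni <- which(rkey == rres[t + 1L] & atoms$name == "N")
      if (length(ci) == 1L && length(ni) == 1L) {
        d <- .pair_len(list(atoms = atoms), ci, ni)
        if (d < 1.8) edges <- .add_edge(edges, ci, ni, 1)
      }
    }
  }

  # disulfides
  sg <- which(atoms$name == "SG" & atoms$element == "S")
  if (length(sg) > 1) {
    for (u in seq_along(sg)[-length(sg)]) for (v in (u + 1):length(sg)) {
      d <- .pair_len(list(atoms = atoms), sg[u], sg[v])
      if (d < 2.3) edges <- .add_edge(edges, sg[u], sg[v], 1)
    }
  }

  g <- .new_bondgraph(atoms, edges, formal)

  # protonated N-termini: first residue of each chain whose N has no incoming
  # peptide bond
  osum <- .order_sums(g)
  for (ch in unique(atoms$chain)) {
    rows <- which(atoms$chain == ch)
    ni <- rows[atoms$name[rows] == "N"]
    if (!length(ni)) next
    first_n <- ni[1]
    nb <- .neighbors(g, first_n)
    has_prev_c <- any(atoms$name[nb] == "C" & rkey[nb] != rkey[first_n])
    if (!has_prev_c) g$formal[first_n] <- 1
  }
  g
}

#' @export
print.lig_bondgraph <- function(x, ...) {
  cat("lig_bondgraph:", nrow(x$atoms), "atoms,", nrow(x$edges), "bonds,",
      "net formal charge", sum(x$formal), "\n")
  invisible(x)
}
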