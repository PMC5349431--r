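# Riding-position placement of polar hydrogens.  Only hydrogens bonded to
# N, O or S are modelled; apolar C-H hydrogens are never added (their charge
# contribution is folded into the parent carbon during PEOE).

.HX_LEN <- c(N = 1.00, O = 0.96, S = 1.34, Se = 1.46)

# Number of hydrogens expected on a heavy atom from its element, formal
# charge and sum of bond orders.
.expected_h <- function(element, formal, order_sum) {
  base <- switch(element, N = 3, O = 2, S = 2, Se = 2, return(0L))
  max(0L, as.integer(round(base + formal - order_sum)))
}

#' Add polar hydrogens at riding positions
#'
#' Hydrogens are generated only on N/O/S donors, at idealized geometry
#' (1.00 Angstrom N-H, 0.96 Angstrom O-H, 1.34 Angstrom S-H): amide and
#' ring N-H along the in-plane bisector, sp2 NH2 groups in the conjugation
#' plane, sp3 ammonium hydrogens staggered, and rotatable hydroxyls anti to
#' the heaviest substituent of the parent's neighbour.  The hydrogen count
#' follows element valence, bond orders and formal charge, so carbonyl and
#' deprotonated oxygens receive none.  Added hydrogens inherit the parent's
#' occupancy and ADP.
#'
#' @param g A \code{lig_bondgraph}.
#' @return A \code{lig_bondgraph} whose atom table is extended with hydrogen
#'   rows (columns \code{is_h} and \code{parent} identify them) and whose
#'   edge list contains the new X-H bonds.
#' @export
place_polar_hydrogens <- function(g) {
  stopifnot(inherits(g, "lig_bondgraph"))
  atoms <- g$atoms
  if (is.null(atoms$is_h)) atoms$is_h <- atoms$element %in% c("H", "D")
  if (is.null(atoms$parent)) atoms$parent <- NA_integer_
  osum <- .order_sums(g)
  n0 <- nrow(atoms)
  new_rows <- list(); new_edges <- list()

  for (i in seq_len(n0)) {
    el <- atoms$element[i]
    if (!(el %in% names(.HX_LEN))) next
    nh <- .expected_h(el, g$formal[i], osum[i])
    if (nh == 0L) next
    nb <- .neighbors(g, i)
    nb <- nb[!atoms$is_h[nb]]
    if (!length(nb)) {
      warning("no geometric context to place H on isolated atom ",
              atoms$name[i], "; skipped")
      next
    }
    P <- function(k) as.numeric(atoms[k, c("x", "y", "z")])
    blen <- .HX_LEN[[el]]
    pos <- .place_h_set(P, i, nb, nh, blen, g, atoms)
    if (is.null(pos)) next
    for (h in seq_len(nrow(pos))) {
      nm <- .h_name(atoms$name[i], h, nh)
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        serial = NA_integer_, name = nm, element = "H",
        x = pos[h, 1], y = pos[h, 2], z = pos[h, 3],
        occ = atoms$occ[i], b = atoms$b[i], altloc = atoms$altloc[i],
        resname = atoms$resname[i], resseq = atoms$resseq[i],
        inscode = atoms$inscode[i], chain = atoms$chain[i],
        is_water = FALSE,
        is_polymer = atoms$is_polymer[i],
        is_h = TRUE, parent = i, stringsAsFactors = FALSE)
      new_edges[[length(new_edges) + 1L]] <- i
    }
  }
  if (length(new_rows)) {
    add <- do.call(rbind, new_rows)
    # align columns with existing table
    for (cn in setdiff(names(atoms), names(add))) add[[cn]] <- NA
    add <- add[, names(atoms)]
    atoms <- rbind(atoms, add)
    g$formal <- c(g$formal, numeric(nrow(add)))
    for (t in seq_along(new_edges)) {
      g$edges <- rbind(g$edges,
                       data.frame(i = new_edges[[t]], j = n0 + t, order = 1))
    }
  }
  rownames(atoms) <- NULL
  g$atoms <- atoms
  g
}

.h_name <- function(parent_name, k, total) {
  stem <- if (parent_name == "N") "H" else sub("^[A-Za-z]", "H", parent_name)
  if (total == 1L) stem else paste0(stem, k)
}

# Compute nh hydrogen positions around atom i with heavy neighbours nb.
.place_h_set <- function(P, i, nb, nh, blen, g, atoms) {
  A <- P(i)
  deg <- length(nb)
  # reference atom: a heavy substituent of the first neighbour (not i),
  # heaviest element first, for dihedral placement
  ref_of <- function(nbid) {
    others <- .neighbors(g, nbid)
    others <- others[others != i & !atoms$is_h[others]]
    if (!length(others)) return(NULL)
    w <- .COV_RADII[atoms$element[others]]
    others[order(-w, others)][1]
  }
  sp2_parent <- {
    # conjugated if any bond at the parent or its neighbour is not single
    osum_nb <- .order_sums(g)
    any(g$edges$order[g$edges$i %in% c(i, nb) | g$edges$j %in% c(i, nb)] > 1)
  }
  out <- NULL
  if (deg >= 2L && nh == 1L) {
    u <- rowMeans(vapply(nb, function(k) .unit(P(k) - A), numeric(3)))
    if (sqrt(sum(u^2)) < 1e-8) return(NULL)
    out <- matrix(A - blen * .unit(u), nrow = 1)
  } else if (deg == 1L && nh == 1L) {
    B <- P(nb[1]); refi <- ref_of(nb[1])
    C <- if (is.null(refi)) NULL else P(refi)
    theta <- if (sp2_parent) 120 else
      if (atoms$element[i] == "S") 96 else 108.5
    out <- matrix(.place_internal(A, B, C, blen, theta, 180), nrow = 1)
  } else if (deg == 1L && nh == 2L) {
    B <- P(nb[1]); refi <- ref_of(nb[1])
    C <- if (is.null(refi)) NULL else P(refi)
    if (sp2_parent) {
      out <- rbind(.place_internal(A, B, C, blen, 120, 0),
                   .place_internal(A, B, C, blen, 120, 180))
    } else {
      out <- rbind(.place_internal(A, B, C, blen, 109.5, 60),
                   .place_internal(A, B, C, blen, 109.5, 300))
    }
  } else if (deg == 1L && nh >= 3L) {
    B <- P(nb[1]); refi <- ref_of(nb[1])
    C <- if (is.null(refi)) NULL else P(refi)
    out <- rbind(.place_internal(A, B, C, blen, 109.5, 60),
                 .place_internal(A, B, C, blen, 109.5, 180),
                 .place_internal(A, B, C, blen, 109.5, 300))
  } else if (deg == 2L && nh == 2L) {
    u1 <- .unit(P(nb[1]) - A); u2 <- .unit(P(nb[2]) - A)
    bis <- -.unit(u1 + u2)
    perp <- .unit(.vcross(u1, u2))
    half <- 54.75 * pi / 180
    out <- rbind(A + blen * .unit(bis * cos(half) + perp * sin(half)),
                 A + blen * .unit(bis * cos(half) - perp * sin(half)))
  } else if (deg >= 3L && nh == 1L) {
    u <- rowMeans(vapply(nb, function(k) .unit(P(k) - A), numeric(3)))
    out <- matrix(A - blen * .unit(u), nrow = 1)
  }
  out
}
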