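# AutoDock-4-style atom typing.

#' Assign force-field atom types
#'
#' Maps every atom of a (hydrogen-complete, charged) bond graph to one
#' AD4-style type: aliphatic carbon \code{C} vs aromatic carbon \code{A};
#' nitrogen \code{N} (carrying hydrogens, donor parent) vs hydrogen-bond
#' accepting \code{NA}; oxygen \code{OA} (always an acceptor); sulfur
#' \code{SA} (acceptor) except in disulfides (\code{S}); phosphorus \code{P};
#' halogens by element; and polar hydrogen \code{HD}.  Apolar hydrogens are
#' never present by construction.
#'
#' @param g A \code{lig_bondgraph} after \code{\link{place_polar_hydrogens}}.
#' @param charges Optional per-atom partial charges (defaults to
#'   \code{\link{compute_peoe_charges}} on \code{g}).
#' @return A data frame of typed atoms: the atom table of \code{g} plus
#'   columns \code{ff_type}, \code{charge}, \code{is_polar_h},
#'   \code{is_donor_h}, \code{is_acceptor}, and for hydrogens the coordinates
#'   of the parent donor atom (\code{dx}, \code{dy}, \code{dz}) used for
#'   hydrogen-bond directionality.
#' @export
assign_atom_types <- function(g, charges = NULL) {
  stopifnot(inherits(g, "lig_bondgraph"))
  if (is.null(charges)) charges <- compute_peoe_charges(g)
  atoms <- g$atoms
  n <- nrow(atoms)
  stopifnot(length(charges) == n)
  osum <- .order_sums(g)
  if (is.null(atoms$is_h)) atoms$is_h <- atoms$element %in% c("H", "D")

  # aromatic: atoms with an explicit aromatic bond, plus members of planar
  # 5/6-rings of C/N/O/S whose carbons all take part in a multiple bond
  # (Kekule-ordered rings from residue or component templates)
  aromatic <- logical(n)
  if (nrow(g$edges)) {
    ar <- g$edges$order == 1.5
    aromatic[unique(c(g$edges$i[ar], g$edges$j[ar]))] <- TRUE
    multi <- logical(n)
    mu <- g$edges$order > 1
    multi[unique(c(g$edges$i[mu], g$edges$j[mu]))] <- TRUE
    for (ring in .find_small_rings(g, max_size = 6L)) {
      if (!all(atoms$element[ring] %in% c("C", "N", "O", "S"))) next
      carbons <- ring[atoms$element[ring] == "C"]
      if (length(carbons) && !all(multi[carbons])) next
      if (!.ring_planar(g, ring)) next
      aromatic[ring] <- TRUE
    }
  }
  if (is.null(atoms$parent)) atoms$parent <- NA_integer_
  has_h <- logical(n)
  for (i in which(atoms$is_h)) {
    nb <- .neighbors(g, i)
    nb <- nb[!atoms$is_h[nb]]
    has_h[nb] <- TRUE
    if (is.na(atoms$parent[i]) && length(nb)) atoms$parent[i] <- nb[1]
  }

  type <- character(n)
  for (i in seq_len(n)) {
    el <- atoms$element[i]
    type[i] <- switch(el,
      H = , D = "HD",
      C = if (aromatic[i]) "A" else "C",
      N = if (has_h[i]) "N" else "NA",
      O = "OA",
      S = , Se = {
        nb <- .neighbors(g, i)
        if (any(atoms$element[nb] %in% c("S", "Se"))) "S" else "SA"
      },
      P = "P",
      F = "F", Cl = "Cl", Br = "Br", I = "I",
      stop("untypable element: ", el)
    )
  }

  atoms$ff_type <- type
  atoms$charge <- charges
  atoms$is_polar_h <- atoms$is_h
  atoms$is_donor_h <- atoms$is_h & !is.na(atoms$parent)
  atoms$is_acceptor <- type %in% c("NA", "OA", "SA")
  atoms$dx <- atoms$dy <- atoms$dz <- NA_real_
  hs <- which(atoms$is_donor_h)
  if (length(hs)) {
    atoms$dx[hs] <- atoms$x[atoms$parent[hs]]
    atoms$dy[hs] <- atoms$y[atoms$parent[hs]]
    atoms$dz[hs] <- atoms$z[atoms$parent[hs]]
  }
  atoms
}
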