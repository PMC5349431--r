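# Gasteiger-Marsili partial charges by partial equalization of orbital
# electronegativities (PEOE).

# Map an atom to its PEOE coefficient class from element and bond orders.
.peoe_class <- function(element, order_sum, orders) {
  has_triple <- any(orders >= 3)
  has_multi <- any(orders > 1)
  switch(element,
    H = , D = "H",
    C = if (has_triple) "C.sp" else if (has_multi) "C.sp2" else "C.sp3",
    N = if (has_triple) "N.sp" else if (has_multi) "N.sp2" else "N.sp3",
    O = if (has_multi) "O.sp2" else "O.sp3",
    F = "F", Cl = "Cl", Br = "Br", I = "I",
    S = , Se = "S.sp3",
    P = "P.sp3",
    stop("element not supported by the PEOE charge model: ", element)
  )
}

#' Gasteiger-Marsili (PEOE) partial charges
#'
#' Iterative electronegativity equalization: at iteration \eqn{k} a charge
#' increment proportional to the electronegativity difference across each
#' bond, damped by \eqn{(1/2)^k}, flows from the less to the more
#' electronegative atom; the per-atom electronegativity is the quadratic
#' \eqn{\chi(q) = a + b q + c q^2} with the published orbital coefficients.
#' Hydrogens missing from the graph (apolar C-H) are accounted for by
#' temporary implicit-hydrogen nodes whose converged charges are folded back
#' into the parent carbon, the united-atom convention of polar-hydrogen-only
#' models.  Charges are seeded from formal charges, so each connected
#' component conserves its total formal charge exactly.
#'
#' @param g A \code{lig_bondgraph} (after \code{\link{place_polar_hydrogens}}
#'   if explicit polar hydrogens are wanted).
#' @param n_iter Number of damped iterations (default 8; the schedule
#'   converges in 6-8).
#' @return Numeric vector of partial charges (elementary-charge units), one
#'   per atom of \code{g}, in atom order.
#' @export
compute_peoe_charges <- function(g, n_iter = 8L) {
  stopifnot(inherits(g, "lig_bondgraph"))
  atoms <- g$atoms
  n <- nrow(atoms)
  if (!n) return(numeric())
  edges <- g$edges
  osum <- .order_sums(g)

  orders_of <- function(i) edges$order[edges$i == i | edges$j == i]
  cls <- character(n)
  for (i in seq_len(n))
    cls[i] <- .peoe_class(atoms$element[i], osum[i], orders_of(i))

  # implicit hydrogens on carbon (and any other element whose valence is not
  # saturated by explicit bonds and formal charge)
  imp <- integer(n)
  for (i in seq_len(n)) {
    el <- atoms$element[i]
    if (el %in% c("H", "D")) next
    if (el %in% c("N", "O", "S", "Se")) next  # donors get explicit H
    v <- .STD_VALENCE[[el]]
    if (el == "P") v <- 5
    imp[i] <- max(0L, as.integer(round(v + g$formal[i] - osum[i])))
  }

  nv <- n + sum(imp)
  a <- b <- cc <- chip <- numeric(nv)
  par_of <- function(class) .PEOE_COEF[[class]]
  for (i in seq_len(n)) {
    p <- par_of(cls[i])
    a[i] <- p[1]; b[i] <- p[2]; cc[i] <- p[3]
    chip[i] <- .peoe_chi_plus(cls[i])
  }
  ei <- edges$i; ej <- edges$j
  virt_parent <- integer(0)
  k <- n
  hp <- .PEOE_COEF[["H"]]
  for (i in which(imp > 0L)) {
    for (t in seq_len(imp[i])) {
      k <- k + 1L
      a[k] <- hp[1]; b[k] <- hp[2]; cc[k] <- hp[3]; chip[k] <- 20.02
      ei <- c(ei, i); ej <- c(ej, k)
      virt_parent <- c(virt_parent, i)
    }
  }

  q <- c(g$formal, numeric(nv - n))
  for (it in seq_len(n_iter)) {
    chi <- a + b * q + cc * q^2
    damp <- 0.5^it
    dq <- numeric(nv)
    for (t in seq_along(ei)) {
      i <- ei[t]; j <- ej[t]
      if (chi[j] > chi[i]) { lo <- i; hi <- j } else { lo <- j; hi <- i }
      tr <- (chi[hi] - chi[lo]) / chip[lo] * damp
      dq[lo] <- dq[lo] + tr; dq[hi] <- dq[hi] - tr
    }
    q <- q + dq
  }

  # fold implicit-H charges into their parent atoms
  if (length(virt_parent)) {
    for (t in seq_along(virt_parent)) {
      p <- virt_parent[t]
      q[p] <- q[p] + q[n + t]
    }
  }
  q <- q[seq_len(n)]
  stopifnot(all(abs(q) < 2))
  q
}
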