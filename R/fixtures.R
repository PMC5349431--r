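# Synthetic protein-pocket/ligand mini-complexes with known interaction
# character.  A short tetrapeptide (Ala-Lys-Ser-Gly, built at idealized
# extended-chain geometry, zwitterionic termini) provides backbone amide
# donors, carbonyl acceptors, the Lys ammonium cation and the Ser hydroxyl;
# a ligand archetype is placed against it at a controlled key distance.

.FIXTURE_KINDS <- c("hbond_pair", "salt_bridge", "clash", "inert_surface",
                    "peg_like", "covalent_suspect")

.FIXTURE_DEFAULT_DIST <- c(
  hbond_pair = 1.9,       # polar H ... acceptor O, Angstrom
  salt_bridge = 2.8,      # N+ ... O- heavy-atom separation
  clash = 1.0,            # severe overlap
  inert_surface = 6.5,    # minimum gap to the protein
  peg_like = 4.0,         # grazing surface separation
  covalent_suspect = 1.3  # unannotated covalent-bond regime
)

#' Generate a synthetic protein-ligand test complex
#'
#' Builds a minimal, chemically sensible complex of a tetrapeptide and a
#' ligand archetype: \code{hbond_pair} (ligand ketone oxygen accepting from
#' a backbone amide at the given H...O distance, alkyl tail in van der Waals
#' contact with the peptide), \code{salt_bridge} (carboxylate against the
#' Lys ammonium group), \code{clash} (an alkyl carbon far inside the
#' repulsive wall of a backbone oxygen), \code{inert_surface} (an alkane
#' separated from the protein by at least the given gap), \code{peg_like}
#' (an ethylene-glycol oligomer grazing the surface) and
#' \code{covalent_suspect} (a ligand carbon at covalent-bond distance from
#' the Ser hydroxyl oxygen, emulating unannotated covalency).
#'
#' All ligands carry 10-50 heavy atoms so they qualify for
#' \code{\link{select_primary_ligand}}; the \code{clash} and
#' \code{covalent_suspect} ligands sit inside the covalent-distance screen
#' and must be scored by explicit reference (\code{"LG1:A:901"}).  The seed
#' controls a small (0.01 Angstrom) jitter on tail atoms; a fixed spec is
#' byte-identical across runs.
#'
#' @param kind One of \code{"hbond_pair"}, \code{"salt_bridge"},
#'   \code{"clash"}, \code{"inert_surface"}, \code{"peg_like"},
#'   \code{"covalent_suspect"}.
#' @param distance Key geometry parameter in Angstrom (see above; per-kind
#'   default when \code{NULL}).
#' @param seed Integer seed for the tail jitter.
#' @return A \code{lig_structure} (writable with
#'   \code{\link{write_structure}}); the ligand is residue \code{LG1 A 901}.
#' @examples
#' s <- make_fixture("clash")
#' rep <- score_complex(s, ligand = "LG1:A:901")
#' rep$category
#' @export
make_fixture <- function(kind, distance = NULL, seed = 1L) {
  if (!kind %in% .FIXTURE_KINDS)
    stop("invalid fixture kind '", kind, "'; must be one of: ",
         paste(.FIXTURE_KINDS, collapse = ", "))
  d <- if (is.null(distance)) .FIXTURE_DEFAULT_DIST[[kind]] else distance
  stopifnot(d > 0)

  pep <- .build_peptide(c("ALA", "LYS", "SER", "GLY"))
  P <- function(res, nm) {
    i <- which(pep$resseq == res & pep$name == nm)
    as.numeric(pep[i, c("x", "y", "z")])
  }
  centroid <- colMeans(as.matrix(pep[, c("x", "y", "z")]))

  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(rng_state)) assign(".Random.seed", rng_state,
                                    envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  lig <- switch(kind,
    hbond_pair = .fx_hbond(pep, P, centroid, d),
    salt_bridge = .fx_salt(pep, P, centroid, d),
    clash = .fx_clash(pep, P, centroid, d),
    inert_surface = .fx_offset_chain(pep, d, peg = FALSE),
    peg_like = .fx_offset_chain(pep, d, peg = TRUE),
    covalent_suspect = .fx_covalent(pep, P, centroid, d)
  )

  atoms <- rbind(pep, lig)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 entry_id = paste0("fx-", kind),
                 links = .empty_links()),
            class = "lig_structure")
}

# ---- peptide scaffold ------------------------------------------------------

.build_peptide <- function(seq) {
  phi <- -140; psi <- 135; omega <- 180
  rows <- list()
  add <- function(res, nm, el, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = NA_integer_, name = nm, element = el,
      x = p[1], y = p[2], z = p[3], occ = 1, b = 20, altloc = "",
      resname = seq[res], resseq = res, inscode = "", chain = "A",
      is_water = FALSE, is_polymer = TRUE, stringsAsFactors = FALSE)
  }
  Nprev <- CAprev <- Cprev <- NULL
  for (i in seq_along(seq)) {
    if (i == 1L) {
      N <- c(0, 0, 0)
      CA <- N + c(1.458, 0, 0)
      C <- .place_internal(CA, N, NULL, 1.525, 111, 0)
    } else {
      N <- .place_internal(Cprev, CAprev, Nprev, 1.329, 116.6, psi)
      CA <- .place_internal(N, Cprev, CAprev, 1.458, 121.7, omega)
      C <- .place_internal(CA, N, Cprev, 1.525, 111, phi)
    }
    O <- .place_internal(C, CA, N, 1.231, 120.8, psi + 180)
    add(i, "N", "N", N); add(i, "CA", "C", CA); add(i, "C", "C", C)
    add(i, "O", "O", O)
    if (seq[i] != "GLY") {
      CB <- .place_internal(CA, N, if (i > 1) Cprev else NULL, 1.53, 110.5,
                            -122)
      add(i, "CB", "C", CB)
      if (seq[i] == "LYS") {
        CG <- .place_internal(CB, CA, N, 1.53, 112, 180)
        CD <- .place_internal(CG, CB, CA, 1.53, 112, 180)
        CE <- .place_internal(CD, CG, CB, 1.53, 112, 180)
        NZ <- .place_internal(CE, CD, CG, 1.49, 112, 180)
        add(i, "CG", "C", CG); add(i, "CD", "C", CD)
        add(i, "CE", "C", CE); add(i, "NZ", "N", NZ)
      } else if (seq[i] == "SER") {
        OG <- .place_internal(CB, CA, N, 1.41, 110.5, 180)
        add(i, "OG", "O", OG)
      } else if (seq[i] == "ASP") {
        CG <- .place_internal(CB, CA, N, 1.52, 112, 180)
        OD1 <- .place_internal(CG, CB, CA, 1.23, 118, 0)
        OD2 <- .place_internal(CG, CB, CA, 1.26, 118, 180)
        add(i, "CG", "C", CG); add(i, "OD1", "O", OD1); add(i, "OD2", "O", OD2)
      }
    }
    if (i == length(seq)) {
      OXT <- .place_internal(C, CA, N, 1.25, 117, psi)
      add(i, "OXT", "O", OXT)
    }
    Nprev <- N; CAprev <- CA; Cprev <- C
  }
  do.call(rbind, rows)
}

# ---- ligand builders -------------------------------------------------------

.lig_row <- function(nm, el, p) {
  data.frame(serial = NA_integer_, name = nm, element = el,
             x = p[1], y = p[2], z = p[3], occ = 1, b = 30, altloc = "",
             resname = "LG1", resseq = 901L, inscode = "", chain = "A",
             is_water = FALSE, is_polymer = FALSE, stringsAsFactors = FALSE)
}

# zigzag chain positions from (excluding) `from` along `u`, lateral axis `v`
.zigzag <- function(from, u, v, n, bond = 1.53) {
  a <- 1.268 * bond / 1.53; b <- 0.856 * bond / 1.53
  out <- matrix(0, n, 3)
  p <- from; s <- 1
  for (k in seq_len(n)) {
    p <- p + a * u + s * b * v
    out[k, ] <- p
    s <- -s
  }
  out
}

.jitter <- function(M, sd = 0.01) M + matrix(stats::rnorm(length(M), 0, sd),
                                             nrow(M), ncol(M))

# replicate the scorer's riding amide H of residue `res` (bisector rule)
.amide_h <- function(P, res) {
  N <- P(res, "N"); CA <- P(res, "CA"); Cp <- P(res - 1L, "C")
  N - 1.0 * .unit(.unit(CA - N) + .unit(Cp - N))
}

.tail_frame <- function(u) {
  w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- .unit(.vcross(u, w))
  list(u = u, v = v)
}

.fx_hbond <- function(pep, P, centroid, d) {
  N2 <- P(2, "N")
  H2 <- .amide_h(P, 2)
  u <- .unit(H2 - N2)
  O1 <- H2 + d * u
  C1 <- .place_internal(O1, H2, N2, 1.23, 120, 0)
  C2 <- .place_internal(C1, O1, H2, 1.51, 120, 180)  # methyl
  # tail parallel to the peptide long axis, in vdW contact with the surface
  axis <- .unit(P(4, "CA") - P(1, "CA"))
  axis <- .unit(axis - sum(axis * u) * u)
  fr <- .tail_frame(axis)
  tail <- .zigzag(C1, fr$u, fr$v, 8)
  tail <- .push_out(tail, pep, u, min_gap = 3.3)
  tail <- .jitter(tail)
  rows <- list(.lig_row("O1", "O", O1), .lig_row("C1", "C", C1),
               .lig_row("C2", "C", C2))
  for (k in seq_len(nrow(tail)))
    rows[[length(rows) + 1L]] <- .lig_row(paste0("C", k + 2), "C", tail[k, ])
  do.call(rbind, rows)
}

.fx_salt <- function(pep, P, centroid, d) {
  NZ <- P(2, "NZ"); CE <- P(2, "CE"); CD <- P(2, "CD")
  PM <- as.matrix(pep[, c("x", "y", "z")])
  mindist <- function(p) sqrt(min(.cross_dist2(matrix(p, 1), PM)))
  # riding ammonium hydrogens as the scorer will place them; approach along
  # the one pointing away from the peptide
  hs <- lapply(c(60, 180, 300),
               function(ph) .place_internal(NZ, CE, CD, 1.0, 109.5, ph))
  H1 <- hs[[which.max(vapply(hs, function(h) mindist(NZ + 2.8 * .unit(h - NZ)),
                             0))]]
  u <- .unit(H1 - NZ)
  O1 <- NZ + d * u                                   # charged oxygen
  # orient the carboxylate plane so the carbon (and tail) leave the surface
  ccs <- lapply(c(0, 90, 180, 270),
                function(ph) .place_internal(O1, NZ, CE, 1.26, 120, ph))
  Cc <- ccs[[which.max(vapply(ccs, mindist, 0))]]
  O2 <- .place_internal(Cc, O1, NZ, 1.23, 124, 180)  # carbonyl oxygen
  # tail leaves along the carboxylate bisector, away from both oxygens
  out_dir <- .unit(Cc - (O1 + O2) / 2)
  fr <- .tail_frame(out_dir)
  tail <- .zigzag(Cc, fr$u, fr$v, 9)
  tail <- .jitter(.push_out(tail, pep, out_dir, min_gap = 3.0))
  rows <- list(.lig_row("O1", "O", O1), .lig_row("C1", "C", Cc),
               .lig_row("O2", "O", O2))
  for (k in seq_len(nrow(tail)))
    rows[[length(rows) + 1L]] <- .lig_row(paste0("C", k + 1), "C", tail[k, ])
  do.call(rbind, rows)
}

.fx_clash <- function(pep, P, centroid, d) {
  O <- P(1, "O"); C <- P(1, "C")
  u <- .unit(O - C)
  head <- O + d * u
  fr <- .tail_frame(u)
  tail <- .jitter(.zigzag(head, fr$u, fr$v, 10))
  rows <- list(.lig_row("C1", "C", head))
  for (k in seq_len(nrow(tail)))
    rows[[length(rows) + 1L]] <- .lig_row(paste0("C", k + 1), "C", tail[k, ])
  do.call(rbind, rows)
}

.fx_covalent <- function(pep, P, centroid, d) {
  OG <- P(3, "OG"); CB <- P(3, "CB")
  u <- .unit(OG - CB)
  head <- OG + d * u
  fr <- .tail_frame(u)
  tail <- .jitter(.zigzag(head, fr$u, fr$v, 10))
  rows <- list(.lig_row("C1", "C", head))
  for (k in seq_len(nrow(tail)))
    rows[[length(rows) + 1L]] <- .lig_row(paste0("C", k + 1), "C", tail[k, ])
  do.call(rbind, rows)
}

# alkane or PEG oligomer at a fixed minimum gap beyond the protein's maximum
# x coordinate; the chain runs along y with its zigzag in the y-z plane, so
# every ligand atom keeps an x separation of at least `gap`.
.fx_offset_chain <- function(pep, gap, peg = FALSE) {
  xmax <- max(pep$x)
  y0 <- mean(range(pep$y)); z0 <- mean(range(pep$z))
  n <- if (peg) 15L else 11L
  u <- c(0, 1, 0); v <- c(0, 0, 1)
  start <- c(xmax + gap, y0 - 0.634 * n / 2, z0)
  pos <- .zigzag(start, u, v, n, bond = if (peg) 1.47 else 1.53)
  pos <- .jitter(pos, sd = 0.005)
  pos[, 1] <- pmax(pos[, 1], xmax + gap)  # never dip inside the gap
  rows <- list()
  for (k in seq_len(n)) {
    el <- if (peg && k %% 3 == 0L) "O" else "C"
    rows[[length(rows) + 1L]] <- .lig_row(paste0(el, k), el, pos[k, ])
  }
  do.call(rbind, rows)
}

# push tail atoms along `u` until none is closer than min_gap to the protein
.push_out <- function(tail, pep, u, min_gap = 3.3) {
  PM <- as.matrix(pep[, c("x", "y", "z")])
  for (t in 1:50) {
    d2 <- .cross_dist2(tail, PM)
    if (sqrt(min(d2)) >= min_gap) break
    tail <- sweep(tail, 2, 0.1 * u, "+")
  }
  tail
}
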