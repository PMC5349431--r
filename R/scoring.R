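# Pairwise protein-ligand energy evaluation, per-atom normalization,
# classification and reporting.

#' Evaluate all protein-ligand pair energies
#'
#' Enumerates every protein-ligand atom pair closer than the nonbonded
#' cutoff and evaluates the four terms.  Donor-hydrogen/acceptor pairs are
#' scored with the directional 10-12 hydrogen-bond well in place of (not in
#' addition to) the 6-12 term; electrostatics and desolvation contribute for
#' every pair.  A pair is flagged as a clash when its distance is below
#' \code{clash_scale} times the pair equilibrium distance, and as a hydrogen
#' bond when the 10-12 term is negative with valid geometry.
#'
#' @param protein Typed protein atoms (\code{\link{assign_atom_types}}
#'   output); waters and ions must already be excluded.
#' @param ligand Typed ligand atoms, polar hydrogens included.
#' @param p A \code{lig_forcefield}.
#' @return Data frame with one row per in-range pair: atom labels, distance,
#'   \code{e_vdw}, \code{e_hbond}, \code{e_elec}, \code{e_desolv},
#'   \code{e_total}, \code{is_clash}, \code{is_hbond}.
#' @export
pairwise_interactions <- function(protein, ligand, p) {
  need <- c("ff_type", "charge", "x", "y", "z")
  if (!all(need %in% names(protein)) || !all(need %in% names(ligand)))
    stop("atoms must be typed and charged (see assign_atom_types)")
  if (any(is.na(protein$ff_type)) || any(is.na(ligand$ff_type)))
    stop("untyped atom encountered")

  PT <- as.matrix(protein[, c("x", "y", "z")])
  LT <- as.matrix(ligand[, c("x", "y", "z")])
  d2 <- .cross_dist2(PT, LT)
  hit <- which(d2 < p$cutoff^2, arr.ind = TRUE)
  empty <- data.frame(
    p_idx = integer(), l_idx = integer(), p_name = character(),
    p_resname = character(), p_chain = character(), p_resseq = integer(),
    l_name = character(), distance = numeric(), e_vdw = numeric(),
    e_hbond = numeric(), e_elec = numeric(), e_desolv = numeric(),
    e_total = numeric(), is_clash = logical(), is_hbond = logical(),
    stringsAsFactors = FALSE)
  if (!nrow(hit)) return(empty)

  pi_ <- hit[, 1]; li_ <- hit[, 2]
  r <- sqrt(d2[hit])
  if (any(r < 1e-6)) stop("coincident protein and ligand atoms")

  tt <- p$types
  tp <- protein$ff_type[pi_]; tl <- ligand$ff_type[li_]
  rp <- tt[tp, ]; rl <- tt[tl, ]
  r_eq <- rp$rii / 2 + rl$rii / 2
  eps <- sqrt(rp$eps * rl$eps)

  # hydrogen-bond-capable pairs: polar H vs acceptor
  hb_pl <- tp == "HD" & tl %in% c("NA", "OA", "SA")
  hb_lp <- tl == "HD" & tp %in% c("NA", "OA", "SA")
  is_hb_pair <- hb_pl | hb_lp

  W <- p$weights
  e_vdw <- W[["vdw"]] * (eps * r_eq^12 / r^12 - 2 * eps * r_eq^6 / r^6)
  e_vdw[is_hb_pair] <- 0

  e_hbond <- numeric(length(r))
  if (any(is_hb_pair)) {
    idx <- which(is_hb_pair)
    acc <- ifelse(hb_pl[idx], tl[idx], tp[idx])
    r0 <- tt[acc, "rii_hb"]; eh <- tt[acc, "eps_hb"]
    # deviation from ideal donor-H...acceptor alignment
    hpx <- ifelse(hb_pl[idx], protein$dx[pi_[idx]], ligand$dx[li_[idx]])
    hpy <- ifelse(hb_pl[idx], protein$dy[pi_[idx]], ligand$dy[li_[idx]])
    hpz <- ifelse(hb_pl[idx], protein$dz[pi_[idx]], ligand$dz[li_[idx]])
    hx <- ifelse(hb_pl[idx], protein$x[pi_[idx]], ligand$x[li_[idx]])
    hy <- ifelse(hb_pl[idx], protein$y[pi_[idx]], ligand$y[li_[idx]])
    hz <- ifelse(hb_pl[idx], protein$z[pi_[idx]], ligand$z[li_[idx]])
    ax <- ifelse(hb_pl[idx], ligand$x[li_[idx]], protein$x[pi_[idx]])
    ay <- ifelse(hb_pl[idx], ligand$y[li_[idx]], protein$y[pi_[idx]])
    az <- ifelse(hb_pl[idx], ligand$z[li_[idx]], protein$z[pi_[idx]])
    t_dev <- numeric(length(idx))
    for (t in seq_along(idx)) {
      if (is.na(hpx[t])) { t_dev[t] <- 0; next }
      ang <- .angle_deg(c(hpx[t], hpy[t], hpz[t]), c(hx[t], hy[t], hz[t]),
                        c(ax[t], ay[t], az[t]))
      t_dev[t] <- 180 - ang
    }
    Et <- ifelse(t_dev < 90, cos(t_dev * pi / 180)^2, 0)
    e_hbond[idx] <- Et * W[["hbond"]] *
      (5 * eh * r0^12 / r[idx]^12 - 6 * eh * r0^10 / r[idx]^10)
  }

  e_elec <- W[["elec"]] * .COULOMB_K *
    protein$charge[pi_] * ligand$charge[li_] / (dielectric(r, p) * r)
  e_desolv <- W[["sol"]] *
    (rp$solpar * rl$vol + rl$solpar * rp$vol) * exp(-r^2 / (2 * p$sigma^2))

  out <- data.frame(
    p_idx = pi_, l_idx = li_,
    p_name = protein$name[pi_], p_resname = protein$resname[pi_],
    p_chain = protein$chain[pi_], p_resseq = protein$resseq[pi_],
    l_name = ligand$name[li_],
    distance = r,
    e_vdw = e_vdw, e_hbond = e_hbond, e_elec = e_elec, e_desolv = e_desolv,
    e_total = e_vdw + e_hbond + e_elec + e_desolv,
    is_clash = r < p$clash_scale * r_eq,
    is_hbond = is_hb_pair & e_hbond < 0,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$p_idx, out$l_idx), , drop = FALSE]
}

#' Sum pair energies into a bound-state energy report
#'
#' The total bound-state interaction energy is the sum over all in-range
#' protein-ligand pairs; dividing by the number of non-hydrogen ligand atoms
#' gives the normalized energy (kcal/mol per atom), the per-atom ligand
#' efficiency analogue used for classification.  A complex with no in-range
#' pairs has energy exactly 0.
#'
#' @param pairs Pair table from \code{\link{pairwise_interactions}}.
#' @param n_heavy Number of non-hydrogen ligand atoms (>= 1).
#' @return An object of class \code{lig_energy_report}: \code{e_total},
#'   \code{n_heavy}, \code{e_normalized}, \code{term_sums}, \code{pairs},
#'   \code{category}, \code{clashes}, \code{covalent_warnings}.
#' @export
bound_state_energy <- function(pairs, n_heavy) {
  if (n_heavy < 1) stop("n_heavy must be >= 1")
  e_total <- sum(pairs$e_total)
  term_sums <- c(vdw = sum(pairs$e_vdw), hbond = sum(pairs$e_hbond),
                 elec = sum(pairs$e_elec), desolv = sum(pairs$e_desolv))
  e_norm <- e_total / n_heavy
  rep <- structure(list(
    e_total = e_total, n_heavy = as.integer(n_heavy),
    e_normalized = e_norm, term_sums = term_sums, pairs = pairs,
    category = NA_character_,
    clashes = pairs[pairs$is_clash, , drop = FALSE],
    covalent_warnings = pairs[0, , drop = FALSE]
  ), class = "lig_energy_report")
  rep$category <- classify_complex(rep)
  rep
}

#' Classify a complex from its normalized energy
#'
#' Positive normalized energies indicate interatomic clashes
#' (\code{"clash_positive"}); values in (-0.1, 0] kcal/mol per atom indicate
#' very weak or nonspecific surface contacts (\code{"weak_nonspecific"},
#' typical of crystallization additives); values at or below -0.1 indicate
#' an unproblematic protein-ligand interface (\code{"unproblematic"}).
#'
#' @param r A \code{lig_energy_report} or a numeric normalized energy.
#' @return One of \code{"clash_positive"}, \code{"weak_nonspecific"},
#'   \code{"unproblematic"}.
#' @export
classify_complex <- function(r) {
  e <- if (inherits(r, "lig_energy_report")) r$e_normalized else as.numeric(r)
  if (e > 0) "clash_positive"
  else if (e > -0.1) "weak_nonspecific"
  else "unproblematic"
}

#' Clash and contact listing
#'
#' @param r A \code{lig_energy_report}.
#' @param top_n Number of most favourable contacts to list (default 10).
#' @return A \code{lig_contact_report} list: \code{clashes} (all flagged
#'   clash pairs with atom names, residues and distances), \code{top_contacts}
#'   (the \code{top_n} lowest-energy pairs) and \code{covalent_suspects}.
#' @export
clash_and_contact_report <- function(r, top_n = 10L) {
  stopifnot(inherits(r, "lig_energy_report"))
  pr <- r$pairs
  fav <- pr[order(pr$e_total), , drop = FALSE]
  fav <- utils::head(fav[fav$e_total < 0, , drop = FALSE], top_n)
  structure(list(clashes = r$clashes, top_contacts = fav,
                 covalent_suspects = r$covalent_warnings),
            class = "lig_contact_report")
}

#' @export
print.lig_contact_report <- function(x, ...) {
  fmt <- function(df) {
    if (!nrow(df)) { cat("  (none)\n"); return(invisible()) }
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %s %s%d %s -- ligand %s : %.2f A, %+.3f kcal/mol\n",
                  df$p_resname[i], df$p_chain[i], df$p_resseq[i],
                  df$p_name[i], df$l_name[i], df$distance[i], df$e_total[i]))
  }
  cat("Clashes:\n"); fmt(x$clashes)
  cat("Most favourable contacts:\n"); fmt(x$top_contacts)
  if (nrow(x$covalent_suspects)) {
    cat("Suspected covalent pairs (scored, but check annotations):\n")
    fmt(x$covalent_suspects)
  }
  invisible(x)
}

#' @export
print.lig_energy_report <- function(x, ...) {
  cat(sprintf("bound-state energy: %.3f kcal/mol over %d heavy atoms\n",
              x$e_total, x$n_heavy))
  cat(sprintf("normalized energy:  %.3f kcal/mol per atom  [%s]\n",
              x$e_normalized, x$category))
  cat(sprintf("terms: vdw %+.3f  hbond %+.3f  elec %+.3f  desolv %+.3f\n",
              x$term_sums["vdw"], x$term_sums["hbond"],
              x$term_sums["elec"], x$term_sums["desolv"]))
  cat(sprintf("%d pair(s) in range, %d clash(es), %d covalent suspect(s)\n",
              nrow(x$pairs), nrow(x$clashes), nrow(x$covalent_warnings)))
  invisible(x)
}

#' Score a protein-ligand complex end to end
#'
#' Full pipeline: collapse alternate locations, select (or look up) the
#' ligand, build covalent connectivity for protein and ligand, place polar
#' hydrogens at riding positions, compute PEOE partial charges, assign
#' AD4-style atom types, evaluate all pairwise terms and return the
#' normalized-energy report.  Waters and monoatomic ions are excluded from
#' the protein environment; protein-ligand heavy-atom contacts below
#' \code{max_bond} are scored but reported as covalent suspects.
#'
#' @param s A \code{lig_structure}.
#' @param ligand \code{NULL} (select the primary ligand), a
#'   \code{lig_ligand}, or a \code{"CODE:CHAIN:SEQ"} string.
#' @param rscc Optional externally computed RSCC for the ligand.
#' @param p A \code{lig_forcefield}.
#' @param template_dir Optional component-dictionary directory for ligand
#'   bond orders.
#' @param max_bond Covalent-suspect distance threshold (Angstrom).
#' @param min_heavy,max_heavy Ligand size bounds used when \code{ligand} is
#'   \code{NULL}.
#' @return A \code{lig_energy_report} with additional elements \code{ligand}
#'   (the \code{lig_ligand} scored), \code{quality}
#'   (\code{\link{ligand_quality_stats}}) and \code{verdict}
#'   (\code{\link{apply_entry_filters}}).
#' @examples
#' s <- make_fixture("salt_bridge")
#' rep <- score_complex(s)
#' rep$category
#' @export
score_complex <- function(s, ligand = NULL, rscc = NULL,
                          p = load_forcefield(), template_dir = NULL,
                          max_bond = 1.7, min_heavy = 10L, max_heavy = 50L) {
  stopifnot(inherits(s, "lig_structure"))
  s <- collapse_altlocs(s)
  if (is.null(ligand)) {
    lig <- select_primary_ligand(s, min_heavy, max_heavy, max_bond)
    if (is.null(lig)) stop("no qualifying ligand found in ", s$entry_id)
  } else if (is.character(ligand)) {
    lig <- .ligand_by_spec(s, ligand)
  } else {
    stopifnot(inherits(ligand, "lig_ligand"))
    lig <- ligand
  }

  pg <- protein_connectivity(s)
  pg <- place_polar_hydrogens(pg)
  pq <- compute_peoe_charges(pg)
  prot <- assign_atom_types(pg, pq)

  lg <- infer_ligand_bonds(lig, template_dir = template_dir)
  lg <- place_polar_hydrogens(lg)
  lq <- compute_peoe_charges(lg)
  ligt <- assign_atom_types(lg, lq)

  pairs <- pairwise_interactions(prot, ligt, p)
  rep <- bound_state_energy(pairs, lig$n_heavy)
  heavy_pair <- !(prot$ff_type[rep$pairs$p_idx] == "HD" |
                    ligt$ff_type[rep$pairs$l_idx] == "HD")
  rep$covalent_warnings <-
    rep$pairs[heavy_pair & rep$pairs$distance < max_bond, , drop = FALSE]
  rep$ligand <- lig
  rep$quality <- ligand_quality_stats(lig, rscc)
  rep$verdict <- apply_entry_filters(rep$quality)
  rep
}

.ligand_by_spec <- function(s, spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("ligand spec must be 'CODE:CHAIN:SEQ', got '", spec, "'")
  a <- s$atoms
  rows <- which(!a$is_polymer & a$resname == parts[1] &
                  a$chain == parts[2] & a$resseq == as.integer(parts[3]))
  if (!length(rows)) stop("ligand not found: ", spec)
  .ligand_from_rows(s, rows)
}
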