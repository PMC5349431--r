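#' Read a macromolecular model from PDB or mmCIF
#'
#' Parses all ATOM/HETATM records of a coordinate file into a
#' \code{lig_structure} object: a flat atom table plus the covalent link
#' annotations (PDB \code{LINK} records or mmCIF \code{_struct_conn} rows)
#' needed to decide whether a ligand is covalently bound.  Alternate-location
#' indicators are preserved; use \code{\link{collapse_altlocs}} to reduce the
#' model to a single conformer before scoring.
#'
#' @param path Path to a coordinate file.
#' @param dialect One of \code{"auto"}, \code{"pdb"}, \code{"mmcif"}.  With
#'   \code{"auto"} the dialect is taken from the file extension
#'   (\code{.cif}/\code{.mmcif} are mmCIF, everything else PDB).
#' @return An object of class \code{lig_structure}: a list with elements
#'   \code{atoms} (data frame with one row per atom: \code{serial},
#'   \code{name}, \code{element}, \code{x}, \code{y}, \code{z}, \code{occ},
#'   \code{b}, \code{altloc}, \code{resname}, \code{resseq}, \code{inscode},
#'   \code{chain}, \code{is_polymer}, \code{is_water}), \code{entry_id} and
#'   \code{links} (data frame of annotated covalent links).
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' write_structure(make_fixture("hbond_pair"), f)
#' s <- parse_structure(f)
#' nrow(s$atoms)
#' @export
parse_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (dialect == "pdb") {
    pdb <- tryCatch(
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
      error = function(e) stop("PDB parse error in '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  } else {
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)),
      error = function(e) stop("mmCIF parse error in '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model in '", path, "'")

  el <- normalize_element(a$elesy)
  missing_el <- is.na(el) | el == ""
  if (any(missing_el)) el[missing_el] <- element_from_name(a$elety[missing_el])

  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    element = el,
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    resname = trimws(a$resid),
    resseq = as.integer(a$resno),
    inscode = ifelse(is.na(a$insert) | a$insert == "", "", a$insert),
    chain = ifelse(is.na(a$chain), "", a$chain),
    stringsAsFactors = FALSE
  )
  atoms$is_water <- atoms$resname %in% .WATER_CODES
  atoms$is_polymer <- a$type == "ATOM" & !atoms$is_water
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in '", path, "'")

  lines <- readLines(path, warn = FALSE)
  if (dialect == "pdb") {
    entry_id <- .pdb_entry_id(lines, path)
    links <- .parse_pdb_links(lines)
  } else {
    entry_id <- .cif_entry_id(lines, path)
    links <- .parse_cif_struct_conn(lines)
  }

  structure(list(atoms = atoms, entry_id = entry_id, links = links),
            class = "lig_structure")
}

.empty_links <- function() {
  data.frame(name1 = character(), resname1 = character(), chain1 = character(),
             resseq1 = integer(), name2 = character(), resname2 = character(),
             chain2 = character(), resseq2 = integer(),
             stringsAsFactors = FALSE)
}

.pdb_entry_id <- function(lines, path) {
  h <- lines[startsWith(lines, "HEADER")]
  if (length(h) >= 1L && nchar(h[1]) >= 66) {
    id <- trimws(substr(h[1], 63, 66))
    if (nzchar(id)) return(tolower(id))
  }
  sub("\\.[^.]*$", "", basename(path))
}

.parse_pdb_links <- function(lines) {
  ln <- lines[startsWith(lines, "LINK")]
  if (length(ln) == 0L) return(.empty_links())
  ln <- formatC(ln, width = 80, flag = "-")
  data.frame(
    name1 = trimws(substr(ln, 13, 16)),
    resname1 = trimws(substr(ln, 18, 20)),
    chain1 = trimws(substr(ln, 22, 22)),
    resseq1 = suppressWarnings(as.integer(substr(ln, 23, 26))),
    name2 = trimws(substr(ln, 43, 46)),
    resname2 = trimws(substr(ln, 48, 50)),
    chain2 = trimws(substr(ln, 52, 52)),
    resseq2 = suppressWarnings(as.integer(substr(ln, 53, 56))),
    stringsAsFactors = FALSE
  )
}

.cif_entry_id <- function(lines, path) {
  m <- grep("^_entry\\.id", lines, value = TRUE)
  if (length(m) >= 1L) {
    id <- trimws(sub("^_entry\\.id", "", m[1]))
    id <- gsub("['\"]", "", id)
    if (nzchar(id)) return(tolower(id))
  }
  # data_XXXX block header
  m <- grep("^data_", lines, value = TRUE)
  if (length(m) >= 1L) {
    id <- sub("^data_", "", m[1])
    if (nzchar(id)) return(tolower(id))
  }
  sub("\\.[^.]*$", "", basename(path))
}

# Minimal mmCIF loop extraction for the _struct_conn category: enough for
# files in the wild whose struct_conn rows are whitespace-delimited one-liners.
.parse_cif_struct_conn <- function(lines) {
  idx <- grep("^\\s*loop_\\s*$", lines)
  for (i in idx) {
    j <- i + 1L
    keys <- character()
    while (j <= length(lines) && grepl("^_", trimws(lines[j]))) {
      keys <- c(keys, trimws(lines[j])); j <- j + 1L
    }
    if (!length(keys) || !all(startsWith(keys, "_struct_conn."))) next
    keys <- sub("^_struct_conn\\.", "", keys)
    rows <- list()
    while (j <= length(lines)) {
      tl <- trimws(lines[j])
      if (tl == "" || startsWith(tl, "_") || startsWith(tl, "loop_") ||
          startsWith(tl, "#") || startsWith(tl, "data_")) break
      tok <- scan(text = tl, what = character(), quiet = TRUE)
      if (length(tok) == length(keys)) rows[[length(rows) + 1L]] <- tok
      j <- j + 1L
    }
    if (!length(rows)) return(.empty_links())
    m <- do.call(rbind, rows)
    colnames(m) <- keys
    getcol <- function(nm) if (nm %in% keys) m[, nm] else rep(NA, nrow(m))
    type <- getcol("conn_type_id")
    keep <- is.na(type) | tolower(type) %in% c("covale", "covale_base",
                                               "covale_phosphate", "disulf")
    if (!any(keep)) return(.empty_links())
    m <- m[keep, , drop = FALSE]
    return(data.frame(
      name1 = getcol("ptnr1_label_atom_id")[keep],
      resname1 = getcol("ptnr1_label_comp_id")[keep],
      chain1 = getcol("ptnr1_auth_asym_id")[keep],
      resseq1 = suppressWarnings(as.integer(getcol("ptnr1_auth_seq_id")[keep])),
      name2 = getcol("ptnr2_label_atom_id")[keep],
      resname2 = getcol("ptnr2_label_comp_id")[keep],
      chain2 = getcol("ptnr2_auth_asym_id")[keep],
      resseq2 = suppressWarnings(as.integer(getcol("ptnr2_auth_seq_id")[keep])),
      stringsAsFactors = FALSE))
  }
  .empty_links()
}

#' Write a structure to a PDB file
#'
#' @param s A \code{lig_structure}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "lig_structure"))
  a <- s$atoms
  hdr <- sprintf("HEADER    %-40s%9s   %s", "SYNTHETIC COMPLEX", "",
                 toupper(substr(s$entry_id, 1, 4)))
  writeLines(hdr, path)
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$is_polymer, "ATOM", "HETATM"),
    resno = a$resseq, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = a$chain,
    insert = ifelse(a$inscode == "", NA, a$inscode),
    alt = ifelse(a$altloc == "", NA, a$altloc),
    o = a$occ, b = a$b, elesy = a$element,
    append = TRUE, end = TRUE, verbose = FALSE)
  invisible(path)
}

#' Reduce alternate locations to a single conformer
#'
#' For every atom with alternate-location records, keeps the location with
#' the highest occupancy (ties broken in favour of altloc \code{"A"}, then
#' file order), matching the convention of scoring one conformer of a fully
#' occupied model.
#'
#' @param s A \code{lig_structure}.
#' @return A \code{lig_structure} with at most one record per atom site.
#' @export
collapse_altlocs <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resseq, a$inscode, a$resname, a$name, sep = "|")
  if (!anyDuplicated(key)) return(s)
  ord <- order(-a$occ, a$altloc != "A" & a$altloc != "", seq_len(nrow(a)))
  keep <- ord[!duplicated(key[ord])]
  s$atoms <- a[sort(keep), , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

# First chain (in file order) containing standard amino-acid residues.
first_protein_chain <- function(s) {
  a <- s$atoms
  prot <- a$is_polymer & a$resname %in% .STD_AA
  if (!any(prot)) return(NA_character_)
  a$chain[which(prot)[1]]
}

# All non-water, non-polymer, non-monoatomic-ion residues as candidate
# ligands, in file order.
.ligand_candidates <- function(s) {
  a <- s$atoms
  het <- !a$is_polymer & !a$is_water & !(a$resname %in% .ION_CODES)
  if (!any(het)) return(list())
  idx <- which(het)
  key <- paste(a$chain[idx], a$resseq[idx], a$inscode[idx], a$resname[idx],
               sep = "|")
  split(idx, factor(key, levels = unique(key)))
}

.ligand_from_rows <- function(s, rows) {
  a <- s$atoms[rows, , drop = FALSE]
  heavy <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  structure(list(
    het_code = heavy$resname[1],
    chain_id = heavy$chain[1],
    resseq = heavy$resseq[1],
    inscode = heavy$inscode[1],
    atoms = heavy,
    n_heavy = nrow(heavy)
  ), class = "lig_ligand")
}

#' Select the primary ligand of a structure
#'
#' Chooses the largest noncovalently bound non-water ligand with a heavy-atom
#' count inside \code{[min_heavy, max_heavy]}.  Covalency is decided from the
#' file's annotated links plus a distance heuristic
#' (\code{\link{detect_covalent_links}}).  When several copies of the winning
#' ligand are present (e.g. in homo-multimers), the copy associated with the
#' first protein chain is returned; remaining ties are broken by file order.
#'
#' @param s A \code{lig_structure} (altlocs are collapsed internally).
#' @param min_heavy,max_heavy Inclusive bounds on the number of non-hydrogen
#'   ligand atoms (defaults 10 and 50).
#' @param max_bond Distance (Angstrom) below which a protein/ligand heavy-atom
#'   pair is treated as covalent (default 1.7).
#' @return A \code{lig_ligand} object, or \code{NULL} when no residue
#'   qualifies.
#' @export
select_primary_ligand <- function(s, min_heavy = 10L, max_heavy = 50L,
                                  max_bond = 1.7) {
  s <- collapse_altlocs(s)
  cands <- .ligand_candidates(s)
  if (!length(cands)) return(NULL)
  ligs <- lapply(cands, function(rows) .ligand_from_rows(s, rows))
  n <- vapply(ligs, function(l) l$n_heavy, integer(1))
  ok <- n >= min_heavy & n <= max_heavy & n > 1L
  ligs <- ligs[ok]
  if (!length(ligs)) return(NULL)
  ligs <- Filter(function(l) nrow(detect_covalent_links(s, l, max_bond)) == 0L,
                 ligs)
  if (!length(ligs)) return(NULL)
  n <- vapply(ligs, function(l) l$n_heavy, integer(1))
  nmax <- max(n)
  best <- ligs[n == nmax]
  if (length(best) > 1L) {
    fc <- first_protein_chain(s)
    codes <- vapply(best, function(l) l$het_code, character(1))
    # among copies of the top het code, prefer the first-protein-chain copy
    top_code <- codes[1]
    same <- best[codes == top_code]
    on_fc <- vapply(same, function(l) identical(l$chain_id, fc), logical(1))
    if (!is.na(fc) && any(on_fc)) return(same[[which(on_fc)[1]]])
    return(same[[1]])
  }
  best[[1]]
}

#' Detect covalent protein-ligand links
#'
#' Flags every protein-heavy-atom/ligand-heavy-atom pair closer than
#' \code{max_bond}, plus any pair named in the file's link annotations
#' regardless of distance.  Unannotated covalency in deposited models shows
#' up as interatomic contacts in the 1.3-1.6 Angstrom range, far below any
#' nonbonded equilibrium separation.
#'
#' @param s A \code{lig_structure}.
#' @param lig A \code{lig_ligand}.
#' @param max_bond Distance threshold in Angstrom (default 1.7).
#' @return Data frame with one row per suspected covalent pair:
#'   protein atom descriptors, ligand atom descriptors, \code{dist} and
#'   \code{source} (\code{"distance"} or \code{"annotated"}).
#' @export
detect_covalent_links <- function(s, lig, max_bond = 1.7) {
  a <- s$atoms
  prot <- a[a$is_polymer & !(a$element %in% c("H", "D")), , drop = FALSE]
  lg <- lig$atoms
  out <- data.frame(p_name = character(), p_resname = character(),
                    p_chain = character(), p_resseq = integer(),
                    l_name = character(), dist = numeric(),
                    source = character(), stringsAsFactors = FALSE)
  if (nrow(prot) && nrow(lg)) {
    d2 <- .cross_dist2(as.matrix(prot[, c("x", "y", "z")]),
                       as.matrix(lg[, c("x", "y", "z")]))
    hit <- which(d2 < max_bond^2, arr.ind = TRUE)
    if (nrow(hit)) {
      out <- data.frame(
        p_name = prot$name[hit[, 1]], p_resname = prot$resname[hit[, 1]],
        p_chain = prot$chain[hit[, 1]], p_resseq = prot$resseq[hit[, 1]],
        l_name = lg$name[hit[, 2]], dist = sqrt(d2[hit]),
        source = "distance", stringsAsFactors = FALSE)
    }
  }
  lk <- s$links
  if (!is.null(lk) && nrow(lk)) {
    for (i in seq_len(nrow(lk))) {
      sides <- list(c("1", "2"), c("2", "1"))
      for (sd in sides) {
        lig_side <- lk[[paste0("resname", sd[1])]][i] == lig$het_code &
          lk[[paste0("resseq", sd[1])]][i] == lig$resseq &
          (lk[[paste0("chain", sd[1])]][i] == lig$chain_id |
             lk[[paste0("chain", sd[1])]][i] == "")
        if (isTRUE(lig_side)) {
          pi_ <- which(prot$name == lk[[paste0("name", sd[2])]][i] &
                         prot$resname == lk[[paste0("resname", sd[2])]][i] &
                         prot$resseq == lk[[paste0("resseq", sd[2])]][i])
          li_ <- which(lg$name == lk[[paste0("name", sd[1])]][i])
          if (length(pi_) && length(li_)) {
            pi_ <- pi_[1]; li_ <- li_[1]
            d <- sqrt(sum((unlist(prot[pi_, c("x", "y", "z")]) -
                             unlist(lg[li_, c("x", "y", "z")]))^2))
            dup <- out$p_name == prot$name[pi_] &
              out$p_resseq == prot$resseq[pi_] & out$l_name == lg$name[li_]
            if (!any(dup)) {
              out <- rbind(out, data.frame(
                p_name = prot$name[pi_], p_resname = prot$resname[pi_],
                p_chain = prot$chain[pi_], p_resseq = prot$resseq[pi_],
                l_name = lg$name[li_], dist = d, source = "annotated",
                stringsAsFactors = FALSE))
            }
          }
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-ligand quality statistics
#'
#' @param lig A \code{lig_ligand}.
#' @param rscc Optional externally computed real-space correlation
#'   coefficient for the ligand (scalar in [-1, 1]).
#' @return A \code{lig_quality} list: \code{mean_adp}, \code{min_occupancy},
#'   \code{n_heavy}, \code{rscc}.
#' @export
ligand_quality_stats <- function(lig, rscc = NULL) {
  stopifnot(inherits(lig, "lig_ligand"), lig$n_heavy >= 1L)
  if (!is.null(rscc)) stopifnot(is.numeric(rscc), rscc >= -1, rscc <= 1)
  structure(list(
    mean_adp = mean(lig$atoms$b),
    min_occupancy = min(lig$atoms$occ),
    n_heavy = lig$n_heavy,
    rscc = rscc
  ), class = "lig_quality")
}

#' Entry-quality filters for a modelled ligand
#'
#' A ligand entry is accepted when it is fully occupied, its mean atomic
#' displacement parameter is below \code{adp_max}, and (when an RSCC value is
#' supplied) the RSCC exceeds \code{rscc_min}.
#'
#' @param q A \code{lig_quality} object.
#' @param adp_max Mean-ADP ceiling in square Angstrom (default 80).
#' @param rscc_min RSCC floor (default 0.917).
#' @return A \code{lig_verdict} list: \code{accepted} (logical) and
#'   \code{reasons} (character vector of failed criteria, empty when
#'   accepted; labels are \code{"occupancy"}, \code{"ADP"}, \code{"RSCC"}).
#' @export
apply_entry_filters <- function(q, adp_max = 80, rscc_min = 0.917) {
  stopifnot(inherits(q, "lig_quality"))
  reasons <- character()
  if (q$min_occupancy < 1 - 1e-9) reasons <- c(reasons, "occupancy")
  if (!(q$mean_adp < adp_max)) reasons <- c(reasons, "ADP")
  if (!is.null(q$rscc) && !(q$rscc > rscc_min)) reasons <- c(reasons, "RSCC")
  structure(list(accepted = length(reasons) == 0L, reasons = reasons),
            class = "lig_verdict")
}

# Squared distances between two coordinate matrices (n x 3, m x 3) -> n x m.
.cross_dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' @export
print.lig_structure <- function(x, ...) {
  cat("lig_structure", x$entry_id, "-", nrow(x$atoms), "atoms,",
      sum(x$atoms$is_polymer), "polymer,",
      nrow(x$links), "annotated link(s)\n")
  invisible(x)
}

#' @export
print.lig_ligand <- function(x, ...) {
  cat(sprintf("ligand %s %s%d: %d heavy atoms\n", x$het_code, x$chain_id,
              x$resseq, x$n_heavy))
  invisible(x)
}
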