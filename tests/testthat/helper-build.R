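# In-code builders for atoms, graphs, ligands, structures and PDB text.

mk_atoms <- function(name, element, xyz, resname = "LIG", resseq = 1L,
                     chain = "A", occ = 1, b = 20, altloc = "",
                     polymer = FALSE) {
  n <- length(name)
  data.frame(
    serial = seq_len(n), name = name, element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = rep_len(occ, n), b = rep_len(b, n), altloc = rep_len(altloc, n),
    resname = rep_len(resname, n), resseq = rep_len(as.integer(resseq), n),
    inscode = "", chain = rep_len(chain, n),
    is_water = FALSE, is_polymer = rep_len(polymer, n),
    stringsAsFactors = FALSE)
}

mk_graph <- function(atoms, edges = NULL, formal = numeric(nrow(atoms))) {
  if (is.null(edges))
    edges <- data.frame(i = integer(), j = integer(), order = numeric())
  ligenergy:::.new_bondgraph(atoms, edges, formal)
}

mk_ligand <- function(atoms) {
  heavy <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  structure(list(het_code = heavy$resname[1], chain_id = heavy$chain[1],
                 resseq = heavy$resseq[1], inscode = "",
                 atoms = heavy, n_heavy = nrow(heavy)),
            class = "lig_ligand")
}

mk_structure <- function(atoms, links = NULL, entry_id = "test") {
  if (is.null(links)) links <- ligenergy:::.empty_links()
  atoms$serial <- seq_len(nrow(atoms))
  structure(list(atoms = atoms, entry_id = entry_id, links = links),
            class = "lig_structure")
}

# minimal typed-atom rows for direct pairwise tests
mk_typed <- function(name, ff_type, charge, xyz, parent_xyz = NULL,
                     resname = "GLY", resseq = 1L, chain = "A") {
  n <- length(name)
  df <- data.frame(
    name = name, ff_type = ff_type, charge = charge,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    resname = rep_len(resname, n), resseq = rep_len(resseq, n),
    chain = rep_len(chain, n), stringsAsFactors = FALSE)
  if (is.null(parent_xyz)) {
    df$dx <- df$dy <- df$dz <- NA_real_
  } else {
    df$dx <- parent_xyz[, 1]; df$dy <- parent_xyz[, 2]
    df$dz <- parent_xyz[, 3]
  }
  df
}

# hand-formatted PDB records so the parser is tested against known text
pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          occ = 1, b = 20, element = "C", het = FALSE,
                          altloc = " ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          altloc, resname, chain, resseq, x, y, z, occ, b, element)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# the same atoms as a minimal mmCIF atom_site loop
write_cif_text <- function(atoms, path = tempfile(fileext = ".cif"),
                           entry = "test") {
  hdr <- c(paste0("data_", entry),
           paste0("_entry.id ", toupper(entry)),
           "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_entity_id", "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
            if (a$is_polymer) "ATOM" else "HETATM", a$serial, a$element,
            a$name, a$resname, a$chain, a$resseq, a$x, a$y, a$z, a$occ, a$b,
            a$resseq, a$resname, a$chain, a$name)
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# idealized adenine heavy-atom coordinates (MMFF-optimized, synthetic)
adenine_atoms <- function() {
  txt <- "N6 N -1.674 1.968 -0.014
C6 C -1.148 0.684 -0.074
N1 N -1.984 -0.337 -0.375
C2 C -1.475 -1.589 -0.428
N3 N -0.200 -1.986 -0.233
C4 C 0.581 -0.933 0.045
N9 N 1.923 -0.947 0.292
C8 C 2.314 0.346 0.514
N7 N 1.306 1.188 0.424
C5 C 0.210 0.397 0.140"
  m <- read.table(text = txt, stringsAsFactors = FALSE)
  mk_atoms(m$V1, m$V2, as.matrix(m[, 3:5]), resname = "ADE")
}
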