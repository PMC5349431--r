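# Connectivity, polar hydrogens, PEOE charges and atom typing.

test_that("ligand bonds follow the covalent-radius distance rule", {
  a <- mk_atoms(c("C1", "C2"), c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  g <- infer_ligand_bonds(mk_ligand(a))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$order, 1)
  a2 <- mk_atoms(c("C1", "C2"), c("C", "C"), rbind(c(0, 0, 0), c(2.5, 0, 0)))
  expect_equal(nrow(infer_ligand_bonds(mk_ligand(a2))$edges), 0L)
})

test_that("a benzene-geometry ring is perceived as aromatic", {
  th <- seq(0, 300, by = 60) * pi / 180
  xyz <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  g <- infer_ligand_bonds(mk_ligand(mk_atoms(paste0("C", 1:6), rep("C", 6),
                                             xyz, resname = "BNZ")))
  expect_equal(nrow(g$edges), 6L)
  expect_true(all(g$edges$order == 1.5))
  t <- assign_atom_types(place_polar_hydrogens(g))
  expect_true(all(t$ff_type == "A"))
})

test_that("protein templates give peptide bonds, chain breaks and disulfides", {
  pep <- ligenergy:::.build_peptide(c("GLY", "GLY"))
  g <- protein_connectivity(mk_structure(pep))
  ci <- which(g$atoms$resseq == 1 & g$atoms$name == "C")
  ni <- which(g$atoms$resseq == 2 & g$atoms$name == "N")
  has_edge <- function(g, i, j) any((g$edges$i == min(i, j)) &
                                      (g$edges$j == max(i, j)))
  expect_true(has_edge(g, ci, ni))

  # chain break: residue 2 shifted 4 A away -> no peptide edge
  brk <- pep
  brk[brk$resseq == 2, c("x", "y", "z")] <-
    brk[brk$resseq == 2, c("x", "y", "z")] + 4
  gb <- protein_connectivity(mk_structure(brk))
  expect_false(has_edge(gb, ci, ni))

  # disulfide: two Cys SG atoms at 2.05 A
  cys <- function(resseq, chain, x0) {
    xyz <- rbind(c(x0, 0, 0), c(x0 + 1.46, 0, 0), c(x0 + 2.2, 1.2, 0),
                 c(x0 + 3.4, 1.2, 0.3), c(x0 + 1.95, -1.0, 1.0),
                 c(x0 + 2.6, -1.2, 2.36))
    mk_atoms(c("N", "CA", "C", "O", "CB", "SG"),
             c("N", "C", "C", "O", "C", "S"), xyz, resname = "CYS",
             resseq = resseq, chain = chain, polymer = TRUE)
  }
  c1 <- cys(1, "A", 0)
  c2 <- cys(1, "B", 0)
  # place the second SG 2.05 A from the first along z
  sg1 <- unlist(c1[6, c("x", "y", "z")])
  c2[, c("x", "y", "z")] <- c2[, c("x", "y", "z")] +
    matrix(rep(sg1 + c(0, 0, 2.05) - unlist(c2[6, c("x", "y", "z")]),
               each = 6), 6, 3)
  gs <- protein_connectivity(mk_structure(rbind(c1, c2)))
  sgi <- which(gs$atoms$name == "SG")
  expect_true(has_edge(gs, sgi[1], sgi[2]))
  # disulfide sulfurs are typed S (non-acceptor) and get no hydrogen
  ts <- assign_atom_types(place_polar_hydrogens(gs))
  expect_true(all(ts$ff_type[ts$name == "SG"] == "S"))
  expect_false(any(ts$element == "H" & !is.na(ts$parent) &
                     ts$parent %in% sgi))
})

test_that("polar hydrogens ride on donors only, at standard bond lengths", {
  pep <- ligenergy:::.build_peptide(c("ALA", "LYS", "SER", "GLY"))
  g <- place_polar_hydrogens(protein_connectivity(mk_structure(pep)))
  a <- g$atoms
  hs <- which(a$is_h)
  expect_true(length(hs) > 0)
  # every hydrogen parent is N, O or S -- never carbon
  expect_true(all(a$element[a$parent[hs]] %in% c("N", "O", "S")))
  # backbone amide N of residues 2..4: exactly one H each
  for (r in 2:4) {
    ni <- which(a$resseq == r & a$name == "N")
    expect_equal(sum(a$parent[hs] == ni), 1L)
  }
  # protonated N-terminus: three H; Lys NZ: three H; Ser OG: one H at 0.96 A
  expect_equal(sum(a$parent[hs] == which(a$resseq == 1 & a$name == "N")), 3L)
  nz <- which(a$name == "NZ")
  expect_equal(sum(a$parent[hs] == nz), 3L)
  og <- which(a$name == "OG")
  hg <- hs[a$parent[hs] == og]
  expect_equal(length(hg), 1L)
  d <- sqrt(sum((unlist(a[hg, c("x", "y", "z")]) -
                   unlist(a[og, c("x", "y", "z")]))^2))
  expect_equal(d, 0.96, tolerance = 1e-6)
  # N-H bond lengths are 1.0 A
  for (h in hs[a$element[a$parent[hs]] == "N"]) {
    dh <- sqrt(sum((unlist(a[h, c("x", "y", "z")]) -
                      unlist(a[a$parent[h], c("x", "y", "z")]))^2))
    expect_equal(dh, 1.0, tolerance = 1e-6)
  }
  # carbonyl O and deprotonated OXT receive no hydrogen
  expect_false(any(a$name[a$parent[hs]] %in% c("O", "OXT")))
})

test_that("tertiary amines get no hydrogen (proline-type nitrogen)", {
  xyz <- rbind(c(0, 0, 0), c(1.47, 0, 0), c(-0.7, 1.3, 0), c(-0.7, -0.7, 1.1))
  a <- mk_atoms(c("N1", "C1", "C2", "C3"), c("N", "C", "C", "C"), xyz)
  g <- place_polar_hydrogens(infer_ligand_bonds(mk_ligand(a)))
  expect_equal(sum(g$atoms$is_h), 0L)
})

test_that("PEOE conserves charge and respects molecular symmetry", {
  # ethane: neutral, symmetric
  a <- mk_atoms(c("C1", "C2"), c("C", "C"), rbind(c(0, 0, 0), c(1.53, 0, 0)))
  q <- compute_peoe_charges(infer_ligand_bonds(mk_ligand(a)))
  expect_equal(sum(q), 0, tolerance = 1e-9)
  expect_equal(q[1], q[2], tolerance = 1e-12)

  # acetate via the bundled component template: net charge -1
  act <- mk_atoms(c("C", "O", "OXT", "CH3"), c("C", "O", "O", "C"),
                  rbind(c(0, 0, 0), c(0.62, 1.06, 0), c(0.62, -1.09, 0),
                        c(-1.51, 0, 0)), resname = "ACT")
  gact <- infer_ligand_bonds(mk_ligand(act))
  expect_equal(sum(gact$formal), -1)
  qact <- compute_peoe_charges(place_polar_hydrogens(gact))
  expect_equal(sum(qact), -1, tolerance = 1e-6)
  # both carboxylate oxygens negative
  expect_true(all(qact[2:3] < -0.2))
})

test_that("PEOE matches an independent reference implementation", {
  # frozen oracle values from Open Babel's Gasteiger routine on identical
  # connectivity (full-hydrogen molecules; apolar H charges summed into the
  # parent carbon to compare with the united-atom convention used here)
  # methanol C-O
  a <- mk_atoms(c("C1", "O1"), c("C", "O"), rbind(c(0, 0, 0), c(1.43, 0, 0)))
  g <- place_polar_hydrogens(infer_ligand_bonds(mk_ligand(a)))
  q <- setNames(compute_peoe_charges(g), g$atoms$name)
  expect_equal(unname(q["O1"]), -0.3982, tolerance = 0.01)
  expect_equal(unname(q["H1"]), 0.2090, tolerance = 0.01)
  expect_equal(unname(q["C1"]), 0.0330 + 3 * 0.0521, tolerance = 0.01)

  # ethanol C-C-O
  a <- mk_atoms(c("C1", "C2", "O1"), c("C", "C", "O"),
                rbind(c(0, 0, 0), c(1.53, 0, 0), c(2.1, 1.3, 0)))
  g <- place_polar_hydrogens(infer_ligand_bonds(mk_ligand(a)))
  q <- setNames(compute_peoe_charges(g), g$atoms$name)
  expect_equal(unname(q["O1"]), -0.3953, tolerance = 0.01)
  expect_equal(unname(q["H1"]), 0.2094, tolerance = 0.01)
  expect_equal(unname(q["C1"]), -0.0418 + 3 * 0.0252, tolerance = 0.01)
  expect_equal(unname(q["C2"]), 0.0414 + 2 * 0.0554, tolerance = 0.01)

  # methylamine C-N
  a <- mk_atoms(c("C1", "N1"), c("C", "N"), rbind(c(0, 0, 0), c(1.47, 0, 0)))
  g <- place_polar_hydrogens(infer_ligand_bonds(mk_ligand(a)))
  q <- setNames(compute_peoe_charges(g), g$atoms$name)
  expect_equal(unname(q["N1"]), -0.3327, tolerance = 0.01)
  hn <- which(g$atoms$is_h & g$atoms$parent == which(g$atoms$name == "N1"))
  expect_equal(length(hn), 2L)
  expect_equal(unname(mean(q[hn])), 0.1180, tolerance = 0.01)
  expect_equal(unname(q["C1"]), -0.0188 + 3 * 0.0386, tolerance = 0.01)

  # dimethyl sulfide C-S-C
  a <- mk_atoms(c("C1", "S1", "C2"), c("C", "S", "C"),
                rbind(c(0, 0, 0), c(1.81, 0, 0), c(2.4, 1.66, 0)))
  g <- place_polar_hydrogens(infer_ligand_bonds(mk_ligand(a)))
  q <- setNames(compute_peoe_charges(g), g$atoms$name)
  expect_equal(unname(q["S1"]), -0.1675, tolerance = 0.01)
  expect_equal(unname(q["C1"]), -0.0184 + 3 * 0.0340, tolerance = 0.01)

  expect_error(compute_peoe_charges(
    mk_graph(mk_atoms("U1", "U", cbind(0, 0, 0)))), "not supported")
})

test_that("PEOE charges are independent of atom input order", {
  a <- mk_atoms(c("C1", "C2", "O1", "N1"), c("C", "C", "O", "N"),
                rbind(c(0, 0, 0), c(1.53, 0, 0), c(2.1, 1.25, 0),
                      c(-0.7, 1.25, 0.2)))
  g <- place_polar_hydrogens(infer_ligand_bonds(mk_ligand(a)))
  q1 <- setNames(compute_peoe_charges(g), g$atoms$name)
  for (rep in 1:5) {
    perm <- sample(nrow(a))
    ap <- a[perm, ]
    gp <- place_polar_hydrogens(infer_ligand_bonds(mk_ligand(ap)))
    qp <- setNames(compute_peoe_charges(gp), gp$atoms$name)
    expect_equal(qp[names(q1)], q1, tolerance = 1e-9)
  }
})

test_that("atom typing is total, deterministic and chemically sensible", {
  # carbonyl O is an acceptor; methyl C aliphatic
  a <- mk_atoms(c("C1", "C2", "O1"), c("C", "C", "O"),
                rbind(c(0, 0, 0), c(1.51, 0, 0), c(2.13, 1.06, 0)))
  t <- assign_atom_types(place_polar_hydrogens(infer_ligand_bonds(
    mk_ligand(a))))
  expect_equal(t$ff_type[t$name == "O1"], "OA")
  expect_true(t$is_acceptor[t$name == "O1"])
  expect_equal(t$ff_type[t$name == "C1"], "C")

  # adenine via the bundled component dictionary: frozen type multiset
  g <- infer_ligand_bonds(mk_ligand(adenine_atoms()))
  t <- assign_atom_types(place_polar_hydrogens(g))
  expect_equal(unname(c(table(t$ff_type)[c("A", "HD", "N", "NA")])),
               c(5L, 3L, 2L, 3L))
  # ring acceptors are N1, N3, N7; donors via H on N9 and the exocyclic N6
  expect_setequal(t$name[t$ff_type == "NA"], c("N1", "N3", "N7"))
  expect_setequal(t$name[t$ff_type == "N"], c("N9", "N6"))
  # repeat run is identical
  t2 <- assign_atom_types(place_polar_hydrogens(
    infer_ligand_bonds(mk_ligand(adenine_atoms()))))
  expect_identical(t$ff_type, t2$ff_type)
})
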