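---
title: "Scoring protein-ligand complexes by their bound-state interaction energy"
author: "ligenergy authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein-ligand complexes by their bound-state interaction energy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligenergy)
```

## The problem

Crystallographic ligand building and validation are dominated by one
question: does the modelled small molecule fit the electron density?  Density
fit alone, however, says nothing about whether the modelled *binding mode* is
physically plausible.  A ligand can correlate well with density while sitting
on top of a protein atom, or while making no interaction with the protein at
all (typical of buffer and cryoprotectant molecules bound at the surface).
`ligenergy` scores the complex itself: it estimates the interaction energy of
the protein-ligand pair **in the deposited (or candidate) bound state** and
normalizes it per non-hydrogen ligand atom.  The result is a one-number
physical sanity check that complements a density-fit statistic such as the
real-space correlation coefficient (RSCC).

This is *not* a free energy of binding: no unbound reference state, no
torsional entropy, no sampling.  Only the bound-state pairwise energy is
evaluated, which is exactly what is needed to ask "is this pose feasible?"

## The energy model

For every protein atom $i$ and ligand atom $j$ closer than a cutoff
(8 &Aring; by default) the model sums four semi-empirical terms of the
AutoDock 4 family:

$$
E = W_{vdw}\sum_{i,j}\left(\frac{A_{ij}}{r_{ij}^{12}}-\frac{B_{ij}}{r_{ij}^{6}}\right)
  + W_{hb}\sum_{i,j}E(t)\left(\frac{C_{ij}}{r_{ij}^{12}}-\frac{D_{ij}}{r_{ij}^{10}}\right)
  + W_{elec}\sum_{i,j}\frac{q_i q_j}{\epsilon(r_{ij})\,r_{ij}}
  + W_{sol}\sum_{i,j}\left(S_iV_j+S_jV_i\right)e^{-r_{ij}^2/2\sigma^2}
$$

* **6-12 dispersion/repulsion.** $A_{ij}$ and $B_{ij}$ come from the
  AMBER-derived per-type radii and well depths of the published AutoDock 4
  parameter set, combined by $r_{eq,ij} = R_{ii}/2 + R_{jj}/2$ and
  $\epsilon_{ij} = \sqrt{\epsilon_i\epsilon_j}$, so the minimum of depth
  $-W_{vdw}\epsilon_{ij}$ sits exactly at $r_{eq,ij}$.
* **10-12 hydrogen bonding.** Donor-hydrogen/acceptor pairs are scored with
  a deeper, shorter-ranged 10-12 well *in place of* the 6-12 term, measured
  from the polar hydrogen to the acceptor heavy atom, with the well
  parameters of the acceptor type (1.9 &Aring;/5.0 kcal mol$^{-1}$ for O and
  N acceptors, 2.5 &Aring;/1.0 for S).  Directionality is
  $E(t)=\cos^2 t$ for deviations $t<90^\circ$ from linear
  donor-H$\cdots$acceptor geometry and zero beyond.  The published
  directionality functions distinguish acceptor hybridizations; the single
  $\cos^2$ form is a deliberate simplification and is an interpretation of
  the source field, not a reproduction of it.
* **Electrostatics.** Coulomb interaction of PEOE partial charges with the
  sigmoidal Mehler-Solmajer distance-dependent dielectric
  ($\epsilon(0)\approx 1.3$, bulk-water 78.4 at long range) and the
  332.06 kcal mol$^{-1}$ e$^{-2}$ &Aring; conversion constant.
* **Desolvation.** A Gaussian-damped pairwise burial term over per-type
  solvation parameters $S$ and fragmental volumes $V$
  ($\sigma = 3.5$ &Aring;).  The charge-dependent part of the source field's
  desolvation is folded into the per-type $S$ values; the model here keeps
  $S$ and $V$ purely per-type.

The four published term weights (0.1662, 0.1209, 0.1406, 0.1322) are applied
as printed.  The cutoff is a hard truncation with no switching function:
this keeps every analytic property of the terms exact and testable; at
8 &Aring; the truncated tail contributions are far below the
thresholds that matter for classification.

## Preparation of the model

* **Conformers.** When alternate locations are present, the highest-occupancy
  conformer is kept (ties prefer altloc `A`, then file order): the method
  scores one conformer of a (preferably fully occupied) model.
* **Connectivity.** Protein bonds come from residue templates with Kekulé
  orders for His/Trp rings and aromatic orders for six-membered carbocycles;
  peptide bonds require C(i)-N(i+1) below 1.8 &Aring; (a longer gap is a
  chain break), disulfides SG-SG below 2.3 &Aring;.  Ligand bonds are
  detected from interatomic distances (covalent radius sum + 0.45 &Aring;);
  bond orders and formal charges come from a CCD-style component template
  when the het code is in the bundled (or a user-supplied) dictionary, else
  from a geometric heuristic: short terminal C-O/P-O contacts become double
  bonds, the remaining short terminal oxygens of carboxylate/phosphate
  groups are deprotonated (the pH-7 convention), and planar 5-6-rings with
  bond lengths in the aromatic window are perceived aromatic.
* **Protonation.** Standard pH-7 conventions: Lys/Arg and N-termini
  protonated, Asp/Glu and C-terminal OXT deprotonated, His neutral with the
  proton on NE2 (the templates can be edited for other tautomers).  No pKa
  prediction and no Asn/Gln/His flipping is attempted.
* **Hydrogens.** Only polar hydrogens are modelled, at riding positions
  (N-H 1.00 &Aring;, O-H 0.96 &Aring;, S-H 1.34 &Aring;; amide H on the
  in-plane bisector, sp2 NH$_2$ in the conjugation plane, ammonium H
  staggered, rotatable hydroxyls anti to the heaviest neighbour
  substituent).  Apolar C-H hydrogens are never added.
* **Charges.** Gasteiger-Marsili PEOE with the published orbital
  electronegativity coefficients, 8 damped iterations ($\tfrac{1}{2}^k$
  damping; the scheme converges in 6-8 iterations).  Carbons carry the
  charge of their implicit hydrogens (united-atom convention), implemented
  by temporary virtual hydrogen nodes whose converged charges are folded
  back into the parent; this reproduces a full-hydrogen reference PEOE
  implementation to better than 0.01 e on identical connectivity.  Protein
  charges are computed on the full chain graph rather than per residue;
  this is an assumption (the per-chain and per-residue conventions differ
  only near the termini and charged groups) and is documented as such.
* **Environment.** Waters and monoatomic ions are excluded from the protein
  environment; through-water and through-ion interactions are out of scope.
  Only the asymmetric unit is scored: crystallographic symmetry mates are
  not expanded, so a ligand truly bound at a crystal contact will look
  weaker than it is.  This is a known limitation, stated rather than
  patched.

## Ligand selection and entry filters

Validation surveys need a reproducible choice of "the" ligand: the largest
noncovalently bound non-water residue with 10-50 heavy atoms, taking the
copy associated with the first protein chain when a homo-multimer carries
several copies.  Covalency is decided by the file's annotated links *or* any
protein-ligand heavy-atom pair below 1.7 &Aring; -- deposited models contain
covalent bonds that are not annotated, and these must be caught by distance.
Entry-quality filters require full occupancy, mean ADP below
80 &Aring;$^2$ and (when supplied) RSCC above 0.917.

Contacts below 1.7 &Aring; are nevertheless *scored* when a ligand is named
explicitly: an unannotated covalent bond then shows up as an enormous
positive normalized energy plus a covalent-suspect warning, which is
precisely the signature that distinguishes "mis-modelled or covalent" from
"noncovalent and fine".

## Classification

The normalized energy $\hat{E} = E/n_{heavy}$ (kcal mol$^{-1}$ per atom, a
ligand-efficiency analogue) partitions complexes into:

| band | category | reading |
|---|---|---|
| $\hat{E} > 0$ | `clash_positive` | interatomic clashes |
| $-0.1 < \hat{E} \le 0$ | `weak_nonspecific` | very weak/surface contacts |
| $\hat{E} \le -0.1$ | `unproblematic` | ordinary specific binding |

The boundary $-0.1$ belongs to `unproblematic` and $0$ to
`weak_nonspecific`; a complex with no in-range pair has $\hat{E}=0$ exactly.

## Ranking candidate ligand identities

For ligand guessing, each candidate placed in the density carries an RSCC
and a normalized energy.  The combined score is a **nonparametric average**:
each metric is converted to a within-list rank (ties share the mean rank)
and the two ranks are averaged.  "Nonparametric" admits several readings
(ranks, percentiles, rescaled values); rank-averaging is adopted here as
the scale-free interpretation, and a min-max-rescaled mean is available
behind `method = "minmax"` for comparison.  The practical effect is the
desired one: a candidate with the best density fit but a clashing pose is
demoted below a slightly worse-fitting candidate with favourable energy.

```{r ranking}
combined_rank(data.frame(
  ligand_id = c("ATP", "AMP", "THP"),
  rscc = c(0.95, 0.93, 0.88),
  e_normalized = c(2.5, -0.28, -0.05)))
```

## The synthetic fixture generator

`make_fixture()` builds minimal complexes around an Ala-Lys-Ser-Gly
tetrapeptide at idealized extended geometry: a ketone accepting a backbone
amide hydrogen bond with its alkyl tail in van der Waals contact with the
peptide (`hbond_pair`, default H$\cdots$O 1.9 &Aring;), a carboxylate
against the Lys ammonium group (`salt_bridge`, N$\cdots$O 2.8 &Aring;), an
alkyl carbon far inside the repulsive wall of a backbone oxygen (`clash`,
1.0 &Aring;), an alkane at a $\ge$6.5 &Aring; gap (`inert_surface`), an
ethylene-glycol oligomer grazing the surface at 4 &Aring; (`peg_like`) and
a carbon at covalent-bond distance from the Ser hydroxyl
(`covalent_suspect`, 1.3 &Aring;).  The key distances are textbook values
for their interaction classes, chosen once; the seed only jitters tail
atoms by 0.01 &Aring;.

```{r fixtures}
for (k in c("hbond_pair", "salt_bridge", "inert_surface", "peg_like")) {
  rep <- score_complex(make_fixture(k))
  cat(sprintf("%-15s %+8.3f kcal/mol/atom  %s\n",
              k, rep$e_normalized, rep$category))
}
rep <- score_complex(make_fixture("clash"), ligand = "LG1:A:901")
cat(sprintf("%-15s %+8.1f kcal/mol/atom  %s\n",
            "clash", rep$e_normalized, rep$category))
```

What the fixtures emulate -- and what they do not.  They exercise every
scoring path (both 10-12 acceptor directions, charged groups, repulsive
walls, the covalency screen, the full file I/O round trip) on chemistry
small enough that every expected number can be computed independently.
They are *not* realistic pockets: no burial, no multivalent coordination,
no water structure, no conformational strain.  A passing fixture suite
demonstrates that the energy model and preparation pipeline behave as
specified, not that any particular deposited complex will reproduce a
particular number; per-entry checks on deposited coordinates require the
deposited files themselves.

## Numerical choices

* PEOE: 8 iterations, $0.5^k$ damping; charges conserve the formal charge
  of each connected component to numerical precision and are independent of
  atom input order.
* Cutoff 8 &Aring;, hard truncation (see above); clash flag at
  $0.6\,r_{eq,ij}$, configurable -- the flag is diagnostic only and does not
  enter the energy.
* Ties: altloc selection (occupancy, then `A`, then file order), ligand
  selection (size, then first protein chain, then file order), ranking
  (combined score, then energy, then id) are all resolved deterministically,
  so byte-identical inputs give byte-identical outputs.
* Degenerate inputs: an empty pair list scores exactly 0; coincident atoms
  raise an error rather than returning infinities; isolated donors skip
  hydrogen placement with a warning.
* Problem sizes: the bundled tests and the acceptance script run on
  mini-complexes of 24 protein atoms and 10-16 ligand heavy atoms, where
  the brute-force double loop is an exact oracle for the pair engine.

## Known limitations

* The exact grouping of weights in the source force field's figure-rendered
  equation is interpreted per the cited AutoDock papers; absolute energies
  of clashing structures are therefore order-of-magnitude quantities, and
  they are treated as such everywhere.
* The heuristic bond-order perception can miss exotic chemistry
  (metal coordination, unusual tautomers); supplying a component dictionary
  entry is the supported remedy.
* Aromatic ring nitrogens perceived heuristically (not via template) do not
  receive pyrrole-type hydrogens.
* No symmetry expansion, no through-water/ion interactions, no
  coordinate-error weighting of the sharply distance-dependent terms.
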