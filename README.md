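# ligenergy

Physical sanity checking for crystallographic protein–ligand complexes.

Density fit (RSCC) tells you whether a modelled ligand matches the electron
density; it does not tell you whether the modelled *binding mode* is
physically plausible. `ligenergy` estimates the interaction energy of a
protein–ligand complex **in its bound state** directly from a PDB/mmCIF
model and normalizes it per non-hydrogen ligand atom. The normalized energy
Ê is a one-number quality estimator, analogous to ligand efficiency:

* **Ê > 0** — the pose contains interatomic clashes (or an unannotated
  covalent bond);
* **−0.1 < Ê ≤ 0 kcal mol⁻¹ per atom** — very weak, usually nonspecific
  surface binding (buffers, cryoprotectants, PEG fragments);
* **Ê ≤ −0.1** — an unproblematic protein–ligand interface.

It is aimed at structural biologists validating deposited or freshly built
ligands, and at ligand-identification pipelines that want to re-rank
candidate identities by combining density fit with interaction energy.

## The model

For every protein–ligand atom pair within 8 Å:

```
E = W_vdw Σ (A/r¹² − B/r⁶)                 6–12 dispersion/repulsion (AMBER-derived)
  + W_hb  Σ E(t) (C/r¹² − D/r¹⁰)           directional 10–12 hydrogen bond
  + W_el  Σ q_i q_j / (ε(r) r)             Coulomb, Mehler–Solmajer sigmoidal ε(r)
  + W_sol Σ (S_i V_j + S_j V_i) e^(−r²/2σ²)  Gaussian desolvation
```

with the published AutoDock 4 per-type parameters and term weights,
Gasteiger–Marsili (PEOE) partial charges for protein and ligand, and polar
hydrogens placed at riding positions (apolar H folded into their parent
carbon). Ê = E / n_heavy. Ranking of candidate ligand identities uses a
nonparametric average: mean of the within-list ranks of RSCC (higher
better) and Ê (lower better).

See the methods vignette (`vignettes/ligenergy-methods.Rmd`) for the full
model, preparation conventions and design decisions.

## Worked example

Score a synthetic salt-bridge complex (a carboxylate ligand against a Lys
ammonium group; `make_fixture` builds legal PDB mini-complexes for every
interaction archetype):

```r
library(ligenergy)
s <- make_fixture("salt_bridge")          # tetrapeptide + carboxylate ligand
rep <- score_complex(s)                   # selects ligand LG1, full pipeline
rep
#> bound-state energy: -2.629 kcal/mol over 12 heavy atoms
#> normalized energy:  -0.219 kcal/mol per atom  [unproblematic]
#> terms: vdw -0.804  hbond -0.448  elec -0.888  desolv -0.490
#> 174 pair(s) in range, 0 clash(es), 0 covalent suspect(s)
clash_and_contact_report(rep, 3)
#> Clashes:
#>   (none)
#> Most favourable contacts:
#>   LYS A2 HZ1 -- ligand O1 : 1.80 A, -1.397 kcal/mol
#>   LYS A2 HZ2 -- ligand O1 : 3.27 A, -0.271 kcal/mol
#>   LYS A2 HZ3 -- ligand O1 : 3.27 A, -0.271 kcal/mol
```

The energy is negative and dominated by the electrostatic and hydrogen-bond
terms; the single most favourable contact is the ammonium H to carboxylate
O pair — exactly the salt bridge the fixture encodes. A clashing pose
instead scores hugely positive and is flagged:

```r
rep <- score_complex(make_fixture("clash"), ligand = "LG1:A:901")
rep$e_normalized   # 12391.35  (kcal/mol per atom: a severe clash)
rep$category       # "clash_positive"
```

Candidate re-ranking demotes a clashing high-RSCC candidate below a clean
lower-RSCC one:

```r
combined_rank(data.frame(
  ligand_id    = c("ATP", "AMP", "THP"),
  rscc         = c(0.95, 0.93, 0.88),
  e_normalized = c(2.5, -0.28, -0.05)))
#>   ligand_id rscc e_normalized combined rank
#> 1       AMP 0.93        -0.28      1.5    1
#> 2       ATP 0.95         2.50      2.0    2
#> 3       THP 0.88        -0.05      2.5    3
```

## Command line

A thin CLI wraps the same functions (installed under `exec/`):

```sh
ligenergy score model.pdb --ligand GDP:A:401 --json out.json --report pairs.tsv
ligenergy rank manifest.tsv --out ranking.tsv
ligenergy fixtures --kind clash --out f.pdb --seed 7
ligenergy params
```

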