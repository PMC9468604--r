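# btbdimer

Tools for studying why zinc-finger-and-BTB (ZBTB) transcription-factor BTB
domains — obligate dimers of ~120 residues — choose homodimerization over
heterodimerization, and what stabilizes the rare heterodimer. The package
is aimed at structural bioinformaticians who have per-frame outputs of
molecular-dynamics simulations of BTB dimers (coordinates and energy logs)
and want the downstream analyses: binding-energy decomposition, interface
salt-bridge barcodes, buried surface area, structural similarity, immune
lineage co-expression, and ortholog selection on phylogenies.

## What it computes

**MM-GBSA binding-energy decomposition.** The dimerization free energy is
estimated per frame as

```
ΔG = ΔE_int + ΔE_ele + ΔG_sol^PB + ΔG_sol^SA + ΔE_vdW
```

where each Δ term is `complex − (monomer A + monomer B)`, ΔE_int is the
combined change in bond, angle, dihedral and improper energies, ΔG_sol^PB
the polar (generalized-Born) and ΔG_sol^SA the nonpolar (SASA-proportional)
solvation terms. Components are averaged over the equilibrated window with
standard errors (SD/√n). These are scoring values for comparing dimers,
not absolute affinities. A heterodimer A–B is scored against the additive
expectation `(ΔG_AA + ΔG_BB) / 2`; an excess stabilization well beyond a
neutrality band (default 10 kcal/mol) marks a genuinely favored
heterodimer.

**Interface descriptors.** Salt bridges are acidic–basic side-chain
heavy-atom contacts (Asp OD1/OD2, Glu OE1/OE2 vs Lys NZ, Arg NE/NH1/NH2)
within 3.0 Å; their per-frame presence over a trajectory forms an occupancy
barcode, with pairs under 8 % occupancy dropped. Solvent-accessible surface
area (Shrake–Rupley with a deterministic Fibonacci point set) gives the
buried surface area `BSA = SASA(A) + SASA(B) − SASA(complex)` and the
interface residue percentage. Cα RMSD series with least-squares (Kabsch)
superposition feed an equilibration detector (terminal window with ≤ 1 Å
spread).

**Comparative layers.** Pairwise Cα RMSD matrices across BTB structures
(Needleman–Wunsch residue correspondence + Kabsch), lineage-stratified
Pearson co-expression with two-sided t p-values, correlation-matrix
clustering, ortholog-clade extraction from rooted trees (walk from the
query tip until a second same-taxon sequence appears; the previous node is
the ortholog clade), and an entropy-based 1–9 conservation grading.

**Synthetic data.** Seed-deterministic generators plant known salt-bridge
occupancies, drifting-then-stable RMSD profiles, component-wise energy
deltas, lineage-structured correlations and ortholog clades, and serialize
the planted truth, so the whole pipeline is testable without downloads.

## Worked example

The bundled reference table carries the printed MM-GBSA component values
for five BTB homodimers (PATZ1, BCL6, MIZ1, LRF, PATZ2) and four
heterodimers from 500-ns dimer simulations:

```r
library(btbdimer)

ref <- btb_reference_energies()
compare_dimers(ref)
#> # A tibble: 4 × 5
#>   dimer       dg_het dg_expected    ddg verdict
#>   <chr>        <dbl>       <dbl>  <dbl> <chr>
#> 1 PATZ1-PATZ2  -530.       -507. -22.2  heterodimer-favored
#> 2 PATZ1-BCL6   -471.       -465.  -5.55 neutral
#> 3 MIZ1-BCL6    -398.       -393.  -4.75 neutral
#> 4 LRF-ThPOK    -471.         NA   NA    <NA>
```

PATZ1-PATZ2 is ~22 kcal/mol more stable than the mean of its parent
homodimers — the signature of a real heterodimer — while PATZ1-BCL6 and
MIZ1-BCL6 sit within ~5–6 kcal/mol of their expectations (neutral: no
energetic reason to prefer the heterodimer). LRF-ThPOK is reported but
unscored because one parent homodimer is absent from the table.

The same analyses run end-to-end on synthetic trajectories:

```r
dimer <- make_toy_dimer(n_residues_per_chain = 14, n_contacts = 2, seed = 1)
sim <- simulate_trajectory(dimer, occupancies = c(0.60, 0.15), n_frames = 500, seed = 1)

bridge_barcode(sim$trajectory)[, c("pair", "occupancy")]
#> # A tibble: 2 × 2
#>   pair    occupancy
#>   <chr>       <dbl>
#> 1 D4a-R4b     0.592
#> 2 D9a-K9b     0.174

find_equilibrated_window(rmsd_series(sim$trajectory))
#> <frame_window [156, 500] (155-499 ns)>

logs <- simulate_energy_logs(n_frames = 1000, seed = 1)
deltas <- frame_component_deltas(logs$complex, logs$mon_a, logs$mon_b)
aggregate_mmgbsa(deltas, NULL, n_residues = 290)
#> MM-GBSA binding-energy summary (1000 frames, window [0, 999])
#>   dE_int       -354.1 +/- 0.3 kcal/mol
#>   dE_ele       -418.4 +/- 0.2 kcal/mol
#>   dG_sol_pb     437.4 +/- 0.2 kcal/mol
#>   dG_sol_sa       0.1 +/- 0.2 kcal/mol
#>   dE_vdw       -194.2 +/- 0.2 kcal/mol
#>   dG_total     -529.0 +/- 0.5 kcal/mol
#>   dG/AA          -1.8 kcal/mol per residue (290 residues)
```

The barcode pair labels read `D4a-R4b`: one-letter residue code, author
residue number, chain tag. Occupancies are the fraction of the 500 frames
in which each bridge is formed; the recovered energy components match the
planted deltas within their standard errors. `tidy()`/`glance()` turn
summaries into tibbles, and `autoplot()` draws RMSD series, barcodes, BSA
series and RMSD matrices with ggplot2.

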