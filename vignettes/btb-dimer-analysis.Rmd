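---
title: "Methods: binding energies, interfaces and co-expression of BTB dimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding energies, interfaces and co-expression of BTB dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btbdimer)
```

BTB domains sit at the N-terminus of the 49 human ZBTB transcription
factors and form obligate dimers whose interface buries 35–40 % of the
domain. Whether two different family members can pair — and whether such a
heterodimer is energetically preferable to the two homodimers — is a
question about interface energetics, interface composition, and
co-expression. This vignette documents the models this package implements,
the parameters that matter, the synthetic data used to test them, and the
numerical choices behind the results.

## The MM-GBSA binding-energy model

The dimerization free energy is scored per trajectory frame as

$$\Delta G \;=\; \Delta E_\mathrm{int} + \Delta E_\mathrm{ele} +
\Delta G_\mathrm{sol}^{PB} + \Delta G_\mathrm{sol}^{SA} + \Delta E_\mathrm{vdW},$$

with every $\Delta$ term defined as the complex value minus the sum of the
two monomer values at the same frame, and
$\Delta E_\mathrm{int}$ the combined change in bond, angle, dihedral and
improper energies. `frame_component_deltas()` forms the per-frame deltas
from three energy series (complex, monomer A, monomer B);
`aggregate_mmgbsa()` averages each component over the analysis window and
attaches the standard error $s/\sqrt{n}$ over frames. Because the total is
the per-frame sum of the components, its mean equals the sum of the
component means exactly — there is no second computational path to
disagree with.

Assumptions worth making explicit:

* **The energies are consumed, not computed.** The package parses MD-log
  style (`ETITLE:`/`ENERGY:`) or TSV energy records; it implements no
  force field, generalized-Born or Poisson–Boltzmann solver. When a log
  lacks the nonpolar column, `nonpolar_from_sasa()` supplies
  $\gamma \cdot \mathrm{SASA}$ (default $\gamma$ = 0.00542 kcal/(mol·Å²),
  a common surface-tension coefficient; configurable).
* **Scoring, not affinity.** Implicit-solvent decompositions of this kind
  rank dimers and attribute stabilization to components; no conversion to
  dissociation constants is offered.
* **No autocorrelation correction.** The SE is the naive SD/√n of frames,
  matching the convention of the analyses the package mirrors; frames of
  an MD trajectory are correlated, so these SEs are optimistic.
  Duplicate runs can be pooled with `combine_mmgbsa_runs()` (mean of
  means, SEs in quadrature).
* **The aggregator does not assume internal-term cancellation.** A strict
  single-trajectory decomposition would cancel bond/angle/dihedral terms;
  the aggregator accepts whatever monomer series are supplied and reports
  the resulting $\Delta E_\mathrm{int}$ as-is, because the reference
  component tables it reproduces print large nonzero internal terms.

A heterodimer A–B is judged against the additive expectation
$(\Delta G_{AA} + \Delta G_{BB})/2$ (`expected_heterodimer_dg()`).
`heterodimer_preference()` calls the pair *heterodimer-favored* when the
excess $\Delta\Delta G$ is below −band, *homodimer-favored* above +band,
else *neutral*. The band defaults to 10 kcal/mol: differences of a few
kcal/mol are within the noise of this scoring scheme, while the one
genuinely favored pair in the bundled reference table sits ~22 kcal/mol
below expectation. The band is a package choice, exposed in
`run_config()`.

```{r}
compare_dimers(btb_reference_energies())
```

## Interface descriptors

**Salt bridges.** A bridge exists in a frame when the minimum distance
between the acidic carboxylate oxygens (Asp OD1/OD2, Glu OE1/OE2) and the
basic side-chain nitrogens (Lys NZ, Arg NE/NH1/NH2) is ≤ 3.0 Å — the
common donor–acceptor heavy-atom convention. Histidine is neutral by
default (its protonation at pH 7 is ambiguous); `his_basic = TRUE` adds
ND1/NE2. Terminal amine/carboxylate groups are not counted. Occupancy is
computed over the *full* trajectory, not only the equilibrated window,
because barcode plots describe the whole run; pairs under 8 % occupancy
are dropped as transient. The window-restricted mean bridge count
(`avg_interface_salt_bridges()`) is the quantity reported next to binding
energies, and is computed over the equilibrated window by default
(configurable — whether full-run or window averaging is intended is
genuinely ambiguous, and the window matches the energy convention).

**SASA and buried surface area.** `shrake_rupley_sasa()` samples each
atom's probe-expanded sphere (probe 1.4 Å, water) with a deterministic
Fibonacci-spiral point set — no RNG, so results are bit-for-bit
reproducible at fixed `n_points` (default 960; the convergence tests use
3840). Bondi-type van der Waals radii are bundled; unknown elements are an
error rather than a silent default. Monomer SASA is evaluated on the
monomer's atoms *at the complex-frame coordinates* (the single-trajectory
convention), so
$\mathrm{BSA} = \mathrm{SASA}_A + \mathrm{SASA}_B - \mathrm{SASA}_{AB}$
is non-negative up to sampling tolerance. A residue joins the interface
when its window-mean buried area exceeds 0.1 Å² — a deliberately small
threshold (no published value exists for it) that separates "touches the
other chain at all" from "does not"; it is exposed in `run_config()`.

**RMSD and equilibration.** `rmsd_series()` superposes every frame onto
the reference (least-squares Kabsch, reflections suppressed) before taking
the Cα RMSD, so global rigid motion contributes nothing.
`find_equilibrated_window()` returns the longest terminal window whose
RMSD spread is ≤ 1 Å — terminal, because production analyses use the
equilibrated tail of a run. If the terminal stable stretch is shorter than
20 % of the series, the longest stable window anywhere is returned with a
warning (ties broken toward the latest end, keeping the terminal
preference); if no two consecutive frames are stable, the result is `NULL`
and the caller must widen the tolerance.

## Structure comparison

Cross-protein residue correspondence comes from global sequence alignment
(Needleman–Wunsch; match 2, mismatch −1, gap −2; traceback ties broken
diagonal > up > left for determinism), and only aligned columns with Cα
atoms on both sides enter the Kabsch superposition. Structural-alignment
tools would give slightly different correspondences, so cross-protein RMSD
values from this route should be read qualitatively (which pairs are most
alike), not as bit-exact reproductions of any particular published matrix.
Two-point and collinear point sets leave the rotation under-determined;
they are accepted with a warning because the minimized RMSD itself is
still well defined.

## Co-expression

`pairwise_correlation()` is the Pearson coefficient of a least-squares
linear fit with the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. Zero-variance
input yields an explicitly undefined result (`r = NA`), never a silent 0.
`lineage_correlations()` stratifies by immune lineage (≥ 3 samples each)
and flags $p \le 0.05$ per pair per lineage with **no multiple-testing
correction by default**, mirroring the per-cell-type significance bolding
convention of the expression tables it reproduces; a Benjamini–Hochberg
option exists (`adjust = "BH"`). Expression values are used as provided
(microarray normalization is upstream); `log_transform` is available.
Correlation matrices are ordered by average-linkage clustering on
$1 - r$, with genes pre-sorted by name so the leaf order is deterministic
under input permutation.

## Ortholog clades and conservation

`select_ortholog_clade()` implements the tree walk: starting at the query
tip, ascend ancestors until the first node whose subtree contains a
*second* sequence of the target taxon; the previous node's leaf set is the
ortholog clade. Two edges the rule leaves open are resolved as follows:
if the query's immediate parent already contains a second target-taxon
leaf, the clade is the query alone; if no ancestor ever does, the whole
tree is returned with a `root_fallback` flag. Unrooted trees are rejected
rather than midpoint-rooted, because rooting changes the answer and the
trees this walk is meant for are rooted by their builder. All same-taxon
leaves count as "second sequences" — isoform-level de-duplication is the
caller's responsibility.

`bin_conservation()` is a clearly-labelled stand-in for phylogeny-aware
conservation scoring: per-column normalized Shannon entropy over the
20-letter alphabet (gaps excluded), mapped onto nine equal-width bins with
9 = invariant. It is *not* the Rate4Site/ConSurf method; externally
computed 1–9 grades can be supplied wherever a conservation track is
accepted.

## Synthetic data: what it emulates and what it does not

The generators produce data with exactly the statistical structure the
analyses assume, plus a serialized truth record (JSON) so recovery tests
read planted values from the record rather than from constants:

* `make_toy_dimer()` — two parallel zig-zag pseudo-backbones (Cα spacing
  3.8 Å, chains 9 Å apart) with minimal side-chain atoms; planted
  acidic–basic contacts face each other at 2.8 Å, everything else is
  alanine pointing away, so no accidental bridges arise.
* `simulate_trajectory()` — each planted bridge toggles i.i.d. per frame
  (Bernoulli at its occupancy) between 2.8 Å and 4.5 Å; neutral residues
  carry a deformation field whose magnitude ramps linearly to a plateau
  (default 3 Å over the first 40 % of 500 frames) plus N(0, 0.1 Å) frame
  noise, giving the drift-then-plateau RMSD shape of a run that
  equilibrates. The truth records both the planted Bernoulli rate and the
  realized per-bridge occupancy, which differ by binomial noise
  ($\approx \sqrt{p(1-p)/n}$); barcode recovery is tested against the
  realized value (an exact statement), the planted rate against its
  binomial envelope. Note the window detector recovers the plateau onset
  to ±2 frames only when the drift slope near onset exceeds roughly half
  the tolerance per frame; with the gentle default ramp the terminal
  stable window legitimately extends ~tol/slope frames into the ramp, so
  the onset-recovery test uses a steep-drift configuration and the gentle
  default is checked for soundness (spread ≤ tol, plateau covered).
* `simulate_energy_logs()` — monomer components i.i.d. normal around
  fixed baselines; the complex is the realized monomer sum plus planted
  per-component deltas (defaults resembling a strongly bound BTB
  homodimer: ΔE_ele −418, ΔG_sol^PB +437.1, ΔE_vdW −194.3 kcal/mol, SD 5)
  plus noise, so each delta is recoverable with SE $\sigma/\sqrt{n}$.
* `simulate_expression()` — log-normal baseline; planted pairs drawn
  bivariate-normal on the log scale at the stated population correlation
  within the stated lineage.
* `random_tree_with_clade()` — a random binary tree whose root splits
  into the planted clade (query + k orthologs) and an outgroup containing
  a second target-taxon leaf, making the planted clade exactly the
  maximal second-target-free subtree.

What the generators do **not** emulate: real protein geometry (no
realistic packing, secondary structure or excluded volume beyond spheres),
Markovian bridge lifetimes (an i.i.d. toggle has geometric lifetimes at
the frame scale; a lifetime-sensitive analysis would need the two-state
option), correlated energy components, autocorrelated frames, microarray
noise structure, or realistic tree shapes. Passing tests therefore
demonstrate that the *estimators and rules* are implemented correctly —
occupancies, component means, correlations and clades are recovered at
their nominal uncertainties — not that the pipeline's scientific
conclusions transfer to any particular real system.

## Numerical choices

* Energies are reported at one decimal, occupancies at two, RMSD at one —
  the display precisions of the tables the package mirrors. Reported
  values round half *away from zero* (`round_half_away()`), with a 1e-9
  guard against the binary representation of decimal halves; base R's
  round-half-to-even would print the mean of −529.1 and −401.6 as −465.3
  instead of −465.4.
* SASA uses `n_points` = 960 by default (single-sphere error well under
  1 %); analytic-oracle tests run at 3840. The spiral point set makes
  results seed-free.
* The equilibration search is O(n²) worst case and is verified against an
  exhaustive window scan for series up to length 500.
* The window used for energy averaging must contain ≥ 2 frames; windows
  are inclusive and expressed in the energy series' own frame numbering.
* Test problem sizes: 500-frame trajectories for occupancy recovery,
  1000-frame energy logs for component recovery, 200 random trees up to
  100 leaves for the clade walk, 1000 draws for the correlation null.
  These sizes put the statistical checks at their nominal resolution
  while keeping the full suite around two minutes.

## Known limitations

* PDB support covers the ATOM/HETATM/MODEL subset (first altloc kept,
  waters dropped); no mmCIF.
* SASA is O(atoms × neighbours × points) in plain R — comfortable for
  BTB-domain-sized systems and the toy dimers, slow for large complexes.
* The conservation track is an entropy binning, not an evolutionary rate
  model.
* MM-GBSA standard errors ignore frame autocorrelation (see above).
* DCD/binary trajectory formats are not read; multi-model PDB and the
  documented coordinate TSV are the supported carriers.
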