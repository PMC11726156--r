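---
title: "Methods: filament polymorph geometry, fold comparison and segment composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filament polymorph geometry, fold comparison and segment composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibril)
```

## Scope and model

Amyloid filaments such as the α-synuclein filaments of multiple system
atrophy (MSA) are helical stacks of planar-ish polypeptide "rungs". Each
rung of a mature MSA filament contains two asymmetric protofilament (PF)
folds, conventionally an A and a B fold; distinct filament *types*
(polymorphs) differ in which folds they combine. `fibril` implements the
analyses that sit downstream of helical reconstruction and model building:

1. **Helical screw geometry** — twist/rise representation, crossover
   distance, stack expansion and screw-parameter fitting.
2. **Fold comparison** — Kabsch superposition, all-atom RMSD, per-residue
   Cα displacement profiles, contact maps.
3. **Hybrid cofilament clash modelling** — can two polymorphs stack within
   one filament?
4. **Segment composition statistics** — per-filament mixtures of classified
   cryo-EM segments under a predominance rule.
5. **Synthetic generators** with analytic expectations, so that 1–4 are
   testable without any deposited data.

## Helical geometry

A filament is generated from one rung by the screw operator: rotation by
the twist $\phi$ (degrees per subunit) about the axis direction composed
with a translation by the rise $\rho$ (Å per subunit) along it.
**Convention:** twist is signed by the right-hand rule about the axis
direction, with the direction chosen so the rise is positive; negative
twist therefore means a left-handed screw. MSA filaments have
$\phi \approx -1.34$ to $-1.42^\circ$ and $\rho = 4.76$ Å.

The crossover distance — the axial period of the flattened-ribbon
appearance in projection, i.e. the half pitch — is

$$d_\times = \rho \cdot \frac{180}{|\phi|},$$

which for $(-1.42^\circ, 4.76\,\text{Å})$ gives $\approx 603$ Å, matching
the ~600 Å crossovers measured on 2D class averages of these filaments.
The module derives the crossover from parameters rather than from images.

`fit_helical_params()` inverts `expand_stack()`: the Kabsch transform
between consecutive rungs is decomposed into a screw (axis from the
antisymmetric part of the rotation, angle via `atan2`, rise as the
translation component along the axis; the axis origin solves
$(I-R)p = t_\perp$ in the plane normal to the axis). Rotation angles below
$10^{-4}$ degrees are treated as degenerate — far below any biologically
meaningful twist — because the axis is then numerically undefined.

## Fold comparison

Atom pairing is deterministic: atoms match by protofilament *role* (A/B,
so chimeric folds pair across types, e.g. an IA₂ fold against a IIA fold),
author residue number and atom name, over the intersection of heavy atoms
present in both models. No sequence alignment is performed (identical
protein); author numbering is never altered. For whole deposited stacks the
central rung is compared by default, avoiding sparser edge rungs; the
choice is recorded in the result.

Cα displacement profiles superpose on Cα atoms of an explicit alignment
selection, then report per-residue Cα–Cα distances over a measurement
range plus their arithmetic mean. For chimeric fold pairs whose N-terminal
region is conformationally shared, the package's default idiom is to align
on that shared region (residues 14–56 for the MSA A-folds) and measure the
divergent C-terminus (57–93); aligning on a different fold of the same
filament (e.g. the common B fold) is supported via `align_a`/`align_b`.
Both options exist because published overlays do not always state which
anchor produced a quoted mean displacement; reproduction tolerances of
±0.2–0.5 Å absorb the difference.

Contact maps list non-bonded heavy-atom pairs within a cutoff (3.5 Å
default for polar contacts, 4.5 Å for hydrophobic packing), excluding
same-residue pairs and backbone–backbone pairs of sequence-adjacent
residues. The search uses an exact cell-list (grid hash, cell = cutoff);
tests verify equality with an $O(n^2)$ scan.

## Hybrid cofilament clash model

`build_hybrid()` asks whether a rung of polymorph B can continue a stack of
polymorph A: the incoming rung is superposed onto the rung above the
junction using Cα atoms of the homologous window only (residues 57–93 of
the A-role fold for the MSA I₂/II₂ pair), and `count_clashes()` reports
inter-rung van der Waals overlaps, split into homologous-window versus
nonhomologous clashes. Clash criterion: overlap
$r_i + r_j - d \ge 0.4$ Å (0.6 Å = "severe"), with fixed element radii
C 1.70, N 1.55, O 1.52, S 1.80 Å. The source study prints no clash count
for its mixed-cofilament figure, so only the qualitative direction — many
nonhomologous clashes in the mixed hybrid, essentially none in native or
same-type controls — is treated as reproducible.

## Segment composition

Segments (boxed windows along picked filaments) carry a class assignment
from 3D classification; a class→type map turns these into filament-type
labels. The pipeline: `filter_micrographs()` keeps micrographs containing
at least one segment of the rarer type (with a ~13-fold abundance
imbalance, only those micrographs are informative); `compose_filaments()`
computes per-filament fractions over *typed* segments only — "other"
segments are counted but excluded from the denominator — and categorises
with an **inclusive** 90% threshold (9 of 10 is predominant);
`strongly_mixed()` counts filaments with ≥ 10 segments of each type;
`summarize_composition()` adds a 10-bin histogram of the I₂ fraction
(left-closed bins, last bin right-inclusive) and summary shares, with
percentages rounded half away from zero to match printed styles. Filament
identity is the (micrograph, filament) pair — filaments never span
micrographs. The minimum typed-segment floor per filament is 1 and
configurable, since published denominators do not state a floor.

## Synthetic generators: what they emulate, and what a green test means

`make_fold_pair()` produces two toy fold templates — planar C-shaped
80-residue arcs (Cα spacing 3.8 Å, arc radius 60 Å about the stacking
axis, one CB pseudo-atom per residue at a 1.5 Å inward offset) — that are
*exactly* identical over a shared residue window and diverge smoothly
outside it, with amplitudes scaled so the mean Cα displacement outside the
window equals the requested divergence exactly (default 4.8 Å, the
magnitude seen between chimeric MSA A-folds). Design notes:

* The divergence direction is tilted 65° out of the rung plane, pointing
  against the stacking direction. A strictly planar divergence can never
  produce an inter-rung clash at a 4.76 Å rise (the largest heavy-atom vdW
  sum is 3.6 Å), because every displaced atom stays ≥ one rise away from
  the neighbouring rung; real filaments clash through side chains and
  non-planar rungs. The tilt is the minimal stand-in for that. A pure-B
  stack remains clash-free (all rungs share the dip), while a B rung
  placed in an A lattice dips toward its A neighbour — exactly the control
  asymmetry the hybrid analysis relies on.
* Because the shared window is bit-identical between variants, aligning on
  it is an exact superposition, and the measured displacement profile
  equals the generator's stored ground truth to machine precision — this
  is what makes the generator a usable oracle.
* The 3.8 ± 0.1 Å Cα-spacing invariant holds for the base template; the
  displaced variant necessarily stretches spacing near the ramp (any
  smooth 0 → ~5 Å displacement over ~40 residues must), which is accepted
  as the price of a controlled displacement field.
* No attempt is made at a realistic Greek-key cross-section, side-chain
  chemistry, or map-level realism. A green geometry test establishes
  correctness of the geometric operators, not structural plausibility of
  the toys.

`generate_segment_table()` draws filament true types (probability `p_I2`,
default 0.5) and per-segment labels under symmetric misclassification
(`epsilon`) plus an "other" fraction (`p_other`), with filaments per
micrograph ~ truncated Poisson(1.3, min 1) and segments per filament ~
truncated Poisson(25, min 1) — unstated in the source data, chosen as
plausible for sparse *ex vivo* micrographs and fully configurable. Its
analytic twin `expected_predominant_fraction()` is the exact binomial tail
$P(\text{minority} \le \lfloor (1-\theta) n \rfloor)$; for $n=20$,
$\varepsilon=0.05$, $\theta=0.9$ this is 0.9245, and the pipeline's
recovered exclusive-or-predominant fraction must agree within binomial
Monte-Carlo error. Note two deliberate subtleties: the pipeline's
"either type" statistic also gains the (negligible for small ε) upper
binomial tail, and conditioning on the micrograph filter biases the
recovery check (it selects for filaments with at least one minority
label), so the recovery tests run on unfiltered tables.

## Numerical choices and degenerate inputs

* Predominance threshold comparisons use a 1e-9 tolerance so that exact
  boundary fractions (9/10) are inclusive under floating point.
* Kabsch superposition requires ≥ 3 non-collinear pairs; collinearity is
  detected by rank of the centred coordinate matrix.
* Altloc policy: highest occupancy, ties to altloc "A"; hydrogens dropped
  on read. Rung inference assigns rung indices by rank along the fitted
  axis within each screw-copy chain signature when copy counts agree
  (robust to per-fold centroid offsets), falling back to gap clustering
  (2 Å) otherwise; a chain→fold override map exists because depositions do
  not label protofilaments.
* All randomness flows through explicit integer seeds; tables and
  templates are bit-reproducible under a fixed seed.

## Known limitations

* Multi-start helices and reconstruction-level operations (classification,
  refinement, maps) are out of scope.
* Fold labelling by residue-range heuristic cannot distinguish subtypes
  with identical cores (e.g. I₁ vs I₂ A-folds); use the override map when
  the identity matters.
* Published RMSD/displacement values depend on unstated pairing details
  (which rung, which atom intersection); reproduction tolerances of
  ±0.2 Å (RMSD) and ±0.2–0.5 Å (displacements) absorb this and the
  package does not claim tighter agreement.
* The real-data comparisons require the four deposited models and hence
  network access; offline, only the synthetic counterparts run.
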