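---
title: "Methods: trajectory analysis of a zinc-site protein–ligand complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of a zinc-site protein-ligand complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zntraj)
```

## Scope and data model

`zntraj` analyses molecular-dynamics trajectories of metalloprotein–ligand
complexes whose chemistry is organised around a structural Zn(II) site — the
kind of system in which a small-molecule inhibitor (here, a macrolactone such
as robotnikinin binding the Sonic Hedgehog signalling domain) competes with
protein residues for coordination of the ion. The package operates on
multi-model PDB trajectories: a fixed topology (atom name, element, residue
name and number, chain) plus one coordinate set per frame, all in Å. Residue
numbering is taken verbatim from the file, so selections use the numbering of
the source structure (e.g. H141, E177 in Shh numbering). There is no
periodic-boundary handling anywhere: inputs are assumed to be whole, unwrapped
complexes (solvent-stripped snapshots), for which minimum-image logic would be
dead code.

Atom elements are read from PDB columns 77–78 when present and otherwise
inferred from the atom name by stripping digits and taking the leading
alphabetic token, with a fixed lookup for two-letter elements. The one genuine
ambiguity, `CA`, resolves to calcium only when the residue itself is the ion
(`resname CA`); otherwise it is an α-carbon.

## Ion coordination: RDF, number integral, first minimum

`compute_rdf()` bins, per frame, the distances from one central atom to a
partner selection and averages the per-bin counts over frames. The profile
deliberately stores **mean counts per bin**, not a bulk-normalised g(r): for
an ion buried in a protein interior there is no well-defined bulk density to
normalise by, and every quantitative statement (coordination numbers, solvent
counts) uses only the running number integral, which is the cumulative sum of
mean counts. Defaults are a 0.05 Å bin and a 10 Å range.

Counting uses a strictly-less-than cutoff with ties at machine precision
(10⁻⁹ Å) counted as inside; the convention is fixed so integer-valued recovery
tests are exact. `coordination_series()` gives the per-frame coordination
number and its mean; `denticity_fractions()` classifies each frame of a
two-oxygen carboxylate group as bidentate, monodentate or unbound;
`mean_count_within()` is the direct per-frame count that equals the number
integral at the same radius (useful for statements like "0.006 water molecules
within 5 Å").

`detect_first_minimum()` scans for the first peak and returns the bin centre
of the lowest-density bin strictly between that peak and the next rise, with
plateaus resolved to the smallest radius. Because raw per-bin counts at
typical frame counts are shot-noise limited, the scan runs by default on a
3-bin moving-average copy of the histogram; the returned value is always a raw
bin centre. The smoothing is a detection aid only and can be disabled; a
single shallow dip on a peak flank is then taken at face value.

## Hydrogen bonds

A donor–H···acceptor triple counts as bonded in a frame when the
hydrogen–acceptor distance is below 3.0 Å **and** the deviation from
linearity is below 35°. Two remarks on these defaults:

* The distance criterion is hydrogen-to-**acceptor**. A literal
  hydrogen-to-donor reading would test a covalent bond length (~1 Å) and could
  never discriminate anything; reported mean O···H contact distances of
  2.1–2.3 Å pairing with high occupancies are consistent only with the
  hydrogen–acceptor reading.
* The 35° angle is implemented as the deviation-from-linearity at the donor,
  between the donor→hydrogen and donor→acceptor vectors (0° = perfectly
  linear). Whether such an angle is measured at the donor or at the acceptor
  is genuinely ambiguous in much of the literature, so both conventions are
  available (`angle_vertex = "donor"` / `"acceptor"`); the donor vertex is the
  default and the choice is documented, not asserted as anyone's intent.

`hbond_occupancy()` reports occupancy as the percentage of frames satisfying
the criteria, and the mean hydrogen–acceptor distance **over all frames**,
bonded or not. The all-frames convention is forced by the way occupancy
tables pair long mean distances (> 4 Å) with small but nonzero occupancies —
impossible if the mean were taken over bonded frames only. When several
acceptor atoms are given, the closest one is used per frame.

## π-stacking

`classify_stacking()` fits each ring's least-squares plane (smallest
principal component of the centred ring coordinates; rings with an RMS
out-of-plane residual above 0.3 Å are rejected), folds the inter-plane angle
θ to [0°, 90°], and classifies: parallel-displaced if the centroid distance
d ≤ 6.5 Å and θ ≤ 30°, T-shaped if d ≤ 6.5 Å and θ ≥ 60°, otherwise
unclassified. These thresholds are conventional geometric gates for stacking
surveys — no primary source prints values for them — and are plain config
parameters.

## Superposition and RMSD analyses

`kabsch_superpose()` is the SVD form of the Kabsch algorithm with the
reflection excluded (determinant forced to +1 via the smallest-singular-vector
sign correction); degenerate inputs (collinear, < 3 points) still yield the
minimal RMSD with a deterministic representative rotation. The test suite
checks it against a brute-force rotational search (coarse Euler grid plus
Nelder–Mead refinement) on small point sets.

`ligand_rmsd_series()` fits the **protein** onto the reference frame, applies
that transform to the ligand, and measures ligand heavy-atom RMSD without a
second fit on the ligand — a ligand refit would silently erase dissociation
events, which are exactly what the series exists to expose.

`per_residue_rmsd()` performs one global Cα fit per frame (atoms matched
across systems by residue number and atom name) and then computes per-residue
heavy-atom RMSDs with **no per-residue refitting**. The choice is deliberate:
collective displacement of a contiguous segment — a lid region closing over
the binding groove — is a rigid motion at the residue scale, and per-residue
refitting would subtract it away. Residues with no matchable atoms go into a
skipped-residues report, never silently missing columns.

`corrected_heatmap()` implements the apo-fluctuation correction: the baseline
is the per-residue time-mean of the apo system's self-comparison matrix, and
the corrected map is the loaded-versus-apo matrix minus that baseline,
clamped at zero. Clamping matches the non-negative colour scale such maps are
rendered on, and self-comparison cancels exactly by construction.

## SASA

`shrake_rupley()` samples each probe-inflated atomic sphere with a
deterministic Fibonacci lattice (seedless and reproducible; 960 points by
default, probe 1.4 Å) and counts points not inside any other inflated sphere.
Points exactly on another sphere's surface (within 10⁻⁹ Å) are occluded only
by atoms earlier in topology order, so exactly coincident duplicate atoms
partition one surface instead of double-counting or annihilating it. Radii
default to the Bondi set. Because the lattice is fixed in space, exact
rotational invariance requires co-rotating the lattice (`orientation` in
`sasa_config()`); without it, invariance holds to the lattice resolution
(~0.1%).

`summarize_series()` uses the sample SD (n−1) and the normal z-quantile:
half-width = z·sd/√n, i.e. 1.96·sd/√n at 95%. This convention is pinned by
arithmetic: it reproduces both of the printed half-widths ±0.7 Å² (SD 12.0,
n = 1000) and ±1.4 Å² (SD 22.7, n = 1000) that a mean-SASA summary of this
kind reports.

## QM/MM boundary utilities

The boundary machinery is exposed as standalone utilities, independent of any
QM engine. `link_param_table()` houses the 12 published link-bond parameter
rows — {ρ, r₀, k_L} for Hid, Hie, Glu, Asp and the two ligand link bonds
(ROB1/ROB2), each for a triple-zeta and a double-zeta basis. `place_link_atom()`
puts the capping hydrogen at Cα + ρ·(Cβ − Cα). `link_correction()` evaluates
the harmonic correction E = k_L(r − r₀)² and its exact force; the convention
**without** the ½ factor is the default, consistent with force constants
quoted in kcal·mol⁻¹·Å⁻², and the ½k convention is a switch since the formula
itself is rarely written out.

Electrostatic embedding export scales **all** MM charges by a single factor
(default 0.666, which maps the TIP3P water oxygen charge −0.83 e to the
−0.55 e a DFT description assigns bulk water) and excludes the QM selection.
The proximity phrasing sometimes attached to such factors is motivation, not
a distance rule: the scaling here is global and the point-charge file is a
neutral whitespace-delimited `x y z q` layout, since QM engines disagree on
input dialects.

## Synthetic-data generators and what they do (not) show

Each generator is a pure function of its arguments including the seed, emits
a ground-truth record sufficient to predict every downstream statistic, and
round-trips through the PDB layer:

* `gen_zn_site()` — Zn(II) at the origin, 5 coordinating O/N partners at
  2.0 Å (a typical first-shell Zn–O/N distance) with 0.05 Å isotropic noise,
  10 water oxygens between 6 and 9 Å, and an optional partner that flickers
  across the 2.83 Å cutoff in an exact fraction of frames. The noise bound
  noise_sd ≤ (cutoff − bond length)/4 is enforced so the planted coordination
  number is recovered exactly, not approximately.
* `gen_hbond()` — a triple that satisfies comfortable bond geometry (2.0 Å,
  5° off linear) in bonded frames and violates both criteria (4.0 Å, 60°) in
  unbonded ones. The deterministic mode bonds exactly ⌊p·n⌋ frames precisely
  so occupancy tests are exact rather than statistical; the Bernoulli mode
  exists for the statistical recovery checks.
* `gen_fluctuating_protein()` — a 31-residue helical Cα/Cβ toy chain
  (helical, because an exactly straight chain would make the global Cα fit
  rotationally degenerate). The apo copy fluctuates at 0.1 Å everywhere; the
  loaded copy fluctuates at 0.3 Å on residues 131–136 and displaces them by
  1.0 Å, emulating a six-residue lid segment that moves on ligand binding.
  Frame 1 of the apo trajectory is noise-free so it can serve as the apo
  reference structure.
* `gen_stacked_rings()` — ideal 1.39 Å hexagons in parallel-displaced
  (offset (1.5, 0, 3.5) Å) or T-shaped (perpendicular, 5 Å) arrangements with
  0.02 Å jitter.

These fixtures validate the *bookkeeping* of every analysis stage against
closed-form truth. They are not physical: there is no force field, no water
structure, no correlated motion, and the fluctuation model is isotropic
white noise. Passing the recovery suite therefore demonstrates that the
statistics are computed correctly, not that any particular real system
behaves a given way.

## Numerical choices and problem sizes

Cutoff ties resolve inside at 10⁻⁹ Å; first-minimum plateaus resolve to the
smallest radius; Kabsch degeneracies resolve by SVD convention; SASA surface
ties resolve by topology order. The test suite and the acceptance script run
at deliberately desk-scale sizes — 100–1000-frame synthetic trajectories,
960-point SASA lattices, 50-seed Bernoulli recovery — chosen so the whole
validation cycle completes in well under a minute while keeping every
statistical check adequately powered.

## Known limitations

No mmCIF or binary trajectory formats, alternate locations or insertion
codes; no mass-weighted superposition; no energy-based hydrogen-bond scoring
or donor/acceptor perception (triples come from configuration); no
Lee–Richards SASA; no per-atom RMSF or B-factor comparison; rendering of
heatmaps beyond base-graphics `plot()` methods is left to external tools, and
the exported TSV matrices are written for exactly that purpose.
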