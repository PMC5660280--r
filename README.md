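# zntraj

Trajectory analysis for metalloprotein–ligand complexes built around a
structural Zn(II) site, plus the QM/MM boundary utilities such studies need.
The motivating system is the Sonic Hedgehog (Shh) signalling domain — whose
binding groove carries one Zn(II) and two Ca(II) ions — bound by the
macrolactone inhibitor robotnikinin, but every operation is generic over
multi-model PDB trajectories.

The package computes, from an MD trajectory:

* **Ion coordination** — ion-centred radial distribution profiles with
  running number integrals n(r) = Σᵣ′≤ᵣ ⟨counts⟩, first-minimum detection,
  per-frame coordination numbers CN(t) = #{j : r_ij < r_cut}, and carboxylate
  denticity fractions (bidentate/monodentate/unbound).
* **Hydrogen bonds** — geometric occupancy statistics: a donor–H···acceptor
  triple is bonded when d(H···A) < 3.0 Å and the deviation-from-linearity
  angle is < 35°; occupancy is the percentage of frames bonded, mean contact
  distances are averaged over all frames.
* **π-stacking** — ring pairs classified as parallel-displaced
  (d ≤ 6.5 Å, θ ≤ 30°) or T-shaped (d ≤ 6.5 Å, θ ≥ 60°) from best-fit ring
  planes.
* **RMSD analyses** — Kabsch superposition (reflection-free SVD), ligand
  RMSD after a protein-only fit, per-residue heavy-atom RMSD matrices, and
  the apo-fluctuation-corrected heatmap
  `corrected = max(loaded − mean_t(apo_vs_itself), 0)`.
* **SASA** — Shrake–Rupley solvent-accessible surface area on a
  deterministic Fibonacci lattice, with mean ± z·sd/√n confidence summaries.
* **QM/MM boundary** — the 12-row link-bond parameter table {ρ, r₀, k_L}
  (TZ/DZ bases), link-atom placement at Cα + ρ(Cβ − Cα), the harmonic
  correction E = k_L(r − r₀)², and charge-scaled (factor 0.666)
  electrostatic-embedding point-charge export.
* **Synthetic trajectories** — seeded generators with closed-form ground
  truth (planted coordination numbers, exact hydrogen-bond occupancies,
  planted lid-residue drift, ideal stacked rings) used throughout the test
  suite.

## Worked example

```r
library(zntraj)

# a synthetic Zn(II) site: 5 O/N partners at 2.0 Å (noise 0.05 Å), 10 shell waters
zn   <- gen_zn_site(n_frames = 100, n_coordinating = 5, seed = 7)
traj <- zn$trajectory   # or read_multimodel_pdb("trajectory.pdb")

coordination_series(traj, list(resname = "ZN"), list(element = c("O", "N")),
                    cutoff = 2.83)
#> CoordinationResult: mean CN 5.00 within 2.83 A over 100 frame(s); RDF peak 2.03 A, first minimum 2.28 A

mean_count_within(traj, list(resname = "ZN"), list(resname = "HOH"), 5)
#> [1] 0

hb <- gen_hbond(n_frames = 1000, occupancy = 0.857, seed = 7)
hbond_occupancy(hb$trajectory, hbond_triple(1, 2, 3))
#> ContactStat: mean distance 2.29 A, occupancy 85.7% over 1000 frame(s)

lookup_link_params("Hid", "TZ")
#> LinkBondParams Hid/TZ: rho 0.7140, r0 1.560 A, kL 139.056 kcal/mol/A^2
unlist(link_correction(1.66, lookup_link_params("Hid", "TZ")))
#>          energy           force force_magnitude
#>         1.39056       -27.81120        27.81120

round(scale_charge(-0.83), 2)   # TIP3P oxygen under the 0.666 embedding factor
#> [1] -0.55
```

The coordination result reads: averaged over 100 frames, exactly 5.00 O/N
atoms sit within the 2.83 Å cutoff of the ion, the most probable ion–partner
distance is 2.03 Å, and the profile's first minimum falls at 2.28 Å. The
contact statistic reads: the hydrogen–acceptor distance averages 2.29 Å over
all frames and 85.7 % of frames satisfy the hydrogen-bond criteria. The link
correction at r = 1.66 Å is 1.39 kcal/mol with a restoring force of
27.8 kcal/mol/Å toward r₀ = 1.560 Å.

A config-driven pipeline (`run_profile()`, `run_heatmap()`,
`run_link_prep()`, YAML schema in `?read_analysis_config`) ties the stages
together, and `inst/cli/zntraj` is a thin Rscript front end with
`profile`, `heatmap`, `rdf`, `sasa`, `link-prep` and `generate` subcommands.

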