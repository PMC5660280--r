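Package: zntraj
Title: Trajectory Analysis of Zinc-Site Protein-Ligand Complexes and
    QM/MM Boundary Utilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of molecular-dynamics trajectories of metalloprotein-ligand
    complexes centred on a structural Zn(II) site: multi-model PDB trajectory
    input/output, ion-centred radial distribution functions with running number
    integrals and first-minimum detection, coordination-number and carboxylate
    denticity statistics, geometric hydrogen-bond occupancy, closest-atom contact
    distance series, pi-stacking classification, Kabsch superposition and
    fluctuation-corrected per-residue RMSD heatmaps, Shrake-Rupley solvent
    accessible surface area with confidence-interval summaries, and QM/MM
    boundary utilities (link-atom placement, harmonic link-bond correction,
    charge-scaled electrostatic-embedding export). Includes deterministically
    seeded synthetic-trajectory generators with closed-form ground truth for
    validation, and a config-driven analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
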