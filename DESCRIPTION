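Package: nbibench
Title: Energetics and Benchmarking of Protein-Ligand Nonbonded Interaction Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies nonbonded interactions between protein kinase
    inhibitors and their binding-site residues from two-monomer structural
    motifs. Parses motif coordinates from PDB fragments, perceives rings and
    hydrogen bonds, measures the geometric descriptors of each interaction
    mode (CH-pi, pi-pi stacking, cation-pi, hydrogen bond, salt bridge), and
    classifies motifs. Computes atom-pairwise D3 dispersion energies with
    Becke-Johnson damping, two-point complete-basis-set extrapolation of
    correlation energies, composite CCSD(T)/CBS interaction energies,
    counterpoise-corrected supramolecular energy differences, and
    solution-phase energies via a dehydration thermodynamic cycle. Provides
    RMSD/MAE/signed-error/maximum-percentage benchmarking of density
    functional methods against coupled-cluster references, per-mode energy
    summaries, accuracy-versus-cost Pareto analysis, and synthetic-data
    generators with known ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
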