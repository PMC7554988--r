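Package: FeSConserv
Title: Conservation and Stability Analysis of the Fe-S Cluster Assembly
    Supercomplex and Frataxin
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-informed conservation and biophysical
    stability analysis of the mitochondrial iron-sulfur cluster assembly
    supercomplex (NFS1/ACP-ISD11/ISCU/FXN) and of frataxin homologs.
    Extracts protein-protein and protein-ligand interface residues from
    multi-chain structures at a distance cutoff, computes Shrake-Rupley
    solvent accessibility and its change upon complex formation, derives
    overall and region-restricted identity and similarity from pairwise
    alignments, profiles column conservation of curated multiple sequence
    alignments with threshold statistics and reference-numbering maps, fits
    two-state chemical (linear extrapolation) and thermal (Gibbs-Helmholtz)
    unfolding models, partitions cross-homolog alanine-scanning ddG
    correlations by conservation class, computes sequence-derived physical
    constants and Myers chain-length correlations, analyses fourth-derivative
    UV absorbance spectra, and ships seeded synthetic-data generators with
    machine-readable ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    bio3d,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    knitr,
    rmarkdown
biocViews: StructuralPrediction, Alignment, Proteomics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
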