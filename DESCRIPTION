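Package: epimode
Title: Binding-Mode Identification for Rigid Protein Binders from Docking
    Ensembles and Mutational Binding Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying the binding mode of rigid scaffold protein
    binders (such as leucine-rich-repeat repebodies) against their targets.
    Designs minimal panels of binding-disruptive target variants that
    discriminate among docking-model ensembles via exact set cover, calls
    per-position binding involvement from dissociation-constant fold changes,
    filters docking models for consistency with those calls (with homodimer
    symmetry handling), ranks surviving models by a coarse interface energy or
    imported force-field energies, and assesses model quality with CAPRI-style
    metrics (fraction of native contacts, interface RMSD, interface-residue
    recovery). Also provides conservation-guided specificity analysis and
    greedy two-position affinity design from a confirmed complex model, plus
    deterministic synthetic fixtures (toy complexes, graded rigid-body decoys,
    C2 homodimers, simulated binding assays) so the whole pipeline can be
    exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
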