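Package: cdnconf
Title: Conformational Analysis of Cyclic Di-Nucleotides from Torsion
    Ensembles and NMR J-Couplings
Version: 0.1.0
Authors@R:
    person("cdnconf", "maintainers", email = "cdnconf@example.org",
           role = c("aut", "cre"))
Description: Pseudorotation and torsion-angle analytics for cyclic
    di-nucleotide (CDN) conformer ensembles, Karplus-based fitting of
    sugar pucker, gamma rotamer populations and backbone torsions from
    scalar coupling constants, population free-energy landscapes over
    the glycosidic/pseudorotation plane, and macrocycle-aware RMSD
    comparison of conformers.  Ships a synthetic-data generator (von
    Mises torsion ensembles, forward-modelled coupling sets, an
    idealized macrocycle template builder) so every stage is testable
    without molecular-dynamics or NMR runs, plus multi-model PDB and
    CSV/JSON readers and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
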