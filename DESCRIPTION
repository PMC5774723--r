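Package: asitetools
Title: Thermodynamic and Structural Analysis of Ribosomal A-Site RNA Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for bipartite RNA models of the 16S rRNA
    decoding A-site and their complexes with 2'-O-methylated
    oligoribonucleotides.  Provides a sequence registry with E. coli
    numbering and antiparallel mismatch scanning; seeded generators for
    idealized A-form duplex trajectories (with scheduled base flips),
    UV melting curves and isothermal titration calorimetry series;
    trajectory metrics (Kabsch RMSD, per-residue RMSF, gromos RMSD
    clustering, block-standard-error convergence curves); hydrogen-bond
    detection and Watson-Crick/Hoogsteen/sugar edge base-pair
    classification with occupancy tables; nucleobase stacking detection
    and Coulomb plus Lennard-Jones stacking energies; base-flip
    pseudo-dihedral angles; and two-state UV melting and 1:1 ITC
    binding-isotherm fitting with van't Hoff analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
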