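Package: nanoem
Title: Iterative Nanobody CDRH3 Design by Expectation-Maximization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and optimization of nanobody (VHH) CDRH3 loops by an
    expectation-maximization loop that alternates between complex generation
    (docking, steric-clash and binding-interface quality control, and
    epitope-recall beam selection) and CDR design (generative proposal,
    side-chain packing, and binding-affinity-ranked selection). Includes a
    hierarchical structure model with PDB input/output, deterministic
    Shrake-Rupley solvent-accessible surface area and dSASA interface
    detection, van der Waals steric-clash quantification with a soft-sphere
    refinement engine, a structure-comparison metric battery (amino-acid
    recovery, Kabsch RMSD, TM-score, lDDT, DockQ), pluggable engine
    contracts with seeded mock reference engines, and a synthetic fixture
    generator so the whole method runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
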