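Package: arpscreen
Title: Screening and Quantitation of ARP-Derivatized Protein Carbonylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for mapping and quantifying protein
    carbonylation sites in serum proteomics experiments that use the aldehyde
    reactive probe (ARP, N'-aminooxymethylcarbonylhydrazino-D-biotin). Provides
    exact monoisotopic mass arithmetic and ARP derivatization chemistry with a
    registry of carbonyl modifications, elemental-composition decomposition from
    accurate mass, reporter-ion screening of tandem mass spectra, spectral
    similarity guided inference of unknown modification mass shifts with ion
    mobility constraints, peptide-centric DIA quantitation with indexed
    retention time calibration, negative-control signal-to-background filtering,
    per-batch quality control, top-5 protein normalization and a batch-aware
    two-group comparison. Includes seeded generators for synthetic DDA spectra
    and DIA cohorts with ground truth, so every stage can be exercised and
    scored end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'chem-composition.R'
    'chem-peptide.R'
    'chem-arp.R'
    'chem-isotopes.R'
    'chem-solver.R'
    'spectra-io.R'
    'reporter-screen.R'
    'modshift.R'
    'dia-quant.R'
    'synthetic-data.R'
    'pipeline.R'
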