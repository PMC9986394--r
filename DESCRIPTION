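Package: apoScreen
Title: High-Content microRNA Inhibitor Screen Analysis for Apoptosis
    Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of high-content microRNA inhibitor screens that read
    out caspase-3/7-mediated apoptosis in drug-responsive and
    endocrine-resistant breast cancer cell lines. Converts two-channel
    fluorescence microscopy fields (Hoechst nuclear stain plus caspase-3/7
    reporter) into per-well apoptotic scores via nuclear segmentation,
    calls hits with robust Z-scores of resistant-vs-parental log fold
    changes (median/MAD with the 0.6745 normal-consistency constant) and a
    three-way phenotype classification, intersects differentially
    expressed genes with predicted and validated microRNA target sets to
    nominate direct targets, scores two-drug dose grids against the
    highest-single-agent synergy reference, and provides the small assay
    formulas (delta-delta-Ct fold change with multiple reference genes,
    xenograft tumour volume, immunohistochemistry scoring, relative
    growth). A seeded synthetic-data module generates microscopy fields,
    full screen tables, target databases and dose-response surfaces with
    recorded ground truth so the entire pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: CellBasedAssays, FeatureExtraction, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
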