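Package: painConn
Title: Individualized Atypical Functional Connectivity Analysis for Chronic Pain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Seed-based resting-state functional connectivity analysis with
    single-subject normative inference. Computes seed-to-atlas Pearson
    correlation matrices (76 pain seeds by 116 AAL regions), tests each
    patient edge-wise against a normative control cohort with a label-shuffle
    permutation test and Benjamini-Hochberg false discovery rate correction,
    aggregates atypical edges across a patient cohort with recurrence
    thresholds, maps recurrent edges onto anatomical region groups to build a
    weighted graph with max-normalized degree-centrality hub scores, and
    relates edge strength to clinical pain outcomes. Ships a synthetic-data
    generator with known ground truth so the full pipeline is testable
    without neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, graphics, jsonlite, yaml, RNifti
Suggests: testthat (>= 3.0.0), igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'timeseries-io.R'
    'connectivity.R'
    'roi-tables.R'
    'simulate.R'
    'permutation.R'
    'aggregate.R'
    'hubs.R'
    'clinical.R'
    'nifti.R'
    'painConn-package.R'
    'pipeline.R'
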