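Package: lesiongraph
Title: Longitudinal Lesion Matching and Match-Graph Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking lesions between longitudinal 3D scans of
    patients with metastatic disease. Implements a registration-based
    automated lesion-matching pipeline (translation initialisation plus
    B-spline free-form deformation, physical-space lesion dilation,
    within-scan lesion clustering, and Munkres assignment maximising
    intersection volume), a bipartite match-graph data model with NEW and
    DISAPPEARED sentinel nodes, agreement metrics (precision, recall, F1,
    number of differences) for comparing match graphs from independent
    readers or automated methods, readers and writers for NIfTI label
    volumes and reader-workbook match tables, and a seeded synthetic
    phantom generator with ground-truth correspondence graphs so the full
    pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    igraph,
    jsonlite,
    Matrix,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils-geometry.R'
    'utils-interp.R'
    'labelvolume.R'
    'graph.R'
    'graph-json.R'
    'io-nifti.R'
    'io-table.R'
    'transforms.R'
    'registration.R'
    'components.R'
    'lesions.R'
    'morphology.R'
    'hungarian.R'
    'matching.R'
    'metrics.R'
    'synthetic.R'
    'cli.R'
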