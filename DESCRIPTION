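Package: neuroscrub
Title: De-Identification and Audited Sharing of Linked Neuroimaging Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless toolkit for preparing linked image/tabular human-subject
    datasets for sharing. Reads and writes Analyze 7.5 and NIfTI-1 headers at
    the byte level with per-field offsets and editable/protected flags, audits
    and scrubs free-text header fields, auto-detects image formats, converts
    between single-file and hdr/img containers, associatively matches image
    files to subject IDs in a demographic table, detects and removes
    identifier columns, generalizes quasi-identifiers, assigns collision-free
    random pseudonym IDs with round-trip validation, removes facial voxels via
    an external brain-extraction tool or a built-in intensity-based fallback
    with QC metrics and montage rendering, scans outputs for identifier
    leaks, and packages the de-identified dataset as an audited tar.gz.
    Includes a synthetic-data generator (head phantoms with ground-truth
    brain/face masks, demographic tables with planted identifiers) so the
    whole pipeline is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    igraph,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
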