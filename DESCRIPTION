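Package: editomekit
Title: A-to-I RNA Editing Detection, Differential Hyper-Editing, and
    Clinical Editing Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for calling adenosine-to-inosine (A-to-I) RNA editing
    sites from paired RNA/DNA per-site pileups, including two filter
    cascades (a matched-exome subtraction cascade and a de novo cascade
    with mapping-quality, SNP, read-position, Alu-conditional and
    uniqueness filters), a paired hyper-editing caller, an
    expression/editing z-score signature with survival stratification
    labels, single-hit limiting-dilution frequency estimation, small
    clinical quantifications (immunoreactive score, delta-delta-Ct,
    tumor volume, copy-number window correlation, RNA stability fits),
    and a synthetic-data generator that produces every input with known
    ground truth at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
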