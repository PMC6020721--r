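Package: qsm
Title: Quality Sequencing Minimum (QSM) Evaluation for Targeted NGS Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Declares, parses and evaluates Quality Sequencing Minimum (QSM)
    statements of the form CX_BY(P_Y)_MZ(P_Z) for next-generation sequencing
    quality assurance. Computes per-base depth of coverage, base-quality pass
    fractions and mapping-quality pass fractions from coordinate-sorted,
    indexed BAM files over BED test regions; flags regions falling below a
    declared QSM; aggregates flags across a sample cohort with a
    percent-of-samples review rule; and renders standardized QSM statements
    suitable for genetic test reports. Includes a synthetic SAM/BAM fixture
    generator with analytically known per-base expectations for validation,
    and command-line entry points for single-sample and cohort workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
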