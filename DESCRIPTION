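Package: constellatr
Title: Retrograde Lineage-Competency Mapping for Multi-Timepoint Single-Cell Chromatin Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping when lineage-specific chromatin accessibility is
    established across a developmental time course of single-nucleus ATAC-seq
    data. Late-stage cluster-enriched peak sets are scored retrogradely on
    earlier timepoints with background-matched deviation z-scores; right-skew
    of the per-cell score distribution calls each (tissue, timepoint) as
    diffuse or skewed and dates competency establishment; a combined distance
    over tissue score vectors and Robinson-Foulds dendrogram distances embeds
    (tissue, timepoint) nodes into a relatedness map; per-tissue regression of
    module scores on motif deviations and transcription-factor gene activities
    surfaces candidate lineage-priming factor pairs; and a cross-timepoint
    cell graph is built by projecting each timepoint's LSI basis onto its
    predecessor. A synthetic-atlas generator with planted lineage trees,
    establishment times and priming pairs makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    ape,
    igraph,
    GenomicRanges,
    IRanges,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
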