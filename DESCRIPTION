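Package: apabypass
Title: Alternative Last Exon Usage and Polyadenylation-Site Bypass from 3'-End Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies alternative 3'-end isoform usage from 3'-end sequencing
    and RNA-seq derived inputs. Parses transcript annotations and classifies each
    gene's 3'-end structure (single, tandem-UTR, alternative last exon, mixed),
    derives ALE-specific unique 3'UTRs, clusters 3'-seq read ends within a fixed
    window, and computes ALE usage, usage ratios, polyadenylation-site bypass
    scores and bypass/unbypassed ratios with two-way ANOVA significance calls.
    Computes psi (fractional distal polyadenylation-site usage) for two-site
    genes, detects neurally-restricted isoform shifts across a differentiation
    timecourse by k-means clustering, and performs sequence analyses around
    cleavage sites and cassette exons: polyadenylation-signal hexamer
    classification, nucleotide metaprofiles, position-weight-matrix scanning
    with a minimum fractional match score, and group-wise enrichment tests.
    Includes a simplified cassette-exon PSI stage with delta-PSI filtering and
    a synthetic-data generator that emulates motif-dependent pA-site bypass
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
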