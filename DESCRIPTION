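Package: rangercall
Title: Dual-Mode ChIP-Seq Peak Calling with Summit Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dual-mode peak caller for ChIP-seq experiments. Reads aligned
    short reads (BED, SAM, BAM, Bowtie or Eland), builds fragment coverage
    profiles by blind extension to the user-supplied shear size, detects broad
    enriched regions by Poisson thresholding with binomial (treatment versus
    control) or Poisson significance under genome-wide Benjamini-Hochberg FDR
    control, and resolves single-basepair summits inside each region with a
    summit-valley-alternator scan whose sensitivity is tuned by a delta factor.
    Includes region and resolution presets for broad histone-mark domains and
    punctate transcription-factor sites, chromosome-partitioned parallel
    execution, wiggle export, a command-line interface, and a semi-synthetic
    spike-in benchmark generator with recall, false-positive and inter-peak
    resolution metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    optparse,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    withr,
    IRanges,
    jsonlite
Config/testthat/edition: 3
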