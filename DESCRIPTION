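Package: tecurator
Type: Package
Title: Transposable Element Library Curation, Annotation and Benchmarking
Version: 0.1.0
Authors@R: person("Avery", "Fielding", email = "avery.fielding@example.org",
    role = c("aut", "cre"))
Description: Tools for curating transposable element (TE) consensus libraries
    and annotating TEs in genome assemblies without external aligner
    dependencies. Implements an iterative consensus-extension procedure
    (search genomic copies, extend their flanks, trim unsupported flank
    sequence, rebuild the consensus by majority rule), tandem-repeat triage
    of consensus sequences, greedy 80/80 library clustering, library-based
    genome annotation on an internal seeded local aligner, annotation
    defragmentation and overlap resolution, Kimura 2-parameter divergence
    summaries and repeat landscapes, a synthetic-genome generator with
    diverged, fragmented and nested TE insertions, and nucleotide-level
    benchmarking of annotations with the Matthews correlation coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
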