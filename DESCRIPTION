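Package: apascreen
Title: In-Silico Screening of CFIm/NUDT21-Responsive Alternative Polyadenylation Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for screening genes whose 3'UTR length responds
    to the CFIm subunit NUDT21 (CFIm25). Implements strand-aware 3'UTR isoform
    modelling from GTF annotation, positional scanning for poly(A)-signal
    hexamers (AAUAAA and variants) 10-60 nt upstream of cleavage ends and for
    CFIm UGUA elements within 200 nt of the proximal poly(A) signal,
    qPCR-style long/total transcript-ratio quantification via the 2^-ddCt
    method with an overexpression-up / knockdown-down responsiveness
    classifier, an in-silico 3'RACE amplicon predictor, and a seeded
    synthetic-genome and expression generator with per-criterion decoys so
    every stage is testable without external downloads. Small deterministic
    calculators for immunohistochemistry composite scores, xenograft tumor
    volume and wound closure are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
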