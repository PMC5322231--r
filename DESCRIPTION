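Package: sshdiff
Title: Differential Transcript Sets from Deep-Sequenced Suppression
    Subtractive Hybridisation Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for deep-sequenced suppression subtractive
    hybridisation (SSH) cDNA libraries. Provides a seeded, banded glocal
    aligner and tiered reference-guided consensus assembly with IUPAC
    ambiguity resolution, read trimming and best-hit read mapping with
    RPKM quantification, two-proportion tag-count tests with Storey
    q-value false discovery rate control, and sequential in-silico
    subtraction of forward/reverse library pairs into non-subtracted (nS),
    subtracted non-enriched (SnE) and subtracted enriched (SE) transcript
    sets.  A synthetic-data generator simulates four SSH-style read
    libraries with known differential structure and the contamination
    classes typical of SSH experiments (rare non-differential transcripts
    and abundant transcripts escaping subtraction), so the whole pipeline
    is testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
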