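Package: glyloopr
Title: Glycine-Loop Detection and Quality Profiling for Loricrin-Like Proteins
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing loricrin-like cornified-envelope proteins:
    detection of glycine loops under the x(y)n quasi-repeat grammar and
    Table-style loop profiling, assembly-gap (NNN/X) aware translation and
    sequence quality classification, amino-acid composition statistics
    (per-residue ANOVA, Welch's t-test, SVD-based PCA), a permutation-based
    scan for gene-conversion fragments between aligned paralogs, and a
    synthetic-sequence generator with ground truth so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
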