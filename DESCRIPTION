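Package: motifOrient
Title: Orientation and Arrangement Statistics for Promoter Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical toolkit for deciding whether the orientation of
    transcription-factor binding-site motifs in gene upstream (promoter)
    regions carries regulatory information. Provides IUPAC consensus motif
    catalog curation, non-overlapping motif scanning of TSS-anchored
    upstream intervals in both orientations, composition-corrected binomial
    orientation tests, positional entropy of motif locations, dinucleotide
    orientation-asymmetry profiles, gene co-expression set comparisons
    (Wilcoxon rank-sum with Cohen's d), randomized-motif control batteries,
    motif-pair order and arrangement-entropy tests with empirical nulls,
    and a synthetic-promoter world generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
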