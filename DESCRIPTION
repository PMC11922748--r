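Package: etymolex
Title: Etymology-Based Formality and Lexical Metrics for Speech Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies speech formality from interview transcripts through
    word etymology. Computes the proportions of content words (nouns, verbs,
    adjectives, adverbs) with exclusively Germanic or exclusively Old French
    origin against an etymology lexicon, together with Honore's statistic of
    lexical diversity and first-order (unigram) perplexity against a
    reference frequency table. Includes the sequential healthy-control
    anchored covariate adjustment used in clinical speech studies, the
    accompanying group-comparison statistics (one-way ANOVA with pairwise
    pooled t tests, Pearson correlation matrices, standardized multiple
    regression, Spearman clinical correlations, Bonferroni control), and a
    seeded synthetic-data generator producing lexicons, Zipfian frequency
    tables, transcripts and participant metadata with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
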