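---
title: "Measuring speech formality through word etymology: methods and design"
author: "etymolex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring speech formality through word etymology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etymolex)
```

## The measurement problem

English carries a historical split in its vocabulary: a core of
Germanic-origin words (descending from Old English, Old Norse and their
ancestors) and a large layer of words that entered via Old French after the
Norman conquest. Speakers lean on the Old-French layer when they feel a
conversation calls for formality — "inquire" rather than "ask", "intelligent"
rather than "smart". The proportion of a speaker's content words drawn from
each layer is therefore a candidate index of speech formality, of interest in
clinical populations (psychosis and its risk states) where communication and
role functioning are affected.

`etymolex` implements this measurement end to end: transcript preprocessing,
etymology classification, two complementary lexical metrics (Honoré's
statistic and unigram perplexity), a healthy-control-anchored covariate
adjustment, and the inferential layer used to compare cohorts. A seeded
synthetic-data generator provides full-pipeline test beds with known ground
truth, since real clinical transcripts are restricted.

## Preprocessing

Participant speech is isolated from speaker-labelled dialogue (unlabelled
files are treated as participant monologue so the tool works on plain text),
lowercased, stripped of punctuation, and lemmatized with a pluggable
tagger. Design choices that the conventions of the field leave open:

* **Apostrophes** are stripped inside words, so contractions collapse
  ("don't" becomes "dont"); a `split` option breaks them into separate
  tokens instead. Hyphens always split compounds, being punctuation.
* **Proper nouns** are mapped to OTHER and excluded from content words:
  names carry no register choice between synonyms.
* **The lemmatizer is a contract, not a dependency.** Any function mapping
  a token vector to (lemma, POS) rows can be plugged in; the bundled
  deterministic rule+lookup tagger keeps the test suite self-contained and
  reproducible. Which tagger produced the lemmas is incidental to the
  method, but results should only be compared across transcripts tagged the
  same way.
* **Fillers** ("um", "uh") pass through as ordinary tokens; no disfluency
  handling is attempted.

## Etymology classification

An `etymology_lexicon` maps each lemma to its set of origin-language labels,
either supplied directly or compiled from an edge list of
(word, relation type, origin language) triples as distributed by
collaborative etymology databases. Only ancestry-type relations count
("inherited from", "derived from", "borrowed from" by default); lateral
relations such as "cognate with" do not establish origin. Origins are used
exactly as listed — no transitive chain resolution is attempted inside the
package, so classification is deterministic relative to the shipped lexicon;
resolving chains (e.g. Middle English from Old French) is the lexicon
builder's job upstream.

Each content lemma falls into exactly one class: exclusively Germanic,
exclusively Old French, BOTH (mixed morphology, e.g. "talkative"), NEITHER
(e.g. "karaoke"), or UNKNOWN (absent from the lexicon; tallied separately so
coverage is auditable). The two reported proportions count only the
exclusive classes in their numerators, but the denominator is **all**
content tokens. This denominator convention is forced by the arithmetic of
published cohort tables, where the two proportions sum to roughly 0.89:
were mixed/other tokens excluded from the denominator, the two exclusive
proportions would sum to 1. Counting is token-level (running text), with a
`per_type` switch for type-level counting; the running-text reading matches
"proportion of these parts of speech".

The default label groupings are Germanic = {Old English, Proto-Germanic,
Proto-West Germanic, Old Norse, Middle English, Old High German, Middle
Dutch, Middle Low German} and Old French = {Old French, Anglo-Norman}; both
are configurable, and the two sets must be disjoint.

## Honoré's statistic

Lexical diversity is summarized by Honoré's statistic on the **whole**
lemmatized text (not the content subset):

$$R = \frac{100\,\log N}{1 - V_1/V}$$

with $N$ total tokens, $V$ distinct lemmas, $V_1$ hapax legomena. The
default logarithm is natural, following the statistic's original
definition; the base is a configuration knob because published applications
are not consistent about it, and reported cohort magnitudes in the clinical
speech literature (means in the several hundreds for half-hour interviews)
are only arithmetically reachable with the base-10 logarithm — with natural
log, $100\ln N$ alone exceeds 680 for any $N > 900$. Comparisons across
studies must therefore fix the base explicitly.

When every type is a hapax ($V_1 = V$) the statistic is undefined; the
package raises an explicit error rather than returning infinity, with an
opt-in $V_1 \to V - 0.5$ correction for short texts.

## Unigram perplexity

Each content lemma is scored by its unary probability $w_i$ (corpus count
over corpus total) in a reference frequency table. The transcript's mean
log probability $m = \frac{1}{n}\sum_i \log w_i$ is necessarily negative;
perplexity is reported with the standard sign convention
$\Pi = \exp(-m)$, so rarer vocabulary yields larger perplexity and
$\Pi = 1/w$ exactly when all tokens share probability $w$. Perplexity is
invariant to the log base (the base cancels); the mean log probability is
reported alongside in the chosen base. Out-of-vocabulary tokens are skipped
and counted by default; a floor policy scoring them at $1/\text{total}$ is
available. Both numbers depend on the reference corpus, so values are only
comparable against the same frequency table.

## HC-anchored covariate adjustment

Demographic covariates are handled sequentially in a fixed order — sex,
age, recruitment site, education, racial identity, maternal education (a
socioeconomic proxy), and IQ in the subset with scores. For each covariate
the association with each *etymology* feature is tested at the whole-dataset
level (pooled t/ANOVA for categorical, Spearman for continuous) at an
uncorrected gate of $\alpha = 0.05$; where any association is found, **all**
lexical features are adjusted for that covariate:

* categorical: per-category offsets equal to the healthy-control (HC)
  median difference from the reference category (the largest HC category —
  the reference choice cancels out of between-group contrasts);
* continuous: residuals from an ordinary least-squares line fitted on HC
  records only, re-centered at the HC feature mean so adjusted values stay
  on the original proportion scale.

Each step is fitted on the current (already adjusted) values, each
covariate is applied at most once, and every test, decision and fitted
model lands in an audit log. Small racial-identity categories (Black,
Other/multiracial) are merged before fitting so every category has HC
support. Antipsychotic use is tested within each clinical cohort for the
audit trail but is never an adjustment covariate: no HC takes
antipsychotics, so no HC-anchored model for it can exist. Covariates with
partial coverage (education, maternal education, IQ) are tested and
adjusted on the subset with values; other rows pass through unchanged.

Anchoring on HC means the healthy cohort defines "expected" covariate
structure, and clinical-cohort deviations from it are preserved rather than
regressed away — the property that makes between-group contrasts after
adjustment interpretable.

## Inferential layer

Group differences use one-way ANOVA followed by all pairwise
pooled-variance t tests ($df = n_1 + n_2 - 2$; Welch available by flag);
degrees of freedom always derive from the actual analytic Ns. Feature
inter-relations use a Pearson correlation matrix. Multiple regression of
each (unadjusted) etymology proportion on cohort, lexical and demographic
predictors reports standardized coefficients obtained by z-scoring the
outcome and every predictor column, dummy columns included (an
`outcome_only` alternative divides raw estimates by the outcome SD).
Clinical relevance uses Spearman correlations (midranks under ties) between
etymology proportions and functioning scores in the combined clinical
cohort, flagged against a Bonferroni level of $\alpha/k$ with $k = 20$ by
default. All p-values are two-sided. Analyses can be stratified by
recruitment site, in which case the adjustment is refitted within the site.

## The synthetic-data generator

The generator emulates the study conditions the package targets; its
defaults are fixed once and are not tuned per analysis:

* **Cohorts**: HC/CHR/ROP of 164/134/86 participants, the analytic sample
  sizes of the emulated study, with demographics (age, sex split, education,
  race composition, antipsychotic rates, functioning and symptom scores)
  following its demographic table.
* **Mixtures**: cohort Germanic/Old-French token mixtures 0.701/0.190,
  0.724/0.172 and 0.724/0.173, with between-participant logit-scale spread
  calibrated so measured SDs land near the published 0.025–0.038 band. A
  single latent normal per participant raises the Germanic logit while
  lowering the Old-French one, reproducing the strong negative coupling of
  the two proportions in speech.
* **Covariate effects** are additive on the mixture logit (female −0.03,
  −0.005/year of age, site offsets up to 0.03, −0.02/year of education,
  small race offsets, −0.003/IQ point, maternal education zero — it is
  tested but should never trigger adjustment). Effects are anchored at the
  HC cohort: HC mixture means stay on target while clinical cohorts carry
  covariate-mediated shifts, exactly the confounding the HC-anchored
  adjustment is designed to remove; recovering the target group contrast
  after adjustment is therefore a parameter-recovery test of the pipeline.
* **Vocabulary**: 5000 synthetic word forms with POS classes (45% function
  words), type-level origin classes, and Zipfian corpus counts
  (count ∝ rank$^{-s}$, $s = 1$); the etymology lexicon and frequency
  table are mutually consistent, with a slice of UNKNOWN words kept out of
  the lexicon so coverage accounting is exercised.
* **Transcripts**: ~1500 tokens (SD 300), the scale of a 30-minute
  open-ended interview; emitted both as token streams and as
  speaker-labelled dialogue text with templated punctuation so the
  preprocessing module is exercised; the two routes produce identical
  profiles, and the suite asserts it.
* **Clinical coupling**: role functioning is tied to the Old-French latent
  through a Gaussian copula targeting Spearman rho = 0.26 in the combined
  clinical cohort. The target refers to the *measured* proportion, which is
  attenuated relative to the latent by binomial counting noise and by
  covariate-shift variance; the copula strength is deflated by that
  predictable attenuation, computed from the generator's own parameters, so
  the observed coupling lands on target. Scores are integer-rounded and
  clamped to the 1–10 scale.

What the generator does **not** emulate: discourse structure, syntax,
semantic content, disfluencies, transcription errors, interviewer behaviour,
and any real lexicon's coverage gaps. Passing tests on synthetic cohorts
demonstrates that the estimators recover known ground truth under the
stated noise model — not that any clinical finding replicates on real
transcripts.

## Numerical choices and degenerate inputs

* Empty participant speech, zero content tokens, all-OOV transcripts and
  $V_1 = V$ all raise explicit errors rather than NaN/Inf.
* Constant covariates and rank-deficient regression designs error, naming
  the offending columns.
* Correlation cells with a constant feature are NA with a warning, not an
  error, so one degenerate feature does not kill a matrix.
* Frequency tables reject duplicates, negative and non-integer counts with
  line numbers; an optional `#total` header lets a truncated table carry
  its full-corpus total.
* Profile CSVs print proportions to 6 decimals, statistics to 4, and carry
  a version/content-hash header; all randomness flows from a single integer
  seed per generated dataset.

## Problem sizes used in validation

The shipped validation uses cohorts of 100 per group for power and recovery
runs (100 seeded replicates; ANOVA power for the HC-vs-clinical Germanic
contrast exceeds 80% at the calibrated effect size of roughly d = 0.64),
full-size 164/134/86 cohorts for the worked study reproduction (averaged
over five replicate cohorts in the acceptance script), and scaled-down
cohorts (tens of participants, 300–800 token transcripts) for unit and
property tests. These sizes were chosen to make the Monte Carlo error small
relative to the tolerances being asserted.

## Known limitations

* Classification fidelity is bounded by the lexicon: coverage gaps surface
  as UNKNOWN mass, and systematic lexicon bias (e.g. under-annotation of
  informal vocabulary) propagates into the proportions.
* The measured proportions carry binomial noise of roughly
  $\sqrt{p(1-p)/n}$ per transcript; short transcripts are noisy, which is
  why the generator refuses token budgets under 50.
* The sequential adjustment estimates each covariate model on HC records
  only; with small HC samples the fitted offsets and slopes add estimation
  noise to every adjusted value, visibly attenuating group contrasts in
  single replicates.
* Honoré's statistic depends on the log base and the metric is only
  comparable within a fixed tagger, lexicon and reference-corpus
  configuration.
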