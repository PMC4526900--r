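---
title: "Detecting HONcode conformity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting HONcode conformity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(honcheck)
```

## The problem

The HONcode is a code of conduct for health websites: eight procedural
principles (authority, complementarity, privacy, attribution,
justifiability, contact details, financial disclosure, advertising policy)
that a site must satisfy to earn certification. Manual certification is slow:
an expert reads a site page by page until a justification for each principle
is found, and records the extract and its page address. honcheck implements
an automated counterpart: it learns, from those labelled extracts, one binary
text classifier per principle, crawls a candidate site, classifies every page
(or every sentence) for every criterion, and aggregates the detections into
site-level verdicts with evidence locations. For detection purposes the
attribution principle splits into two separately detectable parts —
*reference* (sources are cited) and *date* (the page carries a dating
statement) — giving the nine criteria in `hon_criteria()`.

The package also implements the evaluation framework such a system needs:
a five-outcome taxonomy against expert gold assessments, its
"other"-page-tolerant precision/recall convention, and multi-rater agreement
statistics (pairwise percent agreement and Fleiss' kappa) for quantifying how
reliable the expert baseline itself is.

## The model

### Term weighting

Each classification unit (a whole page or one sentence) is tokenized and
converted to a sparse vector under one of two weighting schemes:

* **tfx** — raw term frequency times inverse document frequency,
  `w(t) = tf(t) · ln(N / D(t))`, where `N` is the number of training
  extracts and `D(t)` the number of extracts containing `t`;
* **tfc** — the same vector divided by its Euclidean norm (cosine
  normalization), which removes the effect of document length.

The logarithm is natural. The base is a free constant: it rescales every tfx
weight by the same factor and leaves tfc vectors unchanged, so it affects no
ranking. `N` and `D` are computed once from the training corpus and frozen;
documents seen at assessment time never update them, and their terms unseen
in training are dropped (a page consisting entirely of unseen terms scores
the class prior).

### Per-criterion naive Bayes

Each criterion gets a binary multinomial naive Bayes classifier trained
one-vs-rest: the positive class is the criterion's own extracts, the
negative class every other criterion's extracts — the only labelled text a
certification workflow produces. Because the features are real-valued
tf-idf weights rather than integer counts, the likelihoods are estimated
from fractional "counts": class `c`'s probability for term `t` is

  theta(c, t) = (alpha + S(c, t)) / (alpha · |V| + S(c, ·))

where `S(c, t)` sums the weight of `t` over the class's training vectors and
`V` is the training vocabulary. Prediction is ordinary naive Bayes over the
weighted features, `log P(c | v) ∝ log prior(c) + Σ_t v_t log theta(c, t)`,
and a unit is declared compliant when the posterior strictly exceeds the
decision threshold (default 0.5). A tie at the threshold is negative: when
conformity badges are published, a false claim of compliance is worse than a
missed one, so specificity is favoured over sensitivity.

The nine classifiers are applied independently ("any-of" classification):
one span of text may satisfy several criteria at once, and removing one
classifier never changes another's detections.

### Smoothing

The smoothing constant must be read on the scale of the features. A
cosine-normalized document carries total feature mass of order 1, so `alpha`
= 1 — the textbook Laplace choice for integer counts — dwarfs every
per-term class weight sum. The likelihoods then collapse toward the
smoothing normalizers `(alpha |V| + S(c, ·))`, which differ between the small
positive class and the eight-fold larger negative class; every term inherits
a systematic positive log-ratio bias, and any sufficiently long page sums
that bias past the threshold, so whole-document assessment degenerates to
"everything complies". We therefore default to `alpha = 0.01`, small
relative to typical document mass; the parameter stays configurable
(`train_detector(..., alpha = )`) and the brute-force-oracle tests exercise
several values.

### Classification unit

`unit = "document"` scores a whole page at once; `unit = "sentence"` scores
each sentence and detects a criterion if any sentence passes, reporting the
first passing sentence (0-based) as evidence. Under tfc weighting the two
units behave very differently on long pages: a single compliance statement
buried in hundreds of boilerplate sentences contributes almost nothing to
the normalized whole-page vector, so the page posterior stays near the
prior and the criterion is missed, while the same statement dominates its
own sentence vector and is found. The sentence unit buys recall at the cost
of more false positives (every background sentence is a fresh chance for
noise to cross the threshold) — both directions are visible in the
synthetic experiments below and match the behaviour reported for the
privacy and date criteria in the published evaluation.

## Preprocessing

* **Meaningful content.** "Meaningful content" of a page is
  under-specified; we strip `script`, `style`, `noscript`, `head` and HTML
  comments and keep all remaining visible text (including image `alt`
  attributes) in document order. Navigation and boilerplate are kept:
  separating signal from boilerplate is the classifier's job, and deleting
  it heuristically would be a second, unauditable classifier.
* **Sentences.** Rule-based: a boundary is a run of `.!?` followed by
  whitespace and an uppercase letter or digit; an unterminated trailing span
  is one sentence. Deterministic and dependency-light; joining the output
  with single spaces reproduces the whitespace-normalized input.
* **Tokens.** Maximal runs of Unicode letters, lowercased. Digits never
  enter a token and act exactly like whitespace, so any text tokenizes
  identically with its digit runs removed. This encodes a known blind spot:
  a dating statement written purely as numbers ("07/07/2012") produces no
  tokens and cannot be detected — keeping numbers would trade this silence
  for widespread noise, since digits rarely identify a criterion. A
  consequence of the separator rule is that mixed alphanumerics split into
  their letter runs ("covid19" tokenizes to "covid") rather than being
  dropped whole; we prefer this because it keeps the digit-invariance
  property exact.
* **Stemming and stop words.** An English Porter (1980) stemmer is built in
  (no stemming package ships with the environment) and verified against the
  algorithm's canonical example pairs; stemming and stop-word removal are
  both off by default and configurable, as the original system exposed both
  bag-of-words and bag-of-stems features.

## Crawling and site assessment

`crawl_site()` is breadth-first from the home page over internal links only
(same host live; inside the fixture directory offline), cycle-safe via
normalized URLs, with `max_pages = 500` and `max_depth = 10` defaults and an
explicit `truncated` flag when a limit stops expansion. Individual page
failures are recorded with machine-readable reasons rather than aborting the
site, so exclusions are auditable. `robots.txt` disallow rules for the
generic user agent are honoured in live mode. Unlike a human reviewer, who
stops reading once a principle is justified, `assess_site()` classifies
every retrieved page for every criterion and keeps every positive detection
in crawl order; a site complies with a criterion exactly when its evidence
list is non-empty. Adding pages to a site can therefore never retract a
verdict.

## Evaluation framework

Comparing an automated assessment with an expert's gold assessment for one
site and criterion yields one of five outcomes: TN, TP, FP ("noise"), FN
("silence"), or OTHER — the criterion was correctly detected but on a
different page than the expert designated. OTHER arises naturally because
the automated system reads the whole site while the expert stops at the
first justification. The precision/recall convention counts OTHER as a
positive detection:

* precision = (TP + OTHER) / (TP + FP + OTHER)
* recall = (TP + OTHER) / (TP + FN + OTHER)

with 0/0 defined as 0.00. When detections hit both the gold page and other
pages, TP takes precedence (the mixed case never occurs in the published
tables; this is our documented tie-break). Page identity is normalized-URL
equality — deterministic and auditable.

`hon_study_counts()` ships the published study's confusion counts (27
English health websites; nine criteria by two weighting schemes, plus the
privacy/date document-versus-sentence comparison) so the formulas can be
checked against every printed fraction. Two printed decimals contradict the
fractions printed beside them (contact-details tfc recall "0.39 (10/26)";
date document recall "0.24 (6/21)", whose counts also differ slightly
between the two source tables). The package reproduces the fractions and
flags, rather than matches, those two decimals.

### Inter-rater agreement

Percent agreement is pairwise: agreeing rater pairs over all item-pair
combinations (n·r(r−1)/2), the only reading under which the published values
are all multiples of 1/108 for 3 raters and 36 sites. Fleiss' kappa follows
the standard formulation; if a single category is ever used, chance
agreement is 1 and kappa is undefined (`NaN` with a prevalence warning).
Interpretation bands are the Landis–Koch cut points, consistent with every
published label. Kappa's prevalence paradox — high percent agreement with
kappa at or below zero when one category dominates — is reproducible with
the rating generator (below).

## The synthetic-data generator

No public corpus of certification extracts exists, so every stage is
testable against synthetic data with known ground truth:

* **Corpora.** Nine disjoint criterion vocabularies plus a background
  vocabulary of pseudo-words (pure letter strings, so nothing depends on
  English semantics and everything survives the tokenizer). Each extract
  draws each token from its criterion's vocabulary with probability
  `signal_strength`, else from the background. Defaults: 30 words per
  criterion vocabulary, 200 background words, 100 extracts per criterion of
  40 tokens — large enough for stable df statistics, small enough that a
  full train–assess–evaluate cycle runs in seconds. `sizing = "paper_like"`
  instead uses the published training-set sizes (872 extracts for
  justifiability up to 2861 for contact details; the unpublished seven are
  set to the midpoint).
* **Sites.** Each fixture site is an `index.html` linking content pages.
  Ground-truth compliance is sampled per criterion at `compliance_rate`
  (default 0.7, roughly the manual-positive fraction across the published
  table); each compliant criterion gets one distinct evidence location,
  either a dedicated page of criterion text (`evidence_mode = "page"`) or a
  single criterion sentence inserted into a 200-sentence background page
  (`evidence_mode = "sentence"`). The gold table records the evidence URL.
* **Ratings.** Per item a consensus category is drawn with probability
  `prevalence` for the dominant category; with probability `unanimity` all
  raters report it, otherwise one random rater dissents with the opposite
  category. The prevalence paradox is simulated with consensus prevalence 1
  and unanimity 0.91: the rare category then appears only as dissent,
  rating-level prevalence is ≈0.97, percent agreement stays above 90% and
  kappa is negative for essentially every seed. (If the rare category could
  also reach unanimity, the kappa sign at 36 items would be a coin flip and
  positive in expectation — that regime does not reproduce the published
  direction and is not the paradox.)

What passing the synthetic tests shows — and does not show. With disjoint
vocabularies at `signal_strength = 1`, end-to-end recovery (train on a
generated corpus, assess 30 generated sites, evaluate against gold) reaches
precision and recall ≥ 0.95 for every criterion; this validates the
plumbing — weighting, training, crawling, aggregation, outcome scoring — not
real-world accuracy. Real compliance language overlaps heavily across
criteria and with boilerplate; the published evaluation's recall of 0.2–0.8
per criterion, not our synthetic 1.0, is the realistic expectation. The
sentence-evidence experiment (`signal_strength = 0.9`, so background
vocabulary is part of training, as on real pages) shows the qualitative unit
effect: whole-document recall collapses on long pages while sentence recall
stays near 1.

## Numerical and degenerate-input choices

* Posteriors are computed in log space and converted with a logistic, so
  products of hundreds of small likelihoods cannot underflow.
* An empty or all-unseen unit scores exactly the class prior; with the
  default nine-way corpus the positive prior is ≈1/9, well under any sane
  threshold, so empty pages are negative.
* `idf` requires 1 ≤ D ≤ N and fails fast otherwise; a term found in every
  training document has idf 0 and is dropped from vectors.
* Tie at the decision threshold → negative (see above).
* 0/0 precision and recall → 0.00, matching the published convention.
* Criterion labels outside the nine-member set (including the unsplit
  "attribution") fail fast everywhere.
* Reports serialize sentence evidence as `url#s<index>` (0-based), one
  string field for both units; round-trips are lossless.

## Problem sizes

The test suite and the acceptance script use the generator defaults (900
training extracts, 12-page sites, 30-site batches, 200-sentence background
pages for the unit experiment, 36- and 200-item rating matrices). These
sizes give stable statistics while keeping a full run in tens of seconds;
all of them scale through `generator_config()`.

## Known limitations

* English only; one stemmer, one sentence splitter, no language detection.
* Purely numeric dating statements are invisible by construction.
* No JavaScript rendering; the crawler sees static HTML only.
* The negative class is other criteria's extracts, not general web text, so
  the detector's notion of "background" is whatever the corpus makes it.
* The published per-site classifier results cannot be reproduced exactly:
  neither the certification extract database nor the 27 evaluation sites
  are public. What is reproducible — and reproduced — is the evaluation
  arithmetic on the published counts, the analytic properties of the
  classifier, and the qualitative regime effects on synthetic data.
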