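# honcheck

Automated detection of HONcode conformity on health websites, with the
evaluation framework to judge it.

The HONcode (Health On the Net code of conduct) comprises eight procedural
principles — authority, complementarity, privacy, attribution,
justifiability, contact details, financial disclosure, advertising policy —
that a health website must satisfy for certification. Manual certification
is expert-driven and slow. `honcheck` implements the automated counterpart
for English sites, plus everything needed to evaluate it offline:

* **Detection.** One binary naive Bayes classifier per criterion (the
  attribution principle splits into *reference* and *date*, giving nine),
  trained one-vs-rest on labelled compliance extracts over tf-idf features
  (`tfc` cosine-normalized, or unnormalized `tfx`, with
  `f = ln(N/D)`), applied independently as "any-of" multi-label
  classification. Whole pages or single sentences can be the classification
  unit.
* **Site assessment.** A breadth-first crawler over internal links (live
  URL or offline HTML directory), text extraction, classification of every
  page for every criterion with no early stopping, and site-level verdicts
  with evidence locations (`url` or `url#s<sentence>`).
* **Evaluation.** The five-outcome taxonomy against expert gold assessments
  (TN, TP, FP, FN, and OTHER — detected on a different page than the expert
  designated), and its OTHER-tolerant convention
  `precision = (TP+OTHER)/(TP+FP+OTHER)`,
  `recall = (TP+OTHER)/(TP+FN+OTHER)`, with 0/0 printed as 0.00.
* **Agreement.** Pairwise percent agreement and Fleiss' kappa
  (`P_i = [Σ_j n_ij(n_ij−1)]/[r(r−1)]`, `κ = (P̄ − P̄_e)/(1 − P̄_e)`) with
  Landis–Koch interpretation bands, including the prevalence paradox
  regime.
* **Synthetic data.** Generators for labelled corpora, fixture websites
  with planted evidence and known gold verdicts, and rating matrices, so
  the full pipeline is testable without network access or the (non-public)
  certification extract database.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods for fitted objects, `autoplot()` for results.

## Worked example

Train a detector on a synthetic corpus, assess a generated site, and score a
batch against its gold assessments:

```r
library(honcheck)

cfg      <- generator_config(seed = 42)        # vocabularies drawn here
corpus   <- generate_corpus(cfg)               # 900 labelled extracts
detector <- train_detector(corpus, scheme = "tfc")
glance(detector)
#>   n_criteria n_train vocab_size scheme alpha threshold stem
#> 1          9     900        270 tfc     0.01       0.5 FALSE

batch <- generate_site_batch(cfg, file.path(tempdir(), "sites"), 5)
site  <- crawl_site(batch$dirs[1])
site
#> <hon_site> /tmp/.../sites/site01: 12 pages, 0 failures

tidy(assess_site(site, detector))
#>   site_id criterion            complies n_detections first_evidence
#> 1 site01  authority            FALSE               0 <NA>
#> 2 site01  complementarity      TRUE                1 page01.html
#> 3 site01  privacy              TRUE                1 page02.html
#> ...
```

Each row is one criterion's verdict for the site: `complies` is TRUE exactly
when at least one page (or sentence) passed that criterion's classifier, and
`first_evidence` names where. Evaluating the whole batch against its gold
table reproduces perfect recovery under the generator's fully separable
conditions (disjoint vocabularies, full signal strength):

```r
reports <- dplyr::bind_rows(lapply(batch$dirs, function(d)
  as_report(assess_site(crawl_site(d), detector))))

evaluate_sites(batch$gold, reports) |>
  tabulate_outcomes(label = "tfc") |>
  precision_recall()
#>   criterion            tn    tp    fn    fp other precision_label recall_label
#> 1 authority             1     4     0     0     0 1.00 (4/4)      1.00 (4/4)
#> 2 complementarity       1     4     0     0     0 1.00 (4/4)      1.00 (4/4)
#> ...
```

The published evaluation's confusion counts (27 real health websites) ship
with the package; feeding them through the same `precision_recall()`
reproduces the study's printed fractions:

```r
hon_study_counts("weighting") |>
  precision_recall() |>
  dplyr::filter(arm == "tfx") |>
  dplyr::select(criterion, precision_label, recall_label)
#>   criterion            precision_label recall_label
#> 1 authority            0.78 (7/9)      0.33 (7/21)
#> 2 complementarity      1.00 (3/3)      0.12 (3/26)
#> 3 privacy              1.00 (14/14)    0.58 (14/24)
#> 4 reference            0.75 (9/12)     0.56 (9/16)
#> 5 justifiability       0.19 (3/16)     0.50 (3/6)
#> 6 contact_details      1.00 (18/18)    0.69 (18/26)
#> 7 financial_disclosure 0.50 (1/2)      0.06 (1/17)
#> 8 advertising_policy   0.75 (3/4)      0.19 (3/16)
#> 9 date                 0.00 (0/0)      0.00 (0/21)
```

Here `1.00 (14/14)` reads: of the 14 sites where the system claimed privacy
compliance, all 14 were right (counting detections on a non-designated page
as right); `0.58 (14/24)` says it found 14 of the 24 sites the expert marked
compliant.

A command-line interface wraps the same functions
(`inst/cli/honcheck train | assess | evaluate | agreement | simulate`); see
`?hon_cli`.

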