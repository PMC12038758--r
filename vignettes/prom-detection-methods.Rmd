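---
title: "Methods: rule-based PROM detection, evaluation and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based PROM detection, evaluation and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promnlp)
```

## The problem

Patient-reported outcome measures (PROMs) — standardized questionnaires such
as the Oswestry Disability Index or the Bournemouth Questionnaires — are an
expected component of measurement-based musculoskeletal care, but their use
is typically documented only inside free-text visit notes. `promnlp` detects
that documentation with a deliberately transparent rule-based pipeline and
provides the surrounding corpus preparation, evaluation, baseline-model and
simulation machinery needed to validate it.

This vignette records the package's modelling choices, the parameters that
matter, and what the bundled synthetic data can and cannot demonstrate.

## Corpus preparation

Clinic visits can accumulate several notes (resident and attending
documentation of the same encounter). `prepare_corpus()` concatenates all
notes sharing a visit identifier — in service order, ties broken by note id,
since no clinically meaningful order exists between same-day co-signatures —
separated by an improbable sigil (`note_delimiter()`), giving a strict
1-to-1 visit/note relationship. Visit metadata (patient, visit, date,
facility, consult date, "visit *i* of *t*", days since previous / to next
visit) is rendered into a header terminated by a second, distinct sigil;
`parse_metadata_header()` inverts it losslessly. The header is plumbing, not
clinical text: the matcher never scans it.

**Visit categories.** Each visit receives exactly one of five exclusive
labels: `FIRST_CONSULT`, `FINAL_WITHIN_YEAR`, `PRE_GAP`, `POST_GAP`,
`INTERMEDIATE`. Two genuinely open points are resolved as configuration:

* *Gap definition.* A care gap is an inter-visit interval **strictly
  greater** than `gap_days` (default 60). "More than sixty days without
  care" reads most naturally as an exclusive bound; the threshold is an
  argument for sites that disagree.
* *Precedence.* A single-visit patient is simultaneously a first and a
  final visit; a visit can precede one gap and follow another. Exclusivity
  forces an order, and we use
  `FIRST_CONSULT > FINAL_WITHIN_YEAR > PRE_GAP > POST_GAP > INTERMEDIATE`:
  episode boundaries are the analytically privileged strata, and a
  between-two-gaps visit keeps the forward-looking label. One consequence
  worth knowing: the visit after a gap is labeled `POST_GAP` only when it
  is not itself final or pre-gap.

**Length statistics.** Note length is whitespace tokenization — the count of
maximal non-whitespace runs — because it is reproducible without any
language-specific tokenizer. Histograms pool notes above 2,000 tokens into
an overflow bin (`plot_token_lengths()`). Group comparisons use the
Kruskal-Wallis omnibus test (delegated to `stats::kruskal.test`) and Dunn's
rank-based z post hoc tests with Bonferroni correction over all
`k(k-1)/2` pairs; the Dunn statistic (with tie correction) is implemented
in-package since no installed library provides it.

**Annotation sampling.** `stratified_annotation_sample()` draws
approximately equal notes per category (within one, subject to
availability) and repeats the draw (`draws`, default 20) keeping the
candidate that covers the most distinct facilities — a cheap maximiser that
mirrors how annotation samples are balanced across sites. All sampling is
deterministic in `seed`.

## The lexicon

The catalog ships as YAML: 18 measures (a seed list of 15 plus 3 added
during refinement), each with a stable `prom_id`, canonical name, aliases,
uppercase abbreviations (length at least 2) and an `allow_fuzzy` flag. Only
the Oswestry Disability Index and the back and neck Bournemouth variants
are fixed points of the validation corpus; the remaining entries are widely
used spine/pain instruments and are expected to be aligned with a site's
local instrument list. All Numerical Rating Scale and Visual Analog Scale
surface forms are excluded by policy — unidimensional pain scores are not
multidimensional PROMs — and exclusion dominates: an excluded surface form
compiles to no pattern even if it also appears as an alias.

**Fuzzy policy.** `fuzz_policy()` defaults to one Damerau-Levenshtein edit
per token, applied only to tokens of five or more characters, with
abbreviations always exact. One edit covers the overwhelming majority of
real typos while keeping short tokens (where a single edit reaches many
common words) safe; the distance-1 check uses `utils::adist` for
substitution/insertion/deletion plus an explicit adjacent-transposition
test, which is exact at this radius.

## The matcher

`find_candidate_spans()` emits all alias, abbreviation and fuzzy matches,
then resolves overlaps **longest-match first**, ties by earliest start,
then catalog order, then match kind (alias before abbreviation before
fuzzy). Longest-first makes nested mentions ("Bournemouth Questionnaire"
inside "Neck Bournemouth Questionnaire") resolve to the most specific
measure. Offsets are 0-based, half-open, code-point based; every emitted
span satisfies `surface == substr(body, start + 1, end)`.

`detect_sections()` assigns every character to the section opened by the
nearest preceding header. Headers come from a configurable rule table:
by default a rule matches a line-initial phrase followed by a colon, but a
rule may set `require_colon: false` to open a section anywhere in running
text. That option exists to reproduce a documented and deliberately
tolerated behaviour of section-aware matching: in

> Goals of Care: Improve outcome measures, reduce ODI by 20%

the excluded "Goals of Care" section is immediately re-opened for inclusion
by the in-line "outcome measures" trigger, so the ODI span that follows is
kept. Text before any header forms an implicit include-disposition
preamble. `apply_section_filter()` keeps a span iff its governing section
has include disposition and records dropped spans as an audit trail.

## Evaluation

Three tasks, one convention each:

* **Strict boundary** — a pair matches iff start, end and PROM attribute
  are all equal; one-to-one by multiset intersection.
* **Soft boundary** — a pair matches iff ranges overlap by at least one
  character (configurable minimum) and attributes agree. Pairing is
  one-to-one and *maximises* matches: edges are seeded greedily by overlap
  length (ties by earliest gold start) and completed by augmenting paths,
  so the count provably equals the maximum bipartite matching — the greedy
  order alone can leave one short on adversarial overlap patterns, and the
  test suite checks optimality against exhaustive enumeration.
* **Note categorization** — the 2x2 confusion of note-level labels.

Metrics are percentages. When a denominator vanishes (no predicted or no
gold positives) the affected metric is reported as 0 with a structured
warning (`promnlp_zero_denominator`) rather than NA, so downstream
aggregation stays numeric but the degeneracy is visible. `f_from_pr()`
reports the harmonic mean to one decimal, the convention of printed
evaluation tables. AUC-ROC is the Mann-Whitney concordance probability with
ties counted half; it errors on single-class inputs and is deliberately not
produced for the rule-based model, whose hard 0/1 output makes ranking
meaningless.

**Inter-annotator agreement** is reported as the F-measure of a
soft-boundary, attribute-constrained pairing of the two annotators' spans —
an interpretation, flagged as such, chosen because span-level agreement
with boundary tolerance is what the annotation task actually requires;
note-level percent agreement is available by casting to labels and using
`note_confusion()`.

**Cross-validation.** `monte_carlo_cv()` repartitions the data each cycle
into 75/15/10 train/development/test (100 cycles at default);
`repeated_kfold_cv()` runs 10 repeats of 10 folds with rotating test fold,
the adjacent fold as development set and the remaining eight for training.
Stratified partitioning deals each label class round-robin after an
in-class shuffle, which bounds per-fold prevalence within one item of the
global rate (and fold sizes within one item per class). A master seed
expands to per-cycle seeds through a fixed affine counter map, so any run
is reproducible from `(scheme, seed)` alone. Cycle summaries default to the
normal-approximation interval `mean ± 1.96·sd/√n`; the percentile interval
is available (`ci_method = "percentile"`) since either is consistent with
common reporting.

## Baseline classifiers

The baselines are sized for corpora of hundreds of documents:

* **bow** — ridge-regularised logistic regression (glmnet) over 1-2 gram
  counts from a deterministic sorted vocabulary. The regularisation path is
  an explicit grid (`10^seq(2, -4)`, 30 points) because glmnet's automatic
  ridge path starts far too strong for sparse count features; the strength
  is chosen by development-set F at the 0.5 threshold.
* **cnn** — learned token embeddings (dimension 16), one 1-D convolution
  (24 filters, window 3, ReLU), max-pooling over positions and a logistic
  head, trained with Adam (15 epochs, batch 8, learning rate 0.01, inputs
  truncated at 80 tokens); the epoch snapshot with the best development F
  is kept. It is written in plain R with hand-derived gradients — at this
  scale a deep-learning framework would be ballast.
* **ensemble** — `w · bow + (1 − w) · cnn` with `w` tuned on the
  development set over `{0, 0.1, …, 1}`.

All fitted state (vocabularies included) derives from the train and
development portions only; the test suite asserts the fitted state is
byte-identical across varying test folds. The decision threshold is 0.5
unless overridden. Class imbalance is left alone: the intended workflow
balances the training pool by programmatic labeling
(`make_high_probability_set()`), which enriches matcher-flagged positives
before human review, not by reweighting.

## The synthetic corpus

`generate_corpus()` produces what the pipeline consumes — structure and
lexical surface — and nothing more. Defaults are the package's reference
conditions:

| parameter | default | rationale |
|---|---|---|
| `prom_prevalence` | 0.17 | realistic documented-PROM rate in chiropractic visit notes |
| `gap_probability` | 0.25 | fraction of patients with a >60-day care gap |
| `visit_geom_prob` | 0.13 | geometric visits-per-patient, median 5 |
| `typo_rate` | 0 | clean by default; raise to exercise fuzzy matching |
| `excluded_mention_rate` | 0.05 | decoy terms confined to excluded sections |
| `facility_count` | 20 | enough sites for the facility-maximising sampler |

Notes are assembled from SOAP-style skeletons with filler sentences that
are verified to contain nothing matchable (nor anything within one edit of
a fuzzy-eligible alias token). Positive notes receive 1-3 mentions —
alias, abbreviation, or typo'd alias (single-character substitution,
deletion or adjacent transposition on tokens of 5+ characters) — planted in
include sections with offsets recorded at construction, so gold spans are
correct by construction. Decoy notes place a catalog term only inside an
excluded section (medication list or abbreviation legend) with a false gold
label, which is what makes the section-filter ablation measurable: with
decoys only, the filtered pipeline must emit zero positives while the
unfiltered one flags every note. First-consult notes draw roughly twice the
filler of other visits, reproducing the right-shifted consult length
distribution. A patient drawn to have a care gap is guaranteed at least two
visits, and mid-history gap placement is preferred so the flanking visits
are not swallowed by first/final precedence. Corpora are bit-identical
functions of their configuration; the manifest records seed, config hash
and stratum counts.

What passing on this corpus does **not** show: robustness to real clinical
language (negation, telegraphic style, template noise, OCR artifacts),
to section headers outside the rule table, or to PROM surface forms missing
from the catalog. The generator exists to verify the machinery —
offset bookkeeping, filtering logic, evaluation algebra, CV accounting —
not to certify field performance.

## Problem sizes and numerical checks

The test suite exercises: soft-pairing optimality against exhaustive
enumeration on 1,000 random span-set pairs of up to 6 spans per side;
clean-corpus recall (span- and note-level, both must be 100%) and
prevalence recovery within a binomial 99% interval on a 2,000-note corpus
at 17% prevalence; the decoy ablation on ~300 notes; 100-cycle Monte Carlo
and stratified k-fold runs with the bag-of-words model on 500 notes;
classifier sanity on 400 separable notes (held-out F at least 95 for all
three architectures) and a label-shuffled null on 1,000 notes whose mean
cross-validated AUC must sit within 50±5; and AUC equivalence with an
all-pairs concordance oracle on 100 random instances up to n = 200. These
sizes keep the whole suite in the low minutes on a single core while
leaving each check statistically meaningful.

## Known limitations

* Detection only: the package never parses PROM scores or change values.
* No negation or assertion handling — a mention inside "declined to
  complete the ODI" counts as documentation, consistent with the
  span-matching task definition.
* The governing-header rule means an in-line include trigger re-opens an
  excluded section for the rest of it; this reproduces accepted behaviour
  of the approach and is a known, bounded source of false positives.
* The shipped catalog is a starting point; sites must curate it. Rare
  surface forms sparsely represented in small training pools are the main
  error source for the learned baselines, visible as occasional missed
  positives whose alias never occurred in training.
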