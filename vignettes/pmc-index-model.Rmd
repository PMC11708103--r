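---
title: "The PMC index model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PMC index model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmcindex)
```

## The model

The Policy Modeling Consistency (PMC) index scores the internal consistency
and content completeness of a single policy document against a fixed
measurement frame. The frame is a two-level indicator system: $M$ main
indicators $X_1, \dots, X_M$ (dimensions such as policy nature, time horizon,
release agency, function, guarantees, perspective, evaluation, receptors,
instrument, disclosure), each subdivided into $T(X_t)$ binary sub-indicators
$X_{tj} \in \{0, 1\}$ — 1 if the policy text exhibits the feature, 0
otherwise. All sub-indicators are equally weighted.

Each main indicator scores the fraction of its features the policy exhibits,

$$X_t = \frac{1}{T(X_t)} \sum_{j=1}^{T(X_t)} X_{tj} \in [0, 1],$$

and the PMC index is the sum over *all* main indicators,

$$\mathrm{PMC} = \sum_{t=1}^{M} X_t \in [0, M].$$

The complementary *depression index*, $M - \mathrm{PMC}$, measures the
policy's shortfall from a maximally consistent document; lower is better.
On the bundled 10-indicator system, policies are classified **Excellent**
for PMC in $[7, 10]$, **Good** in $[6, 7)$, **Acceptable** in $[5, 6)$ and
**Poor** below 5, and ranked by descending index.

A main indicator declared without sub-indicators (the bundled system's
`X10`, policy disclosure) is treated as carrying one implicit binary
variable: `sub_counts()` reports 0 declared subs, but the score matrix
carries an `X10` column and the indicator contributes a 0/1 score to the
index. This is the only reading under which the published per-policy scores,
the index values and the detailed-scoring averages are mutually consistent.

The bundled system has 44 sub-indicators across its 10 mains (counts 4, 3,
3, 12, 8, 2, 4, 4, 4, 0). Published summaries of the same system elsewhere
state 40; enumerating the variable table yields 44, and the bundled schema
follows the enumeration.

## Numerical conventions

**Rounding.** Scores are rounded *half-up* at 2 decimals — decimal, not
binary-float, semantics — at two stages: each main-indicator score, and the
summed index. Base R's `round()` (round-half-even) is wrong here: $5/8 =
0.625$ must print as 0.63, as the published score tables do, not 0.62.
`round_half_up()` guards the half-way comparison with a $10^{-9}$ epsilon so
ratios like $5/12$ that are not exactly representable in binary still round
on the correct side. Both stages can be disabled (`round = FALSE`) for
diagnostics; the monotonicity property (flipping any coding 0→1 never
decreases the index) is stated and tested on the unrounded index, since
2-decimal rounding alone can mask a strictly positive increment.

**Level boundaries.** The four class intervals partition $[0, 10]$ with
boundaries belonging to the higher class ($[7,10]$, $[6,7)$, $[5,6)$,
$[0,5)$). No published index value falls on a boundary, so the half-open
convention is a documented choice rather than an inferable fact.

**Ranking ties.** `rank_policies()` defaults to competition ranking (rank =
1 + number of strictly greater values; pattern 1-2-2-4), the usual
convention for published league tables. The bundled study, however, prints a
strict 1..13 ordering even though two policies (P6 and P10) have *identical*
indices — 5.79 printed, and equal even before rounding — so its tie was
broken by table position. `evaluate_scores()` and `evaluate_policies()`
therefore default to `rank_ties = "first"` (ordinal, position tie-break),
which reproduces the published ranks exactly; pass `"competition"` for the
shared-rank convention. No imputation is ever performed: a missing
main-indicator cell is an error.

**Summation bound.** The index sums all $M$ main indicators including the
sub-less disclosure indicator; every published index value equals the
10-column row sum of the published score table, which settles the point.

## The PMC surface and summary series

The *PMC surface* visualizes one policy's strengths and depressions: the
nine sub-scored main indicators are arranged row-major into a $3 \times 3$
matrix $(X_1 X_2 X_3; X_4 X_5 X_6; X_7 X_8 X_9)$, the disclosure indicator
being dropped for squareness (it scores 1 for every bundled policy, so no
information is lost there). `build_surface()` returns the exact grid — the
stored artifact — and `plot_surface()` renders it with a fixed $[0,1]$ fill
range so surfaces of different policies are directly comparable; the
rendering is presentation only.

`radar_series()` averages each main indicator over whatever policies the
score table contains. The bundled study's radar basis is ambiguous (its
13th policy has a published index but no published main-score row), so the
operation is deliberately defined over the table it receives — with the
bundled table that is the 12 decomposed policies. `timeline()` counts
releases per calendar year, zero-filled across the observed span.

## Text mining

The term-statistics front end replaces the proprietary content-mining
application used in this literature with a documented, deterministic
equivalent: it makes no claim of reproducing that application's output
node-for-node, since its stopword list, segmentation dictionary and
frequency thresholds were never published.

Choices: terms are Unicode-NFC normalized and lower-cased, with no
stemming; the segmenter is pluggable (`"whitespace"` default, a
`"character"` fallback for unsegmented CJK text, or any user function, e.g.
a dictionary-based Chinese segmenter), because segmentation is the one
genuinely unspecifiable stage; tokens shorter than `min_chars = 2`
characters are dropped as noise; `top_terms()` breaks count ties
lexicographically so results are total-ordered and `top_terms(n)` is always
a prefix of `top_terms(n + 1)`. Co-occurrence defaults to whole-document
units — an edge weights the number of documents containing both terms,
matching the coarse policy-text networks of this literature — with a
sliding token window available behind `window = <integer>`; weights are
symmetric and self-loops excluded by construction.

## The synthetic generator

The generators make every stage testable without the original (Chinese)
policy corpus. They emulate exactly the statistical structure the analysis
assumes and nothing more:

* `gen_score_matrix()` draws each binary variable independently as
  Bernoulli($p_j$). The natural choice of $p_j$ for study-like data is the
  bundled detailed-scoring averages (`load_fixture("table6")$score`), which
  are the observed per-variable rates; the generic default is $p = 0.5$.
  Independence across variables is an idealization — real codings are
  correlated within a policy — so passing recovery tests shows estimator
  correctness, not realism of inter-indicator structure.
* `gen_corpus()` draws `doc_length = 200` tokens per document from a fixed
  relative-frequency profile (default: an emergency-policy-like vocabulary
  of 19 terms with weights descending 20 to 2). Token order is exchangeable;
  no grammar, collocation or document-length variation is modeled, so
  corpus tests validate counting and ranking machinery only.
* `gen_policy_meta()` produces synthetic metadata (uniform release dates
  over 2003–2023, the study's observation window; agencies from a small
  pool) for exercising the timeline and agency-coding paths.

All generators are reproducible under `seed` and leave the global RNG state
untouched. Parameter recovery is asserted at $n = 2000$ policies within the
3-sigma binomial bound $3\sqrt{p_j(1-p_j)/n}$, and at $n = 5000$ within an
absolute 0.02 — sizes at which those bounds are tight enough to catch an
off-by-one in the scoring denominators while the full suite still runs in
seconds.

`gen_table4_consistent_matrix()` is different in kind: a *deterministic*
reconstruction of a binary coding matrix consistent with the bundled
per-policy score table. Printed 2-decimal scores constrain only the count
$k$ of positive codings per main indicator ($k$ is recovered by exact
decimal search over $0..T$), not which sub-indicators carry them; the
fixture sets the first $k$ sub-indicators of each block, except the
release-agency block, where sub-indicators matching the policy's actual
issuing agencies are preferred before padding (the historical Ministry of
Health fills the health-authority slot for the two pre-2013 joint
releases). The result self-validates against the bundled tables at build
time. Note the published detailed-scoring averages for the agency block
cannot all be reconciled with the published per-policy scores and metadata
simultaneously (one joint-release policy prints an agency score implying a
single issuer); the reconstruction treats the per-policy counts as
authoritative, because the index itself is computed from them.

## Problem sizes and determinism

The test suite exercises: the full 12/13-policy bundled study; random
matrices up to 10,000 policies for the conservation property
(PMC + depression = 10); 25–40 random small schemas (≤ 4 mains, ≤ 5 subs)
against an independent exact-decimal oracle implemented in integer
hundredths; and Bernoulli recovery at $n$ = 2000 and 5000. All randomized
tests run under fixed seeds via `withr::with_seed()`. Pipeline CSV output
uses UTF-8, comma delimiters, `.` decimals and fixed 2-decimal score
formatting, so repeated runs on identical inputs are byte-identical.

## Known limitations

* The model evaluates policy *texts* only: completeness and internal
  consistency, not enforcement, uptake or outcomes.
* Equal weighting of sub-indicators is part of the model definition here;
  entropy-weighted or otherwise weighted composite variants are out of
  scope, as is statistical inference on the scores (no tests, no intervals).
* The 13th bundled policy carries only its published index — its
  main-indicator decomposition was never published — so matrix-level
  operations cover the 12 decomposed policies.
* The text-mining module reproduces the *kind* of evidence (frequency
  tables, co-occurrence networks) used to motivate indicator systems, not
  any particular published figure.
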