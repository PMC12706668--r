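---
title: "Requirement prioritization with kanoqfd: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Requirement prioritization with kanoqfd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kanoqfd)
```

This vignette is the package's own account of the three methods it chains
together, the choices made where the design was genuinely open, and what the
bundled tests do and do not establish.

## 1. The Kano stage

### Model and assumptions

A Kano questionnaire asks each requirement twice — functional form ("the
feature is present") and dysfunctional form ("the feature is absent") — on
the five-level scale Dislike (1), Live-with (2), Neutral (3), Must-be (4),
Like (5). The pair is mapped by the 5 × 5 evaluation table to one of six
categories (A, O, M, I, R, Q). The table is a pure lookup, total over all
25 pairs; the default is the standard table and a custom one may be
supplied (all 25 cells must then be defined).

Aggregation assumes respondents are exchangeable: per requirement, the
category counts are sufficient, and all outputs are invariant to respondent
order (tested by permutation). The modal category classifies a requirement;
the Better–Worse coefficients are

$$SI = \frac{A+O}{A+O+M+I}, \qquad DSI = -\frac{O+M}{A+O+M+I}.$$

R and Q answers are excluded from the denominator — the defining formulas
contain only A, O, M, I — but their fractions are still reported. A
requirement whose answers are *all* R/Q has undefined coefficients; the
summary flags it with `NA` rather than failing, and the low-level
`kano_better_worse()` raises a degenerate-input error. The algebraic
identity $SI - |DSI| = (A-M)/(A+O+M+I)$ is used as a property test.

### Tunable parameters

* **Tie-break ordering** (`tie_break`, default `M > O > A > I > R > Q`).
  Frequency ties between categories are rare but must be deterministic; the
  default puts safety-critical interpretation first (a requirement that is
  as often Must-be as Attractive is safer treated as Must-be). Fully
  configurable.
* **Exclusion set** (`exclude`, default `"R"`). Reverse requirements are
  always poor candidates for further investment; Indifferent ones can
  optionally be dropped too (`c("R", "I")`).
* **Q-rate guard** (`q_warn`, default 0.1). A Questionable fraction above
  10 % usually signals confusing question wording; the summary warns but
  never alters results.
* Respondents with an incomplete pair contribute nothing for that
  requirement and trigger a warning — a visible, conservative handling of
  item non-response.

Fractions are kept at full precision internally; rounding (4 decimals in
printed summaries, percent strings) happens only at the report layer.

### Questionnaire QC

`cronbach_alpha()` uses sample ($n-1$) variances — the duplicated-item
($\alpha = 1$) and zero-total-variance (undefined) cases are
convention-independent. `kmo_bartlett()` computes the KMO sampling-adequacy
measure from squared correlations versus squared anti-image partial
correlations (via the inverse correlation matrix) and Bartlett's statistic
$\chi^2 = -(n-1-(2k+5)/6)\ln|R|$ on $k(k-1)/2$ degrees of freedom. A
singular correlation matrix drops KMO with a warning rather than failing,
since Bartlett's statistic is still informative. Both are cross-checked in
the tests against brute-force recomputations (explicit variance summation;
partial correlations from regression residuals).

## 2. The AHP stage

### Model and assumptions

Requirements retained from the Kano stage are arranged in a three-level
hierarchy (goal, criteria, indicators), each node carrying a positive
reciprocal pairwise-comparison matrix on the Saaty 1–9 scale. The model
assumes a single consensus matrix per node (group aggregation of multiple
experts is out of scope) and ratio-scale judgements: for a perfectly
consistent matrix $a_{ij} = w_i / w_j$ and every weighting method recovers
$w$ exactly.

### Weighting methods — an open choice

Three standard prioritization methods are implemented:

* **eigenvector** (default): principal right eigenvector by power
  iteration, tolerance $10^{-12}$ on the normalized iterate, at most
  10,000 iterations, uniform start. The classical choice, and the one used
  by the package's default interfaces.
* **geometric**: normalized row geometric means (log least squares).
* **colsum**: normalize columns to sum 1, average rows — the "sum-product"
  approximation ubiquitous in applied AHP work and in the spreadsheet/SPSS
  toolchains of many published studies.

The three agree to $10^{-10}$ on consistent matrices (property-tested) and
within 0.01 per component on near-consistent ones (CR < 0.1). They differ
in the third decimal on genuinely inconsistent matrices. The bundled case
study's published indicator weights for its one inconsistent (6 × 6)
matrix are reproduced to ~$10^{-5}$ by **colsum** — and only approximately
(third decimal) by the eigenvector — so `replicate_study()` defaults to
colsum, which is evidently the method that produced those numbers, while
the package default remains the eigenvector.

### Consistency

$CI = (\lambda_{max} - n)/(n - 1)$ and $CR = CI/RI$, accepted when
$CR < 0.1$. $\lambda_{max}$ is the Rayleigh quotient
$\tfrac1n \sum_i (A w)_i / w_i$, which is $\ge n$ for any exactly
reciprocal matrix and any positive $w$; matrices transcribed at 3-decimal
precision can undershoot by the rounding error, so small undershoots clamp
$CI$ to 0 and only clearly impossible values are rejected. $n = 2$ (and
any $RI = 0$) defines $CR = 0$. The default RI table uses 0.52, 0.89,
1.12, 1.26 for $n = 3..6$ — the values of the case study's conformance
table — extended with the standard Saaty values up to $n = 10$, and is
fully overridable; a missing order is a configuration error, not a silent
fallback.

### Synthesis

Comprehensive weight = criterion weight × local weight; they sum to 1
whenever each layer's weights do (conservation is tested). Every matrix
must pass the CR gate unless `force = TRUE`, which downgrades the failure
to a warning. Ranks are descending; exact ties break by ascending
indicator label. The case study contains one exact tie (two identical rows
in the emotional-needs matrix make A1 and A3 interchangeable); the
published table orders them A3 before A1, the package's deterministic rule
orders A1 first — the diff tables report the tied pair as occupying the
same two positions.

### Matrix input precision

Published matrices often print reciprocals at 3 decimals (0.333, 0.111).
`pairwise_matrix()` checks reciprocity at a configurable tolerance
(default $10^{-6}$; the bundled hierarchy file sets $5 \times 10^{-3}$ to
accept its verbatim entries). An upper-triangle-only matrix is completed
by exact reciprocals. The bundled emotional-needs matrix stores exact 1/3
(its published weights, 0.42857 = 3/7, are only reachable from exact
fractions), while the functional-needs matrix keeps its printed 3-decimal
entries (its published weights *and* consistency index match the verbatim
matrix, not the back-derived exact fractions).

## 3. The QFD stage

The House of Quality body is a needs × features grid of symbols
● / ◎ / △ / blank mapped to 5 / 3 / 1 / 0 by default (ASCII aliases
S / M / W are accepted; a 1-3-9 dialect is one argument away). Absolute
weights $W_j = \sum_i W_i P_{ij}$ are linear in the need weights, so
relative weights $W_k = W_j / \sum_j W_j$ are invariant to uniform
rescaling — both properties are tested, along with strict monotonicity in
any single relationship strength and a brute-force double-loop oracle.
Percentages are half-up rounded to 2 decimals at the report layer only
(banker's rounding would disagree with published percentage rows at exact
boundaries).

The candidate feature list is consolidated from the need → feature mapping
by first occurrence; a need missing from the weight table is a linkage
error. The feature–feature "roof" is not modelled: no correlation data
exist in the bundled study, and nothing downstream consumes it.

One source inconsistency shapes the bundled data: the case study's printed
symbol grid does not regenerate its printed absolute weights (the grid as
printed is internally inconsistent — its own header even lists the weight
column among the features). The package therefore ships the printed
absolute-weight vector as the authoritative Develop-stage input, keeps the
symbol grid as documentation (it still parses and runs), and validates the
$W_j$ computation by the summation oracle on seeded random instances
instead.

## 4. The synthetic-data generators

The generators produce inputs with exactly the statistical structure each
stage assumes, under a single seeded RNG whose state never leaks into the
caller's session:

* **Kano panels**: per requirement, categories are drawn i.i.d. from a
  target probability vector, then an answer pair uniformly among the
  evaluation-table cells of that category. They emulate category mixtures
  like the case study's; they do *not* model respondent demographics,
  correlated answering styles, acquiescence bias or non-response patterns
  — so passing recovery tests shows correctness of the aggregation
  arithmetic, not robustness to messy field data.
* **Pairwise matrices**: $a_{ij} = (w_i/w_j)e^{\varepsilon_{ij}}$ with
  log-normal noise, reciprocal by construction; optional snapping rounds
  in log space to the nearest 1–9 scale value, preserving reciprocity.
  At $\sigma = 0$ weights are recovered to $10^{-8}$ and $CR = 0$; mean CR
  increases with $\sigma$ (Monte-Carlo-tested with 200 seeds per level at
  $n = 6$).
* **HOQ grids**: Bernoulli sparsity at a requested density with a
  guaranteed nonzero per need, strengths drawn from the symbol scale's
  image, need weights from a flat Dirichlet.

## 5. Numerical choices and degenerate inputs

* Power iteration: tolerance $10^{-12}$, max 10,000 iterations,
  non-convergence is an error (positive matrices converge by
  Perron–Frobenius; the cap guards malformed input).
* Fractions sum to 1 within $10^{-9}$; weight conservation asserted at
  $10^{-9}$; oracle equivalences at $10^{-12}$.
* Empty response sets, mixed requirement ids, non-square or non-reciprocal
  matrices, unknown relationship symbols (reported with row and column),
  all-zero HOQ columns, and missing RI orders are explicit errors; all-R/Q
  requirements and singular correlation matrices degrade gracefully
  (NA + flag/warning) because they occur in legitimate data.

## 6. The bundled case study and its known inconsistencies

The case study ships as plain-text fixtures. Raw respondent-level answers
were never published, so the response table is a **synthetic
reconstruction** from the published category percentages (denominators 32,
or 17 for the three Reverse-dominated requirements — the percentages
themselves imply those denominators); it reproduces the published
fractions, classifications and coefficients. Three internal
inconsistencies of the published tables are preserved and surfaced rather
than silently corrected:

1. The published SI/DSI columns are transposed relative to the defining
   formulas (the printed "SI" equals $|DSI|$). Engines follow the
   formulas; fixtures store the printed columns verbatim.
2. One requirement's printed classification ("M") contradicts its own
   printed fractions and SI/DSI (both consistent with "O"). The engine
   necessarily reports the modal category; the replication diff shows the
   single mismatch.
3. One printed comprehensive weight is not the product of its printed
   factors under any weighting method (off by ~5 × 10⁻⁴ at report
   precision).

## 7. Test problem sizes

The suite runs entirely on in-code fixtures and generators: 200-seed
Monte-Carlo comparisons for consistency-vs-noise, 100 seeded HOQ instances
for the summation oracle, 1,000 category panels for coefficient range and
identity checks, and a single 10,000-respondent panel for modal-category
recovery — sizes chosen so each statistical claim is comfortably separated
from its null while the whole suite stays desk-scale.

## 8. Limitations

* Single-matrix AHP only: no group aggregation, fuzzy variants, or ANP
  dependence structures.
* The QFD stage stops at feature ranking: no roof correlations,
  competitive benchmarking, target values, or multi-phase cascades.
* The generators' independence assumptions (see §4) mean synthetic
  validation bounds arithmetic correctness, not survey-quality issues.
* Kano category assignment uses the plain modal rule; continuous/fuzzy
  Kano refinements are out of scope.
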