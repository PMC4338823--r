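---
title: "Methods: positional-probability scoring of A-to-I editing sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positional-probability scoring of A-to-I editing sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airliner)
```

## The problem

Adenosine-to-inosine (A-to-I) editing is the most common post-transcriptional
modification in human transcripts: ADAR enzymes deaminate adenosines on
double-stranded RNA, and the resulting inosine is read as guanosine. The
overwhelming majority of catalogued sites sit inside Alu and other repeats,
where inverted repeat pairs form long duplexes. Outside repeats the signal is
much weaker, catalogues are sparser, and prediction is correspondingly harder.
This package implements a predictor for exactly that territory: given a
window of sequence centered on an adenosine in a non-repetitive region, it
returns the probability that the adenosine is edited.

## The model

Let `s` be a window of `2r + 1` nucleotides whose central base is an
adenosine (default `r = 10`, a 21-nt window). From a set of windows around
known edited sites we estimate `P(j, i)`, the probability of nucleotide `j`
at window position `i`; from windows around un-edited (random) adenosines we
estimate `P'(j, i)` the same way. The editing probability of a window is
modelled by logistic regression on the per-position lookups:

$$
\log \frac{P(s)}{1 - P(s)} \;=\; \beta_0
  + \sum_{i=1}^{2r+1} \beta_i \, P(s[i], i)
  - \sum_{i=1}^{2r+1} \beta'_i \, P'(s[i], i).
$$

A window is called edited when the predicted probability strictly exceeds
0.5 (`classify()`); the inequality is strict, so a probability of exactly
0.5 is a negative call.

Positions are treated as independent — there are no dinucleotide or
higher-order context features. This mirrors the structure of the estimated
profiles and keeps the feature map a pure table lookup (`featurize()`).

### Parameterization and sign of the second block

The minus sign in front of the `P'` block is a parameterization, not a
constraint: internally the `P'` features are negated and the fit is fully
unconstrained, so `beta_prime` may take either sign. Constraining
`beta_prime >= 0` would encode an assumption the model does not need.

### Why the central position stays in the sums

The sums run over all `2r + 1` positions, including the central adenosine.
Since every training window has A at the center, the central `P` feature is
(near-)constant and collinear with the intercept. We keep it — the model is
then exactly the displayed equation — and absorb the collinearity with the
ridge penalty rather than dropping the column.

### Smoothing

Profile cells are Laplace-smoothed: `(count + alpha) / (n + 4 alpha)` with
`alpha = 1` by default. With `alpha = 0` a nucleotide never seen at a
position gets probability 0, and such a lookup would contribute a degenerate
constant-zero feature; smoothing keeps all features strictly inside (0, 1).
`alpha` is exposed everywhere (`build_profile()`, `airliner()`) and `alpha =
0` is fully supported — the profile-recovery tests use it because the raw
maximum-likelihood estimate is exactly unbiased for the generating
distribution.

### Fitting

`ridge_logistic()` minimizes the penalized negative binomial log-likelihood

$$
-\sum_k \big( y_k \eta_k - \log(1 + e^{\eta_k}) \big)
  + \frac{\lambda}{2} \lVert (\beta, \beta') \rVert_2^2,
$$

with the intercept unpenalized, by damped Newton iterations started at zero:
the fit is deterministic, with no random initialization. Convergence is
declared when the gradient max-norm drops below `1e-8`, with a 500-iteration
cap. The default `lambda = 1e-3` is small enough to leave coefficients on
well-conditioned data essentially unshrunk, and large enough to keep the
optimum finite on separable data (with `lambda = 0` and separable classes
the likelihood has no maximizer; the fit then warns and returns the
iteration-cap solution). The fit metadata (`fit_info`) records iterations,
final gradient norm and the convergence flag. The test suite cross-checks
the Newton solution against an independent quasi-Newton minimization of the
same objective and against the closed-form intercept-only solution
`qlogis(prevalence)`.

### The 4-nt variant

A narrower model using only 4 nt of flank on each side is the same code
path with `radius = 4`; the radius is a parameter throughout, not a second
model.

## Building the training territory

### Edited regions

Site catalogues are segmented into *edited regions* (ERs) with a gap
threshold `delta`: walking the sorted sites of a (chromosome, strand) group
left to right, the next site joins the current region while its distance
from the previous site is at most `delta`, and a larger gap starts a new
region. `compute_breakpoint_delta()` estimates `delta` as the weighted
average distance between consecutive sites — the pooled mean of all
consecutive-site gaps, equivalently the per-group mean gaps weighted by gap
counts. Groups with a single site contribute no gaps. On the full human
catalogue this style of estimate is on the order of 6 kb; on synthetic data
it sits between the planted within-cluster and between-cluster gap scales,
which is all the segmentation needs.

Two choices here were genuinely open:

* **Strand handling.** Segmentation is per (chromosome, strand), because
  ERs are reported separately by strand downstream; a `stranded = FALSE`
  flag allows strand-agnostic grouping for sensitivity analysis.
* **Span definition.** An ER spans from its first to its last member site
  with no flank padding, and sequence extraction for motif work takes
  exactly that span.

ERs overlapping any repeat interval by at least one base are flagged
repetitive (`classify_repetitive()`, half-open BED intervals); training
regions for motif discovery are the non-repetitive ERs of 2,000–6,000 nt
with at least 10 sites (`filter_training_ers()`). Sites coinciding with
known SNPs are removed first (`filter_snp_sites()`) — an A/G polymorphism
is indistinguishable from an editing call in sequence data.

### Windows

`extract_window()` returns the `(2r + 1)`-nt slice around a site,
reverse-complemented for reverse-strand sites so the central base is always
the edited adenosine in window orientation. Sites are stored on
forward-strand coordinates (BED/VCF practice); orientation is applied only
at extraction. Windows containing `N` or any other ambiguity code are
rejected with a distinct error class — the profiles are defined over four
symbols only — and `extract_windows(skip_invalid = TRUE)` lets catalogue
processing skip them. How reverse-strand sites should be oriented is not
externally fixed; the reverse-complement convention is this package's
decision, checked in the tests against a character-by-character oracle.

## Evaluation

`kfold_cross_validate()` uses stratified folds from a seeded shuffle
(default `k = 10`, `seed = 42`). The positional profiles are estimated
**inside** each training split: held-out windows never contribute to the
matrices they are scored against. The naive variant that estimates profiles
once from all data is available as `profile_scope = "all"` for studying the
leakage, and a test asserts the two variants genuinely differ. "Mean error"
is the mean over folds of the misclassification rate at the 0.5 threshold.
ROC curves are computed from the pooled out-of-fold scores; per-fold AUCs
and their mean are reported alongside, since either convention is defensible
and they answer slightly different questions.

`roc_auc()` sweeps all distinct score values, grouping tied scores into a
single threshold step, so the curve is deterministic with no intra-tie
ordering; the trapezoid area then equals the Mann–Whitney concordance
probability with half credit for ties, which the tests verify exactly.

`compare_scorers()` implements the comparison protocol against a
multiplicative per-neighbor baseline (`multiplicative_scorer()`): percent
score = base rate × one positive multiplier per configured neighbor offset,
edited iff the score exceeds a percent cutoff, conventionally 9.6. When the
baseline has several coefficient tables (one per deaminase) but the data do
not record which enzyme acts at each site, the max/min selection rule gives
the baseline its best case: edited windows take their maximum score over
tables, random windows their minimum. Published coefficient tables are not
shipped — the scorer is a structural baseline with user-supplied tables.

## Motif significance

Candidate motifs (from any external discovery tool; a TSV and a minimal
MEME-text reader are provided) pass through two per-motif filters — E-value
strictly below 0.05, and exclusion of any motif whose consensus matches,
IUPAC-compatibly on either strand, inside a set of ultraconserved sequences
with no known editing — and then a permutation test against a background
pool of 3′-UTR-like sequences (100 samples of 1,000 sequences by default).

Two details are package decisions, since no external definition fixes them:

* **Statistic.** The per-sequence presence fraction (share of sequences
  with at least one match), robust to length variation in UTR pools; a
  total-match-count mode is available (`statistic = "count"`).
* **Estimator.** The add-one permutation p-value
  `(1 + #{null >= observed}) / (n_samples + 1)`, never exactly zero;
  significance at p < 0.01.

Soft-masked (lowercase) stretches and `N` runs in background sequences are
treated as unmatchable. Scanning counts overlapping occurrences; a motif
wider than its sequence simply has zero matches.

## Synthetic data

`generate_window_sets()` samples windows position-independently from a
per-class positional profile (`bias_spec()`), matching the independence
structure of the model itself so that the generating profiles are analytic
ground truth. The default edited profile (`adar_neighbor_profile()`)
emulates the documented deaminase neighborhood preferences — 5′ neighbor
U ≈ A > G > C, 3′ neighbor favoring G — decaying geometrically (scale 3 nt)
toward uniformity away from the center; the default un-edited profile is
uniform. Default sizes are 15,140 windows per class, the scale of the
reference 30,280-window training corpus, with 21-nt windows.

What the generator deliberately does **not** emulate: positional
correlation, secondary structure, repeat-derived sequence composition, and
catalogue noise (false sites, incomplete negatives). A correlated-generator
mode was consciously excluded to keep ground truth analytic. Consequently,
passing recovery tests demonstrates correctness of the estimator and the
pipeline under the model's own assumptions — not real-data accuracy, which
depends on external catalogues.

`generate_genome_with_sites()` plants site clusters with geometric
within-cluster gaps (mean 30 nt by default) and between-cluster gaps of
20–40× that mean, on random strands, editing the reference so every site
has A (forward) or T (reverse) at its position; it emits matching repeat
intervals (interval annotations only — no Alu sequence realism) and a SNP
track, and keeps a ledger of the planted truth for recovery tests. All
generator entry points take a mandatory seed and restore the caller's RNG
state.

## Problem sizes and numerical tolerances

The test and acceptance workloads are sized for a desk-scale run: 1,000
random segmentation instances against an exhaustive oracle; 50 small
logistic fits (≤ 60 observations × ≤ 6 features) against a generic
optimizer at 1e-4; 200 ROC instances (n ≤ 200) against pair counting at
1e-12; cross-validation recovery at 2,000 windows; profile recovery at 500
windows within 3 standard errors per cell; permutation calibration over 200
replicates with 100 null samples of 1,000 sequences from a 3,000-sequence
pool, tested against uniformity by Kolmogorov–Smirnov at α = 0.01. Column
stochasticity of profiles is enforced to 1e-9, convergence to a gradient
max-norm of 1e-8.

## Known limitations

* Headline figures on the human catalogues (genome-scale ER counts, AUCs
  against the published baseline) require external databases and published
  coefficient tables and are out of scope; the package validates by
  property and synthetic ground truth instead.
* The model is strictly positional-independent; windows with strong
  dependent structure (e.g. hairpins) are scored by marginal preferences
  only.
* The permutation test assumes the background pool is exchangeable with
  the observed set under the null; pools with systematic composition
  differences will miscalibrate it.
* Training sets with very few windows make the smoothed profiles close to
  uniform and the model close to intercept-only; there is no small-sample
  correction beyond the pseudocount.
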