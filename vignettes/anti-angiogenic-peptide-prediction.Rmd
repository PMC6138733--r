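---
title: "Predicting anti-angiogenic peptides with AntiAngioPep"
author: "AntiAngioPep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting anti-angiogenic peptides with AntiAngioPep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AntiAngioPep)
```

# The problem and the model

Anti-angiogenic peptides suppress the growth of new blood vessels; a
sequence-only predictor of this activity is useful both for screening
candidate therapeutics and for understanding which sequence properties
carry the signal. AntiAngioPep implements a binary classifier for
peptides of length at least 10 over the 20-letter amino-acid alphabet.
Its design follows the observation that the discriminative signal is
concentrated in (i) which residues occur — positives are enriched in
Cys, Pro, Ser, Arg, Trp, Thr and Gly, negatives in Ala, Asp, Ile, Leu,
Val and Phe — and (ii) *where* they occur, with pronounced biases at
the N- and C-terminal regions.

The model is a soft-voting ensemble of two probabilistic classifiers
trained on sequence-derived features. One base classifier is chosen for
its sensitivity, the other for its specificity; the fused positive-class
probability is their plain arithmetic mean, thresholded at 0.5 (a fused
probability exactly at the threshold is called positive).

# Feature encoders

## Bi-profile Bayes (BpB)

`fitBpB()` estimates, on labelled training data, four tables of
position-specific residue posteriors: N-terminal and C-terminal windows
of `m` positions each, under the positive and under the negative class.
Entry $(i, a)$ of a class-$c$ table is

$$ P(a \mid i, c) \;=\; \frac{n_{i,a,c} + \kappa}{n_c + 20\,\kappa}, $$

where $n_{i,a,c}$ counts class-$c$ training sequences carrying residue
$a$ at window position $i$ and $\kappa$ is a pseudocount.
`encodeBpB()` then converts a query into a $4m$-vector by looking up its
own terminal residues in the four tables, in the block order N-positive,
C-positive, N-negative, C-negative. Encoding is a pure gather: it never
reads the query's label, which is what makes per-fold refitting inside
cross-validation leakage-free.

Choices worth making explicit:

* `m = 10` by default — the benchmark's minimum peptide length, so both
  windows always exist.
* C-terminal positions are indexed left-to-right within the last-`m`
  window (position 1 is residue $L-m+1$). The orientation is a
  convention; we fix it and record it with the serialized model.
* `pseudocount = 1` (add-one smoothing) by default. Smoothing is not
  required for the encoding itself, but keeps all features strictly
  inside $(0,1)$ and stabilises the downstream Gaussian variance
  estimates; `pseudocount = 0` is allowed and used in exact hand-count
  tests.
* Within cross-validation the tables are refit on the training folds by
  default. `wholeDatasetBpB = TRUE` instead fits them once on the full
  dataset before splitting — the protocol commonly paired with this
  encoder in the literature. Both are supported because the two designs
  answer different questions: the default estimates generalisation
  honestly; the whole-dataset protocol reproduces the published
  workflow. On the strongly separated synthetic data the two agree to
  within a percent.

## Composition–Transition–Distribution (CTD)

`encodeCTD()` works on a fixed partition of the alphabet into four
physicochemical groups (hydrophobic, polar, positively charged,
negatively charged; see `ctdGroupScheme()`), chosen because
anti-angiogenic peptides show elevated hydrophobic and cationic residue
content. The 30 features are: 4 group frequencies $N_i/L$; 6 unordered
adjacent-pair transition frequencies $(N_{ij}+N_{ji})/(L-1)$ in the
fixed order (1,2), (1,3), (1,4), (2,3), (2,4), (3,4); and, per group,
the 1-based positions of its first, 25%, 50%, 75% and 100% occurrences
divided by $L$. The occurrence index for quantile $q$ is
$\lceil q\,N_i\rceil$ with the first mark pinned at occurrence 1 — the
ceiling convention guarantees a valid index for every $N_i \ge 1$. An
absent group contributes zeros to all its composition, transition and
distribution entries, keeping the vector finite and fixed-length.
Sequences must have $L \ge 2$ (transitions are undefined below that).

## DFT power spectra

`encodeDFT()` maps the sequence onto numeric profiles via per-residue
property scales and summarises each profile's periodicity by the
discrete Fourier transform

$$ F(k) = \sum_{n=1}^{L} H(p_n)\, e^{-2\pi n k j / L}, \qquad
   PS(k) = |F(k)|^2 , $$

keeping the `nFreq = 10` lowest frequencies $k = 0..9$ per scale
(20 features with the two default scales). The DC component $k=0$ is
included: it carries the mean property level, itself informative, and
keeps ten components per property. The defaults are the Kyte–Doolittle
hydropathy and Hopp–Woods hydrophilicity indices — the canonical
hydrophobicity/hydrophilicity scales; any named 20-residue scale can be
substituted (`readPropertyScale()`), and results on real data can shift
with that choice. Profiles are used raw by default; `center = TRUE`
subtracts the profile mean, which zeroes $PS(0)$ and nothing else. The
implementation rides on `stats::fft()` with the phase adjusted to the
$n = 1..L$ convention; the power spectrum is unaffected by that phase,
and an $O(L^2)$ direct evaluation serves as the test oracle.

# Feature selection

`reliefRank()` implements the classical two-class Relief update. All
features are min–max scaled to $[0,1]$ internally, so weights are
invariant to per-feature affine rescaling; distances are Euclidean on
the scaled features; the per-feature difference is the absolute scaled
difference (a whole-vector norm would give every feature the same
weight). By default every instance is visited once in index order
(`nIter = "all"`), making the result fully deterministic — the number of
randomly sampled instances in the classical formulation is a free
parameter, and the deterministic pass makes results exactly
reproducible; seeded random sampling remains available. Ties — both
nearest-neighbour and ranking ties — break towards the lowest original
index. Weights are reported raw and may be negative (the natural range
is $[-1,1]$); clipping would not change the ranking, so none is applied.

`ifsSelect()` evaluates ranking prefixes $k = 1..d$ with an injected
evaluator and keeps the smallest $k$ attaining the maximum — the
injection lets the NB+LR ensemble, any single classifier, or a synthetic
curve drive the scan. `makeCVEvaluator()` builds the standard evaluator:
pooled cross-validated accuracy on a fold partition fixed once from its
seed, so all prefixes are scored on identical folds.

# Classifiers and fusion

* **Gaussian naive Bayes** (`trainGaussianNB()`): per-class, per-feature
  normal densities with maximum-likelihood variances, floored at
  $10^{-9}\times$ the largest feature variance (absolute $10^{-9}$ if
  all are zero) so constant features degrade gracefully into the prior;
  posteriors are computed in the log domain. Gaussian densities are the
  natural choice for the continuous encoder outputs.
* **Ridge logistic regression** (`trainRidgeLogistic()`): IRLS on the
  L2-penalised log-likelihood (intercept unpenalised), ridge default
  $10^{-8}$ — near-unpenalised but keeping coefficients finite on
  separable data; convergence when the largest coefficient change drops
  below $10^{-8}$, capped at 100 iterations; IRLS working weights are
  floored at $10^{-10}$.
* **Nearest neighbour** (`trainNearestNeighbor()`): label of the
  Euclidean-nearest training sample, distance ties to the lowest
  training index. Its pseudo-probabilities are hard 0/1, so its ROC is
  a single point; it participates in candidate pools but is a poor
  fusion partner for score-based ROC analysis.

`selectBasePair()` picks the argmax-sensitivity and argmax-specificity
candidates from a cross-validated candidate table; if one classifier
wins both, the runner-up on specificity is taken so the pair is
distinct. `FusionModel` objects serialize to a single versioned JSON
file embedding the BpB tables, feature indices and both bases; numbers
are written at full decimal precision, so reloaded models reproduce
predictions to within $10^{-14}$ relative error and repeated writes are
byte-identical.

# Evaluation conventions

`stratifiedFolds()` shuffles within class under a seed and rotates the
leftover samples across classes, so per-class counts *and* total fold
sizes each differ by at most one (with 107 + 107 samples and $k = 10$:
folds of 21–22 with 10–11 positives). Predictions are pooled over folds
into a single confusion matrix (micro-average) rather than averaging
per-fold metrics: with ~21-sample folds, per-fold metrics are noisy and
their mean depends on fold sizes, while pooled counts are stable;
per-fold metrics can be recorded alongside (`perFold = TRUE`). The MCC
is defined as 0 (with a warning) when a denominator factor vanishes.
`rocAuc()` sweeps the threshold over distinct score values with ties
grouped; the trapezoidal AUC then equals the Mann–Whitney statistic with
half credit for cross-class ties, an identity the tests verify exactly.

# The synthetic generator

`simulatePeptides()` emulates the *statistical structure* of the real
benchmark, not its biology: uniform background residue usage, the
documented enriched set boosted by a factor $1 + 2\,\mathrm{effect}$
(renormalised) everywhere and $1 + 4\,\mathrm{effect}$ inside the
first/last `terminalWindow` positions — the doubled exponent creates the
terminal positional signal the BpB encoder is designed to detect.
Defaults are chosen to mirror the published study conditions: 107 + 107
peptides, lengths uniform on 10–30 (the benchmark's minimum length is
10; the maximum is a realistic cap for bioactive peptides of this
class), `terminalWindow = 10` matching the BpB window, `effect = 1`.

What passing tests on this generator do show: every pipeline stage is
wired correctly, recovers a planted terminal-composition signal
(`effect = 1` gives cross-validated AUC near 1 at $n = 400$), and stays
at chance on exchangeable classes (`effect = 0`). What they do not show:
performance on real peptides, which have correlated residues, homology
structure (the original benchmark was filtered at 70% identity — not
modelled here), non-uniform background composition and weaker, messier
enrichment. Published headline metrics on the real benchmark
(accuracy 0.832, AUC 0.872) additionally depend on the exact benchmark
peptide lists — which are not redistributed with this package — and on
unstated fold seeds, so this package treats them as qualitative
context, not as reproduction targets; the metric *formulas* are instead
validated exactly against published metric tables via the
implied-confusion-count identity (`impliedCounts()`).

# Problem sizes and determinism

The test suite and the acceptance script run at deliberately desk-scale
sizes chosen as the package's own verification conditions: oracle
equivalence on 1000 random short sequences (CTD), random profiles up to
length 64 (DFT), up to 8 samples (Relief, $10^{-12}$ agreement), 1000
random score vectors (AUC), 20-seed null panels and 107 + 107 or
200 + 200 synthetic benchmarks for pipeline-level checks. Every source
of randomness — generation, fold shuffles, Relief sampling — flows from
explicit integer seeds, and all deterministic paths (fitting, encoding,
ranking with `nIter = "all"`) are exactly reproducible.

# Known limitations

* Real-data performance is untested here by construction; scale choice
  for the DFT encoder and the BpB fitting protocol (per-fold vs whole
  dataset) both shift absolute numbers on real benchmarks.
* Binary labels only; no multi-class support, no nucleotide input.
* The nearest-neighbour base yields degenerate (0/1) scores.
* Redundancy reduction (sequence-identity clustering) is out of scope;
  users should de-duplicate inputs before evaluation.
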