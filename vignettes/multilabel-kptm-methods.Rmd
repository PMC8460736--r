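---
title: "Methods: multi-label K-PTM site prediction with kptm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-label K-PTM site prediction with kptm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kptm)
```

## The problem and the model

Lysine residues are hubs of post-translational regulation: one K can be
acetylated, crotonylated, methylated, succinylated or glutarylated, alone
or in combination. `kptm` treats site prediction as five coupled binary
problems over a shared representation. A candidate site is the window of
`2*zeta + 1` residues centred on the lysine; its label is the *set* of
modifications observed there, and the empty set is a first-class outcome
(Non-K-PTM). The model is deliberately shallow — hand-crafted sequence
features into cost-sensitive RBF-SVMs — because at the sample sizes
typical of curated PTM corpora (a few thousand positives) such models
remain competitive, trainable in seconds, and fully auditable.

Assumptions worth stating explicitly:

* the predictive signal is local (within `zeta` residues of the site) and
  positional — both encoders that dominate selection (sequence coupling,
  CKSAAP) are position- or pair-specific;
* labels are conditionally independent given the window: each PTM head
  decides alone, and multi-label structure arises only through the shared
  features. Co-occurrence is therefore represented but not exploited;
* one window string is one sample: exact duplicate windows are merged and
  an observed modification anywhere outweighs its absence elsewhere (the
  union rule), since absence of annotation is weak evidence.

## Windowing

`extract_window()` cuts `2*zeta + 1` residues around a 1-based K position;
`zeta = 24` (49 residues) is the default operating point. When the window
overruns a terminus the missing flank repeats the terminal residue. We
chose plain repetition over mirror padding: it matches the "nearest
residue" idea, is the simplest total rule, and keeps padded windows
recognisably low-complexity. Redundancy elimination is exact window-string
identity; similarity-based deduplication (e.g. CD-HIT-style clustering)
would change benchmark composition and is intentionally out of scope.
Nonstandard residues (B, J, O, U, X) map to the wildcard `Z`, the 21st
alphabet symbol, on load.

## The four encoders

**Amino-acid factors (AAF).** Each residue contributes five multivariate
physicochemical factor scores (polarity, secondary-structure propensity,
molecular volume, codon diversity, electrostatic charge) from the Atchley
et al. (2005) factor analysis of the AAIndex collection; the wildcard is
all-zero. The table is a versioned constant in `aaf_table()`.

**Binary encoding (BE).** One-hot over the fixed alphabet order
`ACDEFGHIKLMNPQRSTVWYZ`. The order is the contract: `A` is bit 1, `G` bit
6, `Z` bit 21.

**CKSAAP.** For each spacing `k` in `0..4`, the frequency of every ordered
residue pair at positions `(i, i + k + 1)`, normalised by the number of
such pairs, `(2*zeta + 1) - k - 1`, so each 441-column block sums to
exactly 1. The tests hold this against a brute-force pair enumerator.

**Sequence coupling.** The discriminative encoder: for each non-centre
offset, the probability of the observed residue under a positive-class
model minus the same under a negative-class model. Left-flank offsets
condition on the neighbour one step toward the centre (offset `j` on
`j + 1`), right-flank offsets mirror this (`j` on `j - 1`), and offsets
-1/+1 — whose inward neighbour is the invariant centre K — use
unconditional position-specific probabilities. Tables are position
specific, not pooled: positional preferences are exactly what
distinguishes PTM types. Every count table receives an additive
pseudocount before normalisation, default `1e-4`: large enough that an
unseen (residue, context) cell yields a finite, tiny probability, small
enough (three orders below any real count's contribution at these sample
sizes) to leave supported estimates unchanged. Because both class models
share the smoothing, swapping the classes negates the encoding exactly.

The serial ensemble is `245 + 1029 + 2205 + 48 = 3527` columns at the
default `zeta`, z-scored with parameters learned from training rows only.
A zero-variance column gets scale 1 (mapping to constant 0) with a
warning rather than NaN.

**Leakage policy.** The coupling tables and the scaler are trained
components. `cross_validate()` refits both inside every training fold and
freezes them for the held-out fold; a canary test asserts that corrupting
held-out labels changes nothing trained. Encoders that depend only on the
window string (AAF, BE, CKSAAP) are precomputed once — they cannot leak.

## Two-stage imbalance handling

Curated corpora run near 1:16 modified:unmodified. Stage one,
`balance_dataset()`, undersamples the majority by *instance hardness*
measured on the coupling features: a cost-sensitive RBF-SVM scores each
sample out-of-fold (5 stratified folds), and `hardness = 1 - p(true
label)`. The hardest unmodified samples — borderline or mislabelled-like
points — are removed until 1:1. Ties break by original sample order, so
runs are reproducible; survivors keep their windows and labels verbatim.

The probability map is our own Platt calibration: a logistic fit of the
training fold's labels on its decision scores, applied to the held-out
scores. libSVM's built-in calibration randomises an internal split and is
therefore not bit-reproducible; a deterministic sigmoid on training scores
ranks hardness just as well, and ranking is all undersampling consumes.
The fold count (5) and calibration method are declared defaults, not
values inherited from elsewhere.

Stage two absorbs the residual per-task skew (acetylation is near
balanced after stage one; crotonylation remains ~1:40) through
different-error-cost weights `W+ = M/(2*M1)`, `W- = M/(2*M2)` scaling the
SVM cost per class. Balanced counts give both weights 1, and
`W+*M1 + W-*M2 = M` always.

## Feature selection

Features are ranked per task by the two-group one-way ANOVA F statistic,
computed vectorised and checked against a textbook sum-of-squares oracle
to 1e-10. Degenerate columns follow fixed rules: constant within both
groups with equal means, `F = 0` (ranks last); constant within groups with
different means, `F = Inf` (a perfect separator, ranks first). Ties break
by original column index.

`incremental_selection()` walks nested top-`m` subsets (step 50, clamped
to end at the full dimension), cross-validates the five-head predictor at
each `m`, and returns the grid plus `best_m` — the accuracy maximum, with
ties going to the smaller `m` (parsimony). Two ranking modes exist
because the honest answer differs by purpose: `"global"` ranks once on
all data, the protocol benchmark replications use, and is the default for
`incremental_selection()`; `"fold"` re-ranks inside each training fold,
costs a little optimism, and is the default for `cross_validate()`, whose
job is unbiased assessment. The per-task rankings are computed
independently (the optimal subsets genuinely differ by PTM) but one
shared `m` is selected from aggregate multi-label accuracy; the default
operating point is `top_m = 100`.

## Classification and validation

Each head is an RBF-SVM with libSVM defaults (`C = 1`,
`gamma = 1/n_features`, resolved after selection) and the DEC weights of
its own training split; the optimizer is delegated to e1071/libSVM — this
package owns the cost wiring, thresholding, fold logic and seeds. A label
is predicted when its decision score exceeds 0; probability thresholding
at 0.5 is available for calibrated heads and agrees in sign on separable
fixtures. A training split lacking a class entirely (possible for rare
PTMs in small folds) yields a constant head that predicts the observed
class, with a warning — preferable to failing an entire repeat.

`cross_validate()` runs `n_repeats` (default 5) complete rounds of
`n_folds` (default 5) stratified cross-validation with seeds 0..4
recorded in the report. Stratification shuffles within each label-set
stratum and deals round-robin from a rotating start, so each label
combination spreads as evenly as its count allows — a light-weight stand-in
for full iterative multi-label stratification that is exact for the
strata that matter (the dominant combinations) and still spreads
singletons. Metrics are computed on the pooled out-of-fold predictions of
each repeat; the report carries mean and sd over repeats.

## Metrics

Chou's five multi-label metrics are implemented by direct set arithmetic.
The empty-set division they leave open is resolved by the *null-label*
convention (default): a sample with no modification carries an explicit
`Non-K-PTM` label, so no set is ever empty and the universe has `L = 6`
members — consistent with treating Non-K-PTM as an enumerated outcome.
The alternative (`convention = "strict"`): `L = 5`, empty sets kept,
`0/0 := 1`. Both are exact per-sample means of terms in `[0, 1]` and are
tested against an independent set-counting oracle to 1e-12.

## The synthetic generator

`generate_kptm()` emulates the statistical shape of a curated K-PTM
corpus: background residue frequencies of an average proteome, a 1/17
per-lysine modification rate (1:16 imbalance), a label-multiplicity
histogram dominated by single-label sites
(`0.808/0.170/0.015/0.005/0.001` for 1..5 labels), per-type prevalence
dominated by acetylation, and — the planted signal — per-PTM positional
residue preferences written into the flanks with probability 0.9 at two
or three near-centre offsets. Motifs sit inside the coupling-visible
window on purpose: the sequence-coupling encoder is the intended dominant
signal, mirroring how strongly coupling features dominate selected sets
on real data. The manifest records every planted site and the coupling
columns each motif makes informative, which closes the loop: tests assert
those columns lead the ANOVA ranking and that held-out accuracy beats a
shuffled-label baseline by a wide margin.

What the generator does *not* emulate — homology between proteins,
realistic domain composition, annotation noise, cross-PTM sequence
similarity — bounds what passing tests show: the pipeline recovers
strong, local, positional signal without leakage; they do not certify
real-proteome accuracy. The worked examples use ~200–700 proteins
(roughly 3,000–10,000 windows), sizes at which every stage's behaviour is
already stable and a full study runs in well under a minute.

## Numerical and degenerate-input choices

* Coupling pseudocount `1e-4`; conditional columns sum to 1 within 1e-9.
* Zero-variance columns scale to 1 under standardisation (warning).
* `F = Inf` sentinel ranks first; `F = 0` for doubly-constant columns.
* Hardness ties break by original index; IFS accuracy ties by smaller `m`.
* Undersampling with an unreachable target returns the data unchanged
  with a warning rather than erroring.
* Proteins without lysines predict to an empty, well-formed table.
* All randomness flows through explicit seeds via `withr::with_seed()`;
  identical inputs and seeds give bit-identical outputs end to end.

## Known limitations

Only sequence-derived features; no PSSM, structural or evolutionary
encoders. Exact-identity deduplication only. Label dependence is not
modelled beyond shared features. `C` and `gamma` are fixed at libSVM
defaults by design, not tuned. The five PTM types are fixed; extending
the label universe means regenerating the per-task heads.
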