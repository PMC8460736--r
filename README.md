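# kptm

Multi-label prediction of lysine post-translational modification (K-PTM)
sites from protein sequence.

A single lysine can carry several modifications — acetylation,
crotonylation, methylation, succinylation, glutarylation — and the local
sequence context around the residue carries most of the predictive signal.
`kptm` is for computational biologists who want to build, audit, and apply
such a predictor from nothing more than protein FASTA and a table of
annotated modification sites, with every stage (windowing, encoding,
balancing, selection, classification, evaluation) exposed as a tested,
pipeable function.

## Method

Each candidate site is a peptide window
`P(K) = Q<sub>-ζ</sub> … Q<sub>-1</sub> K Q<sub>+1</sub> … Q<sub>+ζ</sub>`
of 2ζ+1 residues centred on a lysine (default ζ = 24, i.e. 49 residues;
flanks that overrun a terminus are filled by repeating the terminal
residue). Its label set Y ⊆ {acetylation, crotonylation, methylation,
succinylation, glutarylation} may be empty (Non-K-PTM).

Windows are encoded by four serial feature blocks over the 21-letter
alphabet `ACDEFGHIKLMNPQRSTVWYZ` (`Z` is the wildcard):

| block | features | content |
|---|---|---|
| AAF | 5·(2ζ+1) = 245 | five physicochemical factor scores per residue |
| BE | 21·(2ζ+1) = 1029 | one-hot residue identity |
| CKSAAP | 441·5 = 2205 | k-spaced residue-pair frequencies, k = 0..4 |
| coupling | 2ζ = 48 | P⁺(residue at j | neighbour toward centre) − P⁻(·), position-specific |

giving 3527 z-scored columns. The heavy Non-K-PTM majority (about 16:1 in
curated human data) is undersampled to 1:1 by *instance hardness*: an
out-of-fold cost-sensitive RBF-SVM on the coupling features estimates
p(true label | x), and the majority samples with the largest
`IH = 1 − p(y|x,h)` are discarded. Per task, features are ranked by the
one-way ANOVA F statistic and the top m kept (default m = 100; the grid
search over nested subsets is `incremental_selection()`). One RBF-SVM per
PTM type (C = 1, γ = 1/m) with different-error-cost class weights
`W± = M/(2·M±)` assigns its label independently at decision score 0; the
five heads together yield the predicted label set. Performance is measured
with Chou's multi-label metrics — aiming, coverage, accuracy,
absolute-true, absolute-false — under repeated stratified 5×5-fold
cross-validation in which every trained component (coupling tables, scaler,
ranking, weights, SVMs) is refitted inside each training fold.

## Worked example

A synthetic study with planted, recoverable motifs (the generator is part
of the package; real data enters through `read_proteins()` +
`read_annotations()` with the same downstream calls):

```r
library(kptm)

sim <- generate_kptm(kptm_sim_config(n_proteins = 220, seed = 7))
ds  <- build_benchmark(sim$proteins, sim$annotations, zeta = 24)
label_multiplicity(ds)
#>   n_labels n_samples
#> 1        0      3118
#> 2        1       158
#> 3        2        41
#> 4        3         4
#> 5        4         1
#> 6        5         0

bal <- balance_dataset(ds, seed = 0)      # 3322 -> 408 samples, 1:1
cv  <- cross_validate(bal, pipeline_config(n_repeats = 2, seeds = c(0, 1)))
cv
#> <kptm_cv> 2 x 5-fold cross-validation (selection: fold)
#>   aiming          83.15% +/- 0.43
#>   coverage        80.62% +/- 0.35
#>   accuracy        80.02% +/- 0.43
#>   absolute_true   76.59% +/- 0.52
#>   absolute_false   7.05% +/- 0.14
```

The 3322 windows carry a 1:16 modified:unmodified imbalance; balancing
keeps all 204 modified samples and the 204 easiest unmodified ones. The
cross-validated accuracy (mean Jaccard overlap between predicted and true
label sets) of ~80% is what the planted signal supports under leakage-safe
per-fold refitting; a shuffled-label baseline sits near 40%, so roughly
half the head-room is genuine sequence signal. `tidy(cv)`, `glance(cv)`
and `autoplot(cv)` give the per-repeat table, the one-row summary and the
metric plot; `train_multilabel()` + `predict()` score new FASTA, and
`inst/cli/kptm.R` wraps the stages (`simulate`, `build-dataset`,
`balance`, `cv`, `train`, `predict`, `evaluate`) for shell use.

On the published human benchmark (5059 modified / 81507 unmodified
windows, available from its authors), the same configuration is the
replication experiment: that corpus is not bundled here, so those headline
cross-validation numbers are not re-computed by this repository's checks.

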