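---
title: "Methods: hybrid sequence descriptors and bagging-SVM for druggability prediction"
author: "drughybrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid sequence descriptors and bagging-SVM for druggability prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drughybrid)
```

## The problem

A protein is *druggable* when it can bind a drug-like small molecule with
therapeutic effect. Experimental assessment is slow, so sequence-based
classifiers that flag candidate druggable proteins from primary structure
alone are a standard triage tool in early drug discovery. `drughybrid`
implements one family of such classifiers: three fixed-length sequence
descriptors, redundancy-aware feature selection, and a bagged ensemble of
linear support vector machines, evaluated by stratified cross-validation
and a stratified holdout split.

The package works on any labeled FASTA input; it also ships a synthetic
sequence generator so every stage is testable without external data.

## Descriptors

**Grouped amino-acid composition (GAAC).** The 20 residues are partitioned
into five physicochemical groups — aliphatic `GAVLMI`, aromatic `FYW`,
positively charged `KRH`, negatively charged `DE`, uncharged `STCPNQ` —
and a sequence of length $N$ maps to the 5-vector $f(g) = N(g)/N$. The
components always sum to 1. For the 18-residue reference sequence
`EAHGAFLMDKPSMFNERV` the group counts are $(7, 2, 3, 3, 3)$:

```{r}
gaac_encode(worked_example()$sequence) * 18
```

**Cross-covariance (CC).** Each residue carries three physicochemical
property values $x_{i,1}, x_{i,2}, x_{i,3}$ (hydrophobicity,
hydrophilicity, side-chain mass). For every ordered pair of *distinct*
properties $(k, j)$ and every lag up to `lg`,

$$\mathrm{CC}(k, j, \mathrm{lag}) \;=\; \sum_{i=1}^{L-\mathrm{lag}}
  (x_{i,k} - \bar{x}_k)(x_{i+\mathrm{lag},j} - \bar{x}_j),$$

with $\bar{x}_k$ the mean of property $k$ over the sequence's own
residues. With 3 properties and `lg = 2` the descriptor has
$3 \times 2 \times 2 = 12$ components. Two numerical choices are
deliberate and exposed:

* *No denominator by default.* The defining sum is implemented exactly as
  written; many descriptor suites divide by $L - \mathrm{lag}$, so
  `cc_encode(..., normalize = TRUE)` provides that variant. The default
  stays with the plain sum for fidelity to the method as published.
* *Property standardization.* The three raw scales (a Tanford-style
  hydrophobicity scale, Hopp–Woods hydrophilicity, side-chain mass in Da)
  have wildly different units, and the source method does not state which
  scales it used. The packaged table (`inst/extdata/physchem_pseaac.tsv`,
  the triple in common use for pseudo-amino-acid-composition work) is
  therefore standardized to mean 0 / unit variance across the 20 residues
  before the sum, and the loader accepts any user table. Absolute CC
  values are consequently comparable only within one table choice; the
  descriptor's dimensionality and structure are what the rest of the
  pipeline relies on.

**monoDiKGap.** A gapped 3-mer composition: for each gap width
$g = 1 \dots k$, every pattern of one residue, $g$ ignored positions, and
two residues (shape `X_XX` at $g = 1$, `X__XX` at $g = 2$, written e.g.
`"A_AA"`, `"A__AA"`). Each gap shape contributes $20^3 = 8000$
descriptors, so the default $k = 2$ space has 16,000. The value of a
descriptor is its window count divided by the number of windows
$L - (3 + g) + 1$, so each gap block sums to 1 whenever the sequence is
long enough to hold one window and is all-zero otherwise (a convention
that keeps matrices rectangular for very short inputs). Window
normalization is itself a choice — "frequency" admits both count and
count-per-window readings — and the per-window reading was chosen because
it makes blocks comparable across sequence lengths and gives the testable
block-sum invariant.

Hybrids concatenate blocks in the fixed order (monoDiKGap, CC, GAAC); a
boosted-stump-selected monoDiKGap subset of, say, 466 features yields the
483-dimensional hybrid ($466 + 12 + 5$).

## Feature selection

**Boosted-stump importance** (`adaboost_select`). The 16,000-dimensional
gapped k-mer space is mostly zeros; a discrete AdaBoost ensemble of
depth-1 decision stumps (100 rounds by default, exhaustive threshold
search implemented in C++) is fitted and features with accumulated stump
weight $\alpha > 0$ are retained, ordered by importance. The procedure is
deterministic given the data; the boosting configuration (depth-1, 100
rounds, strict `> 0` retention) is explicit because the method family it
follows leaves it unstated.

**MRMD** (`mrmd_select`). Features are ranked by combining *relevance*
(absolute Pearson correlation with the ±1 label, min-max normalized) with
*distance* (non-redundancy): the mean over a pair of features of three
distance measures — min-max-normalized Euclidean distance, cosine
distance, and one minus the Tanimoto coefficient. Weights default to
$w_r = w_d = 1$. The ranking is greedy: after the first pick the distance
term is recomputed against the already-ranked set, and a candidate at
numerically zero distance from the ranked set (an exact duplicate) is
deferred to the end — a duplicated column carries no new information and
must not ride its twin's relevance. The returned subset is the top-$k$
maximizing stratified 5-fold CV accuracy of a linear SVM over a coarse
$k$ grid (ties to the smaller $k$). Because the greedy objective is not
monotone, the reported scores are its running minimum, keeping the
ranked list's score order consistent.

**Rank fusion** (`mrmd2_rank`). Seven rankers — one-way ANOVA F, chi-square
on equal-width-binned features, absolute Pearson correlation, a binned
mutual-information estimator (a proxy for MIC, and labeled as such), order
of entry along the LASSO regularization path, greedy mRMR on binned mutual
information, and the combined MRMD relevance score — each produce a full
ordering. For every list, an edge of weight 1 runs from each feature to
every feature ranked above it; edge weights accumulate across lists, and
PageRank (damping 0.85, power iteration to an L1 change below $10^{-9}$,
hard iteration cap) scores the nodes. This complete-dominance edge
construction is the simplest one consistent with fusing ranked lists and
is documented as an approximation; the ranker roster is a configurable
list because the fused-ranking method it follows names its mechanism
precisely but its roster loosely ("seven algorithms, such as ...").
Ties everywhere break by (score descending, descriptor name ascending).

## Classifier

`train_bagging_svm` draws $T$ bootstrap resamples (size $n$, with
replacement; learner $t$ uses seed $\mathrm{seed} + t$), fits one SVM per
resample (linear kernel and $C = 1$ by default; degree-2 polynomial and
RBF available), and predicts by majority vote. Two conventions the
source method leaves open are fixed here and flagged:

* *Even-$T$ ties* break by the sign of the mean decision value, an
  exactly-zero mean going to the negative class — deterministic, and it
  uses information the ensemble already has.
* *Standardization* of features with training-fold mean/sd is on by
  default (a linear SVM at fixed $C$ is scale-sensitive); disable with
  `standardize = FALSE`.

The per-sample score is the mean decision value (smoother than vote
counts, hence used for ROC curves). The SVM solver is consumed from
`e1071`/libsvm as a solved component; KNN ($k = 3$), random forest and a
single SVM are available as baselines behind the same predict contract.

## Evaluation

`metrics` computes the confusion-matrix rates
($\mathrm{TPR} = \mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$,
$\mathrm{FPR} = \mathrm{FP}/(\mathrm{FP}+\mathrm{TN})$, precision,
recall, F-score as the harmonic mean, accuracy) on integer counts, with
zero-denominator cases reported as `NaN` and flagged rather than coerced
to 0. `auroc` is the rank statistic (tied ranks averaged): the
probability that a random positive outscores a random negative.

`cross_validate` uses stratified folds and pools confusion counts across
folds by default. Both choices are flags (`stratified`,
`aggregate = "mean"`): stratification because realistic druggability
datasets are class-imbalanced, pooling because per-fold rates are noisy
when folds are small. `holdout_split` is a stratified 80/20 split by
default. `sweep_axis` reproduces the standard parameter studies: kernel
in {linear, poly2, rbf}, $C$ in {1, 10, 100, 1000}, ensemble size
$T = 1..20$, and accuracy-versus-top-$k$ feature curves.

**Selection inside the folds.** `full_pipeline` runs the whole recipe —
validation, optional greedy identity reduction, hybrid encoding,
boosted-stump reduction of the gapped k-mer block, MRMD over the hybrid,
bagging-SVM — with the two selection stages executed *inside each
training fold* (and inside the holdout training split). Selecting
features on the full data before cross-validating looks innocuous but is
not: with 16,000 candidate features, chance associations chosen on all
$n$ samples leak into every test fold and inflate null-data accuracy well
above chance. The package treats the unbiased protocol as the only
supported one; the cost is re-running selection once per fold.

## Sequence handling

Records containing the non-standard residue codes B, J, O, U, X or Z (or
any other symbol outside the 20-letter alphabet) are rejected with a
reason, never repaired, and validation is idempotent. Redundancy
reduction is a deliberately simple greedy stand-in for CD-HIT-style
clustering: records are processed longest-first (ties by id), and a
record is kept only if its identity to every kept record is below the
threshold (0.6 by default). Identity is the best ungapped overlay of the
shorter sequence on the longer, scored as matches over the shorter
length — the least order-sensitive ungapped convention. This is **not**
CD-HIT: no word index, no alignment, no clustering output. It exists so
the pipeline has no external binary dependency; for publication-grade
redundancy reduction of real datasets, run CD-HIT and feed the result in.

## Synthetic data: what it does and does not emulate

The generator draws residues i.i.d. from a background distribution
(uniform by default, swappable) and injects class signal into positives
through three channels, all scaled by one `effect_size` knob and all
exactly inert at `effect_size = 0` (the two classes are then
distributionally identical — the basis of the null-data tests):

* `group_composition`: log-scale tilt of residue probabilities by a fixed
  per-group contrast $(+0.15, -0.10, +0.10, -0.10, -0.12)$ for
  (aliphatic, aromatic, positive, negative, uncharged), times
  `effect_size`. At the default `effect_size = 2` and lengths 60–140 this
  produces a GAAC shift detectable but not saturating — single-descriptor
  classifiers land in the 70–90% range, qualitatively mirroring the
  regime where composition alone is informative but clearly weaker than
  the hybrid.
* `kmer_motifs`: a fixed set of four gapped 3-mers (`planted_motifs()`),
  inserted at Poisson($1.5 \cdot$ `effect_size`) random positions per
  positive sequence. Against a chance expectation of roughly $L/8000$
  occurrences per pattern this is a strong, sparse k-mer signal — the
  regime in which the gapped k-mer encoder and the boosted-stump selector
  should shine.
* `property_runs`: Poisson($0.8 \cdot$ `effect_size`) hydrophobic
  (I/L/V/F) runs of length 6 per positive sequence — a weaker, smoother
  composition signal.

Defaults (500 + 500 sequences, lengths 60–140 uniform, channels
`group_composition` + `kmer_motifs`, `effect_size = 2`) were fixed once
as the package's study conditions: large enough for stable
cross-validation estimates, small enough that the whole nested pipeline
runs in minutes on one core. What passing tests on this generator shows:
the encoders measure what they claim, selection finds planted signal
without conjuring signal from noise, and the ensemble behaves like a
bagging ensemble. What it does not show: performance on real proteomes —
real protein sequences have length distributions in the hundreds,
homology structure, domain grammar and non-i.i.d. composition that the
generator deliberately omits (homology is exercised only via duplicate
injection for the identity filter). Accuracies on synthetic data are
properties of the generator, not forecasts for DrugBank-style corpora.

## Known limitations

* The greedy identity filter is a stand-in, not CD-HIT; identity
  conventions (denominator, ungapped overlay) are explicit but
  necessarily unverifiable against tools that do alignment.
* Absolute CC values depend on the property table; only structure and
  dimensionality are table-independent.
* The mRMR and MIC components use binned mutual-information estimates
  (5 equal-width bins); they are labeled proxies, not the exact MIC
  statistic, and the mRMR ranker is quadratic in the feature count — use
  it on reduced spaces, not on the raw 16,000.
* No probability calibration, no multiclass, no class reweighting; ROC
  areas come from mean decision values.
* Boosting retains at most one feature per round, so `adaboost_select`
  returns at most `n_estimators` features; raise the rounds if a larger
  subset is wanted.

## Problem sizes used in the shipped checks

The packaged test-suite and acceptance script run the full nested
pipeline at 500 + 500 synthetic sequences (the generator defaults),
planted-motif recovery at 100 + 100 over 20 seeds, and the ensemble
sweeps at 75 + 75 — sizes chosen as the package's own desk-scale study
conditions so the complete suite runs on a single core in well under half
an hour.
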