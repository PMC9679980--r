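---
title: "Thermal-trait regression from protein sequence: model, interpretation and design notes"
author: "ThermoCNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-trait regression from protein sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Organisms occupy thermal niches from below freezing to above 100 °C, and the
adaptations that keep their enzymes folded and catalytically active are
written into protein sequence. ThermoCNN models that relationship directly:
a one-dimensional residual convolutional network maps an amino-acid sequence
to a scalar thermal trait — the optimal growth temperature (OGT) of the
source organism, an enzyme's catalytic optimum $T_{opt}$, or a melting
temperature $T_m$, all in °C. Because OGT labels are abundant (every protein
of a sequenced organism inherits its organism's growth temperature) while
$T_{opt}$ and $T_m$ measurements are scarce, the package is built around
transfer learning: pretrain on the abundant weak labels, then re-use the
learned feature extractor for the scarce targets.

# The model

The network consumes one-hot encoded sequences ($L_{max} \times 20$, fixed
alphabetical residue ordering, zero post-padding) and applies:

1. an entry convolution ($f$ filters, kernel $s$, "same" padding) with batch
   normalization and ReLU;
2. $1\!-\!3$ residual blocks (Conv–BN–ReLU–Conv–BN with an identity skip,
   then ReLU);
3. valid max-pooling with pool size $p$ and stride $w$;
4. a flatten stage of width $f \times (\lfloor (L_{max}-p)/w \rfloor + 1)$;
5. dropout, a dense layer with BN and ReLU, dropout, and a single linear
   output unit.

Training minimizes mean squared error with Adam. The default configuration
(`modelConfig()`) is the full-size variant: $L_{max} = 2000$, one residual
block with 512 filters, pool 50 / stride 50, giving a flatten width of
$512 \times 40 = 20{,}480$ — the learned sequence representation that
`extractRepresentation()` exposes.

Several architecture constants are deliberate package choices where the
design was genuinely open:

* **Pooling 50/50.** A 20,480-wide flatten with 512 filters forces 40 pooled
  positions, and $\lfloor(2000-p)/w\rfloor + 1 = 40$ with valid pooling
  pins $p = w = 50$.
* **Entry convolution.** The first residual block needs matching channel
  widths for its identity skip; an entry convolution (rather than a
  projection shortcut) provides them.
* **BN before ReLU**, after every convolution and dense layer.
* **Dropout** is implemented as standard activation dropout after the
  flatten and dense stages (ratio 0.3 by default, configurable); a
  weight-level (DropConnect-style) variant was considered and rejected as
  needlessly exotic for the same regularizing role.
* **Glorot-uniform initialization** under an explicit seed; kernel size 5
  and a 128-unit hidden dense layer as defaults.
* **No early stopping** — epochs are explicit, so runs are comparable.

The implementation of the network — forward passes, backpropagation through
convolution (im2col + BLAS), batch normalization, pooling and dense layers,
and the Adam optimizer — is authored in R inside the package. Batch
statistics are used only for layers whose weight group is trainable; frozen
groups always run on their stored running statistics. This is what makes the
freezing guarantees exact (see below).

A numerical note: Adam's per-step update magnitude is bounded by the
learning rate, so a freshly initialized network (predicting ≈ 0) would spend
most of a short run crawling toward the label mean (tens of °C). Training
therefore applies a one-time *output-bias warm start*: before the first
epoch the output bias is shifted so that the mean initial prediction equals
the mean training label. This is a pure reparameterization of the intercept,
leaves the learned sequence dependence untouched, is skipped whenever the
output group is frozen, and can be disabled (`warmStart = FALSE`).

# Transfer modes

`setTransferMode()` reproduces the four canonical fine-tuning regimes by
toggling per-group trainability flags on weight groups tagged `pre_flatten`
or `post_flatten`:

| mode | weights | trainable |
|------|---------|-----------|
| `from_scratch` | re-initialized | all |
| `frozen_all`  | preserved | none |
| `frozen_cnn`  | preserved | dense head only |
| `tune_all`    | preserved | all |

Under `frozen_cnn` the feature extractor is bit-identical after fine-tuning
(weights *and* BN running statistics), so representations extracted before
and after are exactly equal — a property the test suite asserts with
`identical()`. When every pre-flatten group is frozen the trainer computes
the flatten representations once and iterates only the dense head, which
makes frozen fine-tuning orders of magnitude faster than full training.

# Occlusion relevance

To ask *where* in a sequence the model finds its signal, a window of
`width` residues (default 5, matching short secondary-structure elements) is
slid along the sequence with stride 1; at each position the window's one-hot
columns are zeroed — the same all-zero content the network sees for padding
— and the relative prediction change
$(\hat{y}_{occluded} - \hat{y}_{wt})/\hat{y}_{wt}$ is recorded. Because a
window anchored at the ends covers terminal residues fewer times, the
sequence is first flanked by `width − 1` repeats of each terminal residue,
so every original position is covered by exactly `width` windows; a
residue's score is the mean over its covering windows (this realizes the
moving average over window scores). Scores are standardized within each
protein ($z$), and positions with $|z| > 2$ (strict) are called significant.
Per-protein standardization matches the per-protein "relevance profile"
reading; nothing stops a user from pooling scores and standardizing
globally, but it is not the default. A model that predicts a constant yields
an all-zero profile and no significant calls, and the wild-type prediction
must be nonzero for the relative score to exist — the synthetic generator
keeps labels strictly positive for exactly this reason.

Downstream statistics:

* **Enrichment** (`enrichCategories()`): positions are pooled across
  profiles and each category (amino acid, DSSP code, or any per-position
  annotation) is tested for over- and under-representation among
  significant positions with one-sided hypergeometric tests in both
  directions, at α = 0.05 on the smaller tail. No multiplicity correction
  is applied by default — the convention for this style of compositional
  screen — and `p.adjust` can be applied to the returned columns.
  Positions without annotation are excluded from every count rather than
  treated as a category.
* **Domain coverage** (`domainCoverage()`): for domains no longer than half
  the protein, the fraction of domain positions called significant is
  compared against a control built from the outside sequence: every window
  of the domain's length inside the contiguous outside segments is counted
  ($\sum_{seg} \max(0, |seg| - d + 1)$), the significant count outside is
  divided by that window count, and the result divided by the domain
  length. One subtlety is worth stating plainly: with *overlapping*
  windows this control is a deliberately conservative yardstick, not an
  unbiased estimate of the coverage a random domain-length window would
  show — the tests therefore check the control against direct window
  enumeration and check the unbiasedness of coverage itself, not the
  equality of the two. Domains longer than half the protein are flagged
  ineligible and left unscored; `selectDomains()` applies the 30% coverage
  cutoff.
* **Width stability** (`stabilityCheck()`): Jaccard overlap of
  significant-position sets across occlusion widths (2, 5, 10, 20 by
  default); the Jaccard index of two empty sets is defined as 1.

# Classical descriptor baseline

`computeDescriptors()` provides the 5,494-dimensional classical baseline:
20 families with fixed dimensionalities (AAC 20, DPC 400, CKSAAP 2400, DDE
400, GAAC 5, CKSAAGP 150, GDPC 25, GTPC 125, Moran/Geary/NMBroto 240 each,
CTDC/CTDT 39 each, CTDD 195, CTriad and KSCTriad 343 each, PAAC 50, APAAC
80, SOCNumber 60, QSOrder 100). The family parameters are pinned by those
widths: pair gaps $k = 0..5$; autocorrelation over 8 property scales with 30
lags; PAAC/APAAC with λ = 30 and weight 0.05; sequence-order families with
30 lags over two residue-distance matrices; CTD over 13 three-class
groupings with 5 distribution points. The k-spaced triad family uses gap 0
(hence its width equals the conjoint triad's $7^3$).

The constant tables are vendored in code: eight standard published property
scales (Kyte–Doolittle hydropathy, Hopp–Woods hydrophilicity, side-chain
mass, residue volume, Grantham polarity, Charton polarizability,
isoelectric point, net charge), the five-group and seven-group (conjoint
triad) partitions, and the seven classical three-class CTD partitions
extended to 13 with tertile partitions derived from the scales. The two
residue-distance matrices are computed at load as Euclidean distances in
standardized property space (all eight scales; and a
hydropathy/polarity/volume subspace) and normalized to unit maximum. These
are the package's own documented choices; any fixed scale set yields the
same dimensional and structural contracts, which is what the tests pin.
Degenerate cases are defined rather than fatal: autocorrelations of a
homopolymer (zero property variance) return 0, and constant feature columns
standardize to 0.

`fitScaler()`/`applyScaler()` implement standardization. Two protocols are
supported: fitting on training data only (recommended; no information flows
from the test partition), and fitting on the pooled train + test matrix — a
historically common but leaky protocol that is reproduced for comparability
and clearly flagged in the documentation.

# Data assembly

* `filterRecords()` enforces corpus validity: length within [100, 2000]
  (inclusive bounds — "shorter than 100" and "longer than 2000" are strict
  rejections) and the 20-letter standard alphabet; selenocysteine and other
  extended codes count as nonstandard.
* `splitLabeledSet()` partitions uniformly at random with
  $|test| = \lfloor fraction \times n \rfloor$. Published corpus sizes in
  this area are inconsistent about rounding (a 1,902-record set splits
  90–10 into 190, the floor, while other corpora imply the ceiling); one
  rule had to be fixed, floor was chosen, and this note records the
  divergence.
* `aggregateMeanLabel()` collapses replicate measurements per id by
  arithmetic mean; `removeOverlap()` de-overlaps corpora by id.
* `uniformSubsample()` rebalances a skewed label distribution by drawing
  equal quotas from 5 °C bins (anchored at
  $\lfloor \min/width \rfloor \times width$; the anchoring had to be fixed
  somewhere). Bins with fewer members than their quota contribute all of
  them — resampling with replacement would duplicate sequences — and the
  shortfall is logged. Redundancy clustering of near-identical sequences is
  out of scope: it belongs to an external clustering tool, and the module
  simply consumes a representative-id list if one is supplied.

# The synthetic generator, and what passing tests mean

`generateSynthetic()` is first-class, tested code: it defines the study
conditions under which every claim in the test suite is evaluated. Residues
are drawn i.i.d. from a background distribution (uniform by default),
motif occurrences (default: one 5-mer, `WYMHK`, 0–4 non-overlapping copies
per sequence) are planted at recorded positions, and the label is

$$y = base + \sum_m \beta_m \cdot count_m + \sum_a c_a \cdot freq_a +
\mathcal{N}(0, \sigma)$$

with defaults $base = 30$ °C, $\beta = 2.5$ °C per occurrence, no
composition effects, and $\sigma = 2$ °C — a signal-to-noise ratio at which
a small network can demonstrably recover the planted function while labels
stay strictly positive. Lengths default to 100–120 residues so that a
width-5 occlusion of the flanked sequence still fits a 128-residue model
input. Fake annotations give the interpretation pipeline a planted truth:
one eligible domain containing each motif occurrence, and run-length
sampled DSSP strings whose motif positions are forced to a designated code.
`emulateImbalance()` replaces the planted labels with a 90/10 bimodal
normal mixture (30 °C and 70 °C, sd 1.5) to exercise rebalancing, and a
stratified `labelDistribution` mode produces exact target histograms.

What the generator does *not* emulate is equally important: real protein
sequences are not i.i.d. draws (they carry composition bias, repeats and
homology structure), real thermal signal is not a single planted motif, and
real labels carry measurement heterogeneity. Passing the desk-scale suite
demonstrates that the machinery — encoding, optimization, freezing,
occlusion, enrichment — is correct and recovers known signal under
controlled conditions; it does not certify real-data accuracy, which in the
original setting required millions of sequences and GPU-scale training and
is explicitly out of scope here.

# Desk-scale problem sizes

The heavy validation uses deliberately small instances, chosen once as the
package's study conditions: planted-signal recovery trains a 16-filter,
128-input network on 2,000 records (90/10 split, 10 epochs, batch 128,
learning rate 2e-3, median over 5 seeds, holdout $R^2 \ge 0.5$); transfer
pretrains on 5,000 records and fine-tunes on a correlated 200-sample task
(frozen extractor vs. from scratch, median over 5 seeds); occlusion
enrichment uses 50 held-out sequences. The evaluation harness reports
$R^2$, RMSE, Pearson and Spearman correlations; repeated runs are compared
with Welch's unequal-variance t-test (the degenerate all-equal comparison
is defined as $p = 1$).

# Hyperparameter search

`randomSearch()` draws a fixed budget of distinct configurations from the
Cartesian product of candidate sets and ranks them by validation loss —
around 100–200 draws is the intended scale. `greedySearch()` refines
coordinate-wise in declared parameter order, accepting the best candidate
per coordinate and sweeping until a full pass yields no improvement; the
result never scores worse than the start. Coordinate order and restart
policy are fixed conventions of this package (declared order, no restarts),
since a greedy protocol is underdetermined without them. The classical
regressors behind the descriptor baseline (ridge, elastic net, decision
tree, random forest, SVM) are delegated to their established
implementations; the package owns only the protocol around them — scaling,
tuning, held-out scoring.

# Known limitations

* Fixed-seed reproducibility is promised within one platform and BLAS;
  bit-exactness across platforms is not.
* The occlusion flanking convention (width − 1 terminal repeats, mean over
  covering windows) is one defensible reading of "flanked by repeats of the
  terminal amino acids" followed by a moving average; others exist, and the
  package documents rather than asserts its choice.
* The network trains on a single CPU at desk scale; there is no GPU path,
  no distributed training, and no attempt to reproduce corpus-scale
  accuracy figures.
* Descriptor property scales are standard published values but not the
  only possible set; swapping scales changes feature values, never
  dimensions or invariants.
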