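---
title: "Methods: physicochemical encodings and the stacked-RBM classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physicochemical encodings and the stacked-RBM classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seqrbm` classifies labelled protein sequences — its motivating case is the
seven class C GPCR subfamilies — from physicochemical representations of
the primary sequence, learned end-to-end by a deep belief network rather
than hand-engineered. This vignette is the package's account of the
underlying models, the parameters that matter, the synthetic data used to
validate the pipeline, and the numerical choices taken where the design was
genuinely open.

## Sequence representations

### Position-wise property encoding

For an aligned sequence of length $L$, `encode_sequences()` replaces each
residue $R_i$ by its value $I_i^k$ under one or more AAindex property
scales. With $n$ indices the values are interleaved position by position,

$$S'' = I_1^{j}, I_1^{k}, \dots, I_L^{j}, I_L^{k},$$

so the feature vector has length $L \cdot n$ and feature names record
`(position, index ordinal)` provenance. Alignment gaps carry no
physicochemical information and encode as 0; ambiguity codes (B/Z/X/U) are
accepted on input but treated the same way, with a warning at parse time.
The assumption behind this representation is that the alignment has already
absorbed the positional correspondence between sequences — the encoding
itself adds no frequency or order information.

The AAindex1 database is sourced from the parsed copy in seqinr
(544 entries). The "preprocessed" form drops the 13 entries with missing
residue values and renumbers the remaining 531 in file order; experiments
refer to indices by this ordinal. Because other preprocessings of AAindex
exist, `aaindex_manifest()` records the ordinal → accession mapping with
every analysis, so an ordinal like "531" is always interpretable. A
flat-format parser and writer (`load_aaindex1()` / `write_aaindex1()`)
round-trip the canonical text format for users who carry their own database
version.

### Alignment-free transforms

Four transforms produce fixed-length vectors from unaligned sequences; all
of them first strip gaps and ambiguity codes.

**Composition** (`aacomp()`): the 20 relative residue frequencies, rows
summing to 1.

**Pseudo-amino-acid composition** (`pseaa()`), amphiphilic form: the
composition is augmented with sequence-correlation factors of $n$
physicochemical properties (default 2: hydrophobicity and hydrophilicity,
the standard tables), each standardized to zero mean and unit *population*
standard deviation over the 20 residues. For property $p$ and lag
$\ell \le \lambda$,

$$\tau_{p,\ell} = \frac{1}{L-\ell} \sum_{i=1}^{L-\ell} h_p(R_i)\, h_p(R_{i+\ell}),$$

and the feature vector
$[P_1 \dots P_{20}, P_{21} \dots P_\Lambda]$, $\Lambda = 20 + n\lambda$,
is jointly normalized: $P_u = f_u / (1 + w \sum \tau)$ for the composition
block and $P_{20+j} = w\,\tau_j / (1 + w \sum \tau)$ for the correlation
block, ordered property-major (all lags of property 1, then property 2).
The weight $w = 0.05$ is the conventional server default for this
representation. At $\lambda = 0$ the transform reduces exactly to
`aacomp()`; at the defaults $\lambda = 21$, $n = 2$ the length is 62.
Sequences must be longer than $\lambda$.

The amphiphilic (per-property) variant is one of two established
correlation-factor conventions; the arithmetic $\Lambda = 20 + n\lambda$
forces it here, and the choice is recorded in the transform tag.

**Haar multiscale energy** (`mse_wavelet()`): each sequence becomes a
numeric signal via the Fauchère–Pliska hydrophobicity scale (FHscale), and
the orthonormal Haar DWT is applied to depth $m$. The features are the RMS
energies of the detail coefficients at scales $1 \dots m$ plus the RMS
energy of the level-$m$ approximation, $m + 1$ values. Signals are
zero-padded to the next power of two $\ge \max(\text{length}, 2^m)$ so $m$
levels always exist; with `m = "auto"` the depth is
$\lfloor \log_2(\max_i L_i) \rfloor$ across the dataset, giving a common
vector length (11 for sequences up to ~2000 residues, hence the 74-length
hybrid `pseaa_mse()` = 62 + 12). The Haar recursion is implemented directly
(a two-tap orthonormal filter bank); tests verify it against an independent
basis-function construction of the same coefficients.

**Auto-cross-covariance** (`acc_transform()`): each residue maps to the
five Sandberg z-scales ($D = 5$), and for each lag $\ell = 1 \dots Lag$ the
transform computes the 5 auto terms

$$AC_d(\ell) = \frac{\sum_{i=1}^{n-\ell} (v_{d,i} - \bar v_d)(v_{d,i+\ell} - \bar v_d)}{(n-\ell)^p}$$

and the 20 cross terms $CC_{dd'}(\ell)$ over ordered pairs $d \ne d'$ in
lexicographic order $(1,2), (1,3), \dots, (5,4)$ — the pair order is a free
choice, fixed and recorded in the feature names. Per-lag blocks of
$5 + 20 = 25$ values are concatenated, so the length is $25 \cdot Lag$
(325 at the default $Lag = 13$, $p = 0.5$). Note the per-lag block size is
additive (5 + 20), not multiplicative. Because the sums are centred, the
transform is invariant to adding a constant to any one descriptor, which
tests assert. Every sequence must be longer than $Lag$. Within this module
$n$ denotes sequence length; the number of properties elsewhere is a
distinct field (`n_props`) to avoid the symbol clash.

### Normalization

`minmax_normalize()` scales each feature to $[0,1]$. Statistics are fitted
on the training fold only and applied with clipping to the held-out fold
(`normalize_scope = "fold"` in `cross_validate()`, the default) — this
prevents test-set leakage. `normalize_scope = "dataset"` restores
toolbox-style whole-dataset normalization for replication of older
protocols. Constant features map to 0: a constant carries no information,
and this avoids division by zero.

## The stacked-RBM classifier

The deep model is a stack of restricted Boltzmann machines unrolled into a
feedforward classifier:

1. **Pretraining** (`pretrain_stack()`): the first RBM is
   Gaussian–Bernoulli — a linear, unit-variance visible layer that accepts
   real-valued inputs — trained by CD-k contrastive divergence (default
   CD-1). Inputs are z-scored internally before the Gaussian layer; the
   unit-variance assumption of that layer makes this standardization an
   implementation necessity, and the statistics are stored in the model.
   Hidden states are sampled (Bernoulli draws) on the positive phase; the
   negative phase and the upward propagation between layers use mean-field
   probabilities — a common convention that reduces gradient variance.
   Each subsequent RBM is Bernoulli–Bernoulli, trained on the previous
   layer's hidden probabilities. Reconstruction-error traces per epoch are
   kept (`autoplot()` on the stack shows them).
2. **Fine-tuning** (`fine_tune()`): a softmax layer with one unit per class
   is appended and the whole network minimizes cross-entropy by mini-batch
   gradient descent with Nesterov momentum (gradient evaluated at the
   lookahead point $\theta + \mu v$) and a step-decayed learning rate.

Training hyperparameters are deliberately conventional defaults for
Gaussian-visible deep belief networks, all exposed in
`deep_net_config()`: pretraining 100 epochs at rate 0.001 for the Gaussian
layer and 0.01 for Bernoulli layers; fine-tuning 200 epochs at rate 0.1
halved every 50 epochs; momentum 0.9; batch size 32; weight decay `1e-4`;
architecture `c(500, 500)`. None of these is canonical — published work on
this task does not fix them — so exact replication of any particular
reported accuracy is not expected, and the package treats them as tunables.

Prediction returns softmax probabilities (rows sum to 1) and argmax labels
with exact ties broken toward the lowest class ordinal (classes are kept in
sorted order). All randomness — weight initialization, CD sampling, batch
shuffling — flows from the configuration seed through a local RNG stream,
so identical seeds give bit-identical models; the caller's RNG state is
untouched.

Baselines (k-NN, decision tree, MLP, RBF-SVM) delegate to `class`, `rpart`,
`nnet` and `e1071` behind the same predict contract; the SVM grid spans
$C \in [1, 16]$, $\gamma \in [2^{-10}, 2^5]$ and selects by internal
stratified 3-fold CV when given candidate vectors.

## Evaluation protocol

`confusion_matrix()` counts $C_{ij}$ = true class $i$ predicted as $j$.
From it: accuracy $= \mathrm{tr}(C)/\Sigma C$; balanced error rate
$= 1 - \overline{\text{recall}}$ (computed through the recall identity so
`ber(C) == 1 - mean(per_class_recall(C))` holds exactly in floating
point); and the multi-class Matthews correlation in the Gorodkin form

$$\mathrm{MCC} = \frac{c\,s - \sum_k t_k p_k}{\sqrt{s^2 - \sum_k p_k^2}\,\sqrt{s^2 - \sum_k t_k^2}},$$

with $c$ the trace, $s$ the total, $t_k$/$p_k$ the true/predicted class
counts. Degenerate denominators (either factor zero, e.g. all predictions
in one class) return 0, consistent with the "no correlation" reading of
that situation.

`stratified_kfold()` shuffles indices within class under a seeded stream
and deals them round-robin, so per-class fold sizes differ by at most one;
every class must have at least $k$ members. `cross_validate()` reports both
the mean of per-fold metrics (the primary summary, matching the "average
classification accuracy" convention) and the pooled confusion matrix, from
which per-class recalls are computed. Grid search enumerates architectures
with later layers' widths varying fastest and breaks ties toward the first
architecture scanned. Index ranking and combination search seed each
per-index task as `seed + ordinal` (or `seed + combination index`), so
results are identical regardless of how the loop might be scheduled.

## The synthetic generator

`generate_sequences()` emulates the *shape* of the aligned class C GPCR
data: seven classes with the unbalanced sizes 36/139/296/82/356/60/230
(total 1199 at `scale = 1`), alignment length 259, and i.i.d. gaps
(default rate 0.05). The signal model is position-wise categorical:

- a background residue distribution per position, Dirichlet-sampled once
  per run and shared by all classes;
- a `signal_fraction` (default 0.1) of positions where each class's
  distribution is tilted toward a class-specific anchor residue with
  mixture weight $1 - e^{-\text{effect}}$, so `effect = 0` leaves classes
  exchangeable and `effect = 5` makes anchors near-deterministic;
- anchor residues are strongly downweighted in the background. This
  mirrors real subfamily alignments, where diagnostic residues are rare
  outside diagnostic columns, and it is what makes the construction
  separable: without it, chance occurrences of anchor residues at the
  ~90% non-signal positions drown the class signal under any
  anchor-separating index.

`generate_property_index()` produces a random scale
($\mathcal N(0, 0.25^2)$ per residue); with `discriminative_for` the
anchor residues receive values on an alternating-sign grid
$(+6, -6, +12, -12, \dots)$, chosen so that pairwise anchor separations
stay commensurate with anchor magnitudes — a gap (encoded 0) then never
looks more like another class than a genuine anchor mismatch does.

Under this construction the pipeline behaves as designed: 1-NN accuracy on
raw encodings rises monotonically with effect (≈0.22, 0.52, 0.91, 0.98 at
effect 0/1/3/5 and full scale), the zero-effect null stays at or below the
majority proportion, and the stacked RBM recovers ≥ 90% 10-fold accuracy at
effect 5.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: phylogenetic correlation between sequences (records
are exchangeable within class), insertion/deletion evolution (gaps are
i.i.d., not block-structured), realistic inter-column dependence, and the
actual physicochemical structure of receptor domains. Results on synthetic
data validate the machinery, not biological performance claims.

## Problem sizes used in the checks

The package's own test suite and acceptance script run the study-scale
pipeline at $N = 1199$, $L = 259$ with a 128–128 network, 15 pretraining
and 120 fine-tuning epochs — a deliberately compact training budget that
the strong-signal synthetic conditions support (accuracy is within a point
or two of larger budgets at a fraction of the cost). Oracle suites use
1,000 random confusion matrices, 30-residue sequences for the brute-force
covariance comparison, and 90-residue sequences for the wavelet comparison.

## Known limitations

- The PseAA correlation-factor convention (amphiphilic, $w = 0.05$,
  population-SD standardization) is one of several in circulation; numeric
  equality with any specific external implementation is not guaranteed,
  only the documented definition.
- The Gaussian-visible RBM assumes approximately unit-variance inputs;
  heavy-tailed feature distributions after min-max scaling can slow CD
  convergence (the divergence guard raises a training error suggesting a
  smaller rate).
- `class::knn` breaks exact distance ties randomly; with continuous
  features this is immaterial, but discrete feature tables could make 1-NN
  results depend on the tie stream.
- Multi-label assignment (a sequence belonging to several subfamilies) is
  out of scope; every record carries exactly one label.
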