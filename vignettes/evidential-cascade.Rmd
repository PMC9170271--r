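---
title: "An evidential cascade for per-residue secondary-structure prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An evidential cascade for per-residue secondary-structure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sscascade)
```

## The model

`sscascade` predicts the eight DSSP secondary-structure states (or their
three-state coarsening) per residue with a *multistage combination
classifier*: two classifiers of different capacity share one feature
extractor, and each residue is routed to the classifier suited to its
difficulty.

Every residue is encoded as 50 features: a 21-dimensional identity
one-hot (20 standard residues plus `X`), the 21 logistic-rescaled
substitution scores of a sequence profile, 7 physicochemical properties
(steric parameter, polarizability, van der Waals volume, hydrophobicity,
isoelectric point, helix and sheet propensity), and a conservation
score.  The conservation score inverts the logistic rescaling, converts
scores $S_i$ to aligned-residue probabilities
$L_i = \exp(S_i \lambda_u)\,P_i$ against background frequencies $P_i$
(with $\lambda_u = 0.3176$), renormalises onto the simplex and
summarises the column as $R = \log 20 + \sum_i L_i \log L_i$, which
ranges from 0 (uninformative column) to $\log 20$ (perfectly conserved).

The extractor stacks:

1. one affine projection per feature block (widths 64/128/32/16,
   dropout at training time), concatenated to width 240;
2. three same-length 1-D convolutions with rectified-linear activation,
   kernel sizes 5/9/13 and 64 channels each, concatenated to the *easy
   feature* $c$ (width 192) — local context at three scales;
3. a bidirectional gated recurrent pass over $c$ (hidden size 256 per
   direction) giving global contexts $h$ (width 512);
4. sequential attention: position scores
   $\tilde\alpha_t = s_a^\top \tanh(W_a h_t + b_a)$ are softmax-normalised
   over real residues into weights $\alpha_t$, and
   $\alpha_h = \sum_t \alpha_t h_t$ summarises the sequence.

The *easy classifier* is a single affine map on $c$.  The *hard
classifier* is a 512/1024 rectified-linear perceptron (dropout at
training time) on the concatenation $v = [c, h, \alpha_h]$, with the
per-sequence summary $\alpha_h$ tiled across positions — the only
shape-consistent reading of concatenating a sequence-level vector with
per-residue features.

## Evidential difficulty and routing

The easy classifier's pre-softmax outputs are read as *evidence*:
$e_z = \max(\hat y_z, 0)$, Dirichlet parameters $\alpha_z = e_z + 1$,
strength $S = \sum_z \alpha_z$, expectation $p_z = \alpha_z / S$.  The
difficulty signal is the base-2 Shannon entropy $H(p)$.  A confident
opinion such as $\alpha = (14.10, 1.33, 1.21)$ concentrates $p$
($H \approx 0.77$ bits); a vague one such as $\alpha = (2.24, 1.82,
1.78)$ stays near uniform ($H \approx 1.58$ bits).

During training a residue is routed *easy* iff the easy prediction is
correct **and** $H(p)$ lies strictly below the `per`-th percentile of
the batch's entropies (`per` of 15, 30 or 35; default 30).  At test
time labels are unavailable, so routing uses the entropy alone against
a frozen threshold: we freeze the running mean of the realised
per-batch training thresholds, because the percentile rule defines a
threshold per batch but test-time routing needs a fixed number.
Easy-routed residues take the easy classifier's call; hard-routed
residues take the hard classifier's.

Four variants share this skeleton: `mccm_dir` (entropy routing — the
deployable model), `mccm` (label routing, a diagnostic upper bound),
`mccm_easy` (label routing with no backpropagation through the hard
loss), and `mccm_conf` (an early-exit baseline that routes on softmax
confidence against a fixed 0.9 threshold).  For the confidence variant
we adopt the early-exit semantics — a residue exits early, i.e. stays
easy, when it is classified correctly *and* confidently — since exiting
on *low* confidence would route the classifier's worst residues away
from the stronger head.  An easy-only ablation `mccm_c1` (convolutional
features plus the easy head alone) serves as the reference point for
the cascade's value.

The objective sums four terms,
$\mathcal{L} = \mathcal{L}^{CE}_{easy} + \beta L^{dir}_{easy} +
\mathcal{L}^{CE}_{hard} + \beta L^{dir}_{hard}$:
cross-entropy plus an evidential loss per classifier, the easy terms
over all real residues, the hard terms over hard-routed residues only.
The evidential loss is the expected Brier score under the Dirichlet
opinion, $\sum_z (y_z - p_z)^2 + p_z(1-p_z)/(S+1)$.  We use the divided
form of the variance term: it is the exact expectation
$\mathbb{E}_{q \sim \mathrm{Dir}(\alpha)} \sum_z (y_z - q_z)^2$, which
the test suite confirms against a Monte-Carlo oracle.  Because the hard
terms are non-negative and added on top of the easy ones, a hard-routed
residue always contributes at least as much loss as it would under the
easy head alone — difficulty accumulates penalty, which is the point of
the cascade.

Both losses of each classifier are computed from the same logits
(softmax for the cross-entropy, rectified evidence for the Dirichlet
head); nothing in the architecture suggests separate heads.  Ties in
argmax readouts break toward the lowest class index.

## Training

Adam with learning rate 0.0005 optimises all parameters; gradients of
both classifiers flow into the shared extractor, except in `mccm_easy`,
where the hard-loss gradient is withheld (its hard head still produces
logits, so both readouts remain available).  Dropout (probability 0.5
by default) applies to the four block projections and the perceptron
layers only.  Batches are formed by protein; losses are normalised by
real-residue counts, and padding positions are excluded from every
loss, routing decision and metric (their feature rows are zero by
construction, so no stage can see padding content).  All randomness —
initialisation (uniform fan-in), shuffling, dropout — flows from one
integer seed, and runs are bit-reproducible given it.  Training aborts
with a diagnostic on a non-finite loss.  No learning-rate schedule or
early stopping is applied; the epoch count is a configuration knob.

The gate algebra of the recurrent unit follows the reference
formulation exactly, including the placement of the candidate bias
inside the recurrent product
($\tilde h_t = \tanh(W_{c\tilde h} c_t + W_{h\tilde h}(r_t \odot h_{t-1}
+ b_{\tilde h}))$), which is equivalent to the common form up to a bias
reparameterisation.  The recurrent layer is bidirectional, with the two
directions' outputs concatenated.  Same-length convolution uses
centred zero padding, because per-residue labelling needs one output
per input position.  Every backward pass is hand-derived matrix
algebra; a finite-difference check over the full objective, for every
variant, anchors its correctness in the test suite.

## Data formats

Benchmark data arrives as packed dense arrays: one row of
$700 \times 57$ channels per protein (22 identity channels including
`NoSeq`, 9 label channels including `NoSeq`, 2 terminal flags, 2
solvent-accessibility channels, 22 profile channels).  The reader drops
the `NoSeq` channel from the identity and profile blocks (keeping the
20 standard residues plus `X`), masks and trims padding, and errors on
real residues with empty label channels.  Terminal and solvent channels
are read but unused — the model consumes exactly the four feature
groups above.  The background frequencies for the conservation score
default to the Robinson–Robinson amino-acid frequencies, and the
physicochemical table to the standard 7-parameter descriptor set; both
are arguments, since neither is intrinsic to the model.

## The synthetic generator

`generate_proteins()` emulates what the method assumes about real data,
at testable scale and with ground truth attached:

* **labels with run structure** — a short-memory Markov chain whose
  stationary distribution matches the benchmark Q8 frequencies (30.86 %
  helix, 21.25 % strand, …), so convolutional and recurrent stages have
  genuine local and global context to exploit;
* **easy residues** — profile scores drawn from class-conditional
  Gaussians whose centroids sit 6 noise-SD units apart (orthogonal
  directions in the 20-dimensional score space), plus a mild
  class-conditional residue-identity preference: Bayes-separable from
  local features alone;
* **hard residues** — the same construction with centroids shrunk until
  their pairwise distance is `hard_overlap` (default 1.5): ambiguous
  from local features, but partly recoverable from sequence context;
* **label noise** — each emitted label is replaced by a uniform draw
  with probability `label_noise`.

Centroids live in the profile-*score* space rather than the raw
50-dimensional feature space so that generated records are valid packed
records (one-hot rows, profile entries strictly inside (0,1)) and
round-trip exactly through the fixture writer and the benchmark reader.
Planted easy/hard flags ride along in an otherwise unused channel of
the packed layout.

What passing tests on this generator do **not** show: real proteins are
not a mixture of two Gaussian difficulty modes, their label runs are
not first-order Markov, and profile columns are correlated in ways the
generator ignores.  The synthetic results certify the machinery —
routing separates planted difficulty, the cascade's extra capacity
reaches the residues that need it — not benchmark-level accuracy.
Reproducing published benchmark accuracies requires the external
training corpus and long training, and is supported as an optional
workflow through the same reader, configurations and CLI.

## Scaled problem sizes

The behavioural checks run at desk scale, chosen once: 50 proteins of
90–110 residues, a proportionally narrowed extractor (block projections
12/16/6/4, 12 convolution channels, recurrent hidden size 16,
perceptron 32/32 — the same shape at roughly a hundredth of the
parameters), batches of 2 proteins and 25–60 epochs.  At this scale the
separable task is mastered (Q8 ≥ 95 %), entropy routing separates
planted difficulty after a few epochs, the full objective dominates the
easy-only backpropagated loss at every epoch, and across five seeds the
entropy-routed cascade's median hard-residue accuracy at least matches
the easy-only ablation.  `scripts/acceptance.R` recomputes all of these
from scratch under a caller-supplied seed.

## Known limitations

* Two cascade stages only; deeper cascades are out of scope.
* Sequence profiles must be provided (packed arrays); no alignment tool
  is wrapped to build profiles from raw sequences.
* The frozen-threshold rule is the simplest consistent reading of a
  per-batch percentile; calibrating it on a validation split would be a
  natural extension.
* Pure-R training is practical at desk scale and for moderate corpora,
  not for GPU-scale experiments.
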