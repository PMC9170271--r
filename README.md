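# sscascade

Per-residue protein secondary-structure prediction with a multistage
combination classifier.  Most residues of a protein are easy to label
from local sequence features; a minority — transitions between
structural elements, rare states such as π-helices and β-bridges — are
not, and a single classifier trained on everything spends its capacity
on the easy majority.  `sscascade` trains two classifiers of different
capacity over one shared feature extractor and routes each residue to
the right one with an *evidential* difficulty rule, so that the hard
residues accumulate extra loss and extra model capacity.

It is aimed at structural bioinformaticians working with the standard
packed benchmark encodings (700 residue slots × 57 channels per
protein, as distributed for the CullPDB/CB513 benchmarks) and at anyone
studying difficulty-aware (early-exit / cascade) training on sequence
labelling.

## The model

Each residue is encoded as 50 features (21 one-hot + 21 profile + 7
physicochemical + 1 conservation).  A shared extractor produces an
*easy feature* `c` (per-block linear projections, then multiscale 1-D
convolutions with kernels 5/9/13) and a *hard feature*
`v = [c, h, α_h]` (bidirectional GRU contexts `h` plus a sequential
attention summary `α_h`).  A linear head classifies from `c`; a
512/1024 multilayer perceptron classifies from `v`.

The easy head's rectified logits are treated as Dirichlet evidence:

    α_z = max(ŷ_z, 0) + 1,   S = Σ_z α_z,   p_z = α_z / S

and the base-2 entropy `H(p)` measures difficulty.  During training a
residue stays *easy* iff it is classified correctly and `H(p)` falls
below the `per`-th percentile of batch entropies; at test time the
entropy alone is compared against a threshold frozen from training.
The objective is

    L = CE_easy + β·Dir_easy + CE_hard + β·Dir_hard

with the hard terms taken over hard-routed residues only, and
`Dir` the expected Brier score under the Dirichlet opinion,
`Σ_z (y_z − p_z)² + p_z(1−p_z)/(S+1)`.

Variants: `mccm_dir` (entropy-routed, deployable), `mccm` (label-routed
upper bound), `mccm_easy` (no hard-loss backprop), `mccm_conf`
(confidence-routed early-exit baseline), `mccm_c1` (easy-only
ablation).  Evaluation reports Q8/Q3 accuracy, per-state recall and
percent-of-total confusion matrices.

## Worked example

```r
library(sscascade)

# a seeded synthetic dataset with planted easy and hard residues
spec <- synthetic_spec(n_proteins = 12, length_range = c(40, 60),
                       class_set = "Q3", easy_fraction = 0.6,
                       hard_overlap = 1, seed = 73)
recs <- generate_proteins(spec)

cfg  <- extractor_config(branch_hidden = c(12, 16, 6, 4), conv_hidden = 12,
                         recurrent_hidden = 16, attention_hidden = 12,
                         mlp_hidden = c(32, 32))
m    <- fit_mccm(recs, classes = "Q3", extractor = cfg,
                 control = train_config(epochs = 40, batch_size = 2, seed = 3,
                                        dropout = 0.1, variant = "mccm_dir",
                                        track_scores = FALSE))
m
#> <mccm_model mccm_dir: Q3 classes, seed 3, frozen threshold 1.536 bits>
#>   trained 40 epochs, final total loss 2.3004

pred <- predict(m, recs)
tapply(pred$entropy, pred$routed, mean)
#>     easy     hard
#> 1.417433 1.560144
q_score(pred$true, pred$pred, k = 3)
#> [1] 86.06965

hard <- unlist(lapply(recs, function(r) attr(r, "hard")[r$mask]))
round(100 * c(easy = mean((pred$true == pred$pred)[!hard]),
              hard = mean((pred$true == pred$pred)[hard])), 2)
#>  easy  hard
#> 91.48 77.82
```

The frozen threshold (bits) is the running mean of the per-batch
entropy percentiles seen in training; `routed` marks which classifier
produced each call, and hard-routed residues carry visibly higher mean
entropy (1.56 vs 1.42 bits).  40 % of these residues were generated
with overlapping class centroids (`hard_overlap = 1`), and the
per-difficulty accuracies show exactly the planted gap the router is
meant to find.

A command-line interface covers the same pipeline
(`inst/cli/sscascade simulate|stats|train|evaluate|predict`); every run
writes a `manifest.json` beside its outputs.

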