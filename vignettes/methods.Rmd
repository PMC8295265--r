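---
title: "Profile-based disorder and disorder-function prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based disorder and disorder-function prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fldpr)
```

## The prediction problem

Intrinsically disordered regions (IDRs) are protein segments that lack a
stable tertiary structure under physiological conditions. Beyond knowing
*where* a chain is disordered, curated resources annotate *what* the
disordered segment does — the four most commonly annotated disorder
functions being protein binding, DNA binding, RNA binding, and flexible
linkers. `fldpr` implements a complete prediction stack for both tasks:

1. a per-residue **sequence profile** (45 named channels standing in for
   the outputs of upstream sequence-analysis tools),
2. a **three-level feature encoding** of that profile,
3. a small **feedforward deep network** producing per-residue disorder
   propensities (with a logistic-regression twin on identical features),
4. four **random forests** assigning disorder functions *inside* the
   predicted disordered regions, and
5. the **evaluation protocol**: pooled per-residue ROC-AUC/MCC/F1,
   fully-disordered-protein calling, and a paired half-dataset
   resampling significance test.

The package does not run any upstream profile tool. Profiles arrive as
tab-separated tables (or from the bundled synthetic generator), which
makes every stage trainable and testable with no external downloads.

## The profile and its schema

A `ProfileSchema` names the channels and partitions them into groups.
The default 45-channel schema comprises:

| group | channels | count |
|---|---|---|
| `pssm` | logistic-squashed substitution scores, one per amino acid | 20 |
| `conservation` | entropy-based conservation derived from the PSSM | 1 |
| `secondary_structure` | helix/strand/coil probabilities + binaries | 6 |
| `iupred` | long and short disorder propensities + binaries | 4 |
| `function_predictors` | protein/DNA/RNA-binding, MoRF and linker baselines (propensity + binary each) | 10 |
| `physchem` | hydrophobicity, charge, polarity, volume (min–max scaled) | 4 |

Every channel lives in [0, 1]. The channel count is pinned down by the
network's input width: with residue window $r = 5$, one window-level
mean, and a protein-level block of $P + 3$ features, the encoder
produces $rP + P + (P + 3) = 7P + 3$ features, and $7P + 3 = 318$
forces $P = 45$. The exact membership of the 45 channels is this
package's documented default — the schema is a first-class object and
alternative breakdowns can be swapped in.

Two profile computations are performed in-package. Conservation is
defined as $1 - H(p)/\ln 20$ where $p$ is the softmax of the 20 PSSM
scores and $H$ is Shannon entropy: a flat row scores 0, a single
dominant residue approaches 1, and adding a constant to all scores
changes nothing. Raw PSSM scores are squashed by the logistic
$x \mapsto 1/(1+e^{-x})$ to match the [0, 1] range of the other
channels. Both choices are deliberately simple, monotone and exactly
testable; conservation in particular follows the standard
normalised-entropy construction because the upstream literature fixes
only "entropy-based", not a formula.

## Three-level feature encoding

For residue $i$ the encoder emits:

* **residue level** — raw channel values at the $r$ positions centred
  on $i$ ($r = 5$ for disorder, $1$ for functions);
* **window level** — per-channel arithmetic means over a wider centred
  window ($15$ for disorder, $11$ for functions);
* **protein level** — per-channel whole-chain means, a normalised
  length $\min(L, 10^4)/10^4$, and the terminus distances $(i-1)/L$
  and $(L-i)/L$.

Window slots that fall outside the chain are filled with the
**protein-level channel mean** rather than zero. Zero-filling would
fabricate "low signal" at the termini; mean-filling keeps the exact
invariant that a constant profile encodes to that constant at every
position and level, and makes the window mean collapse to the chain
mean whenever the window covers the whole chain (width $\ge 2L - 1$).
The length cap and $L$-normalised distances are this package's own
choices — bounded features that need no dataset statistics. Column
order is fixed (residue block position-major, then window, then
protein) and recorded, together with the schema, in a plain-text
*encoding fingerprint* stored inside every trained model; models refuse
features produced under a different schema or encoding.

## The disorder models

The deep model is a feedforward network: input of 318 nodes, dropout
0.2, a 64-node ReLU layer, dropout 0.2, an 8-node ReLU layer, and one
sigmoid output emitting the disorder propensity. Training controls are
not dictated by the architecture, so the package fixes reproducible
defaults: adaptive-moment gradient descent (learning rate $10^{-3}$,
batch 256), binary cross-entropy with inverse-frequency class weights
(disorder is the minority class in curated data), at most 200 epochs
with early stopping when validation ROC-AUC has not improved for 10
epochs, and the best-epoch weights retained. Every stochastic step —
weight initialisation, batch shuffling, dropout masks — draws from one
seeded stream, so a seed fixes the model bitwise. The logistic twin is
fit on the *identical* feature matrix (ridge-regularised at a tiny
fixed penalty for numerical stability on separable data); on synthetic
data with a linear signal both kinds reach the same quality, which is
the expected behaviour when the information lives in the profile and
encoding rather than in the model class.

Binary calls use a strict rule: disordered iff propensity $>$
threshold. The threshold is chosen on the validation set by scanning
all unique propensity values and maximising the F1 of calling positive
*at or above* each candidate (ties toward the smaller candidate). The
inclusive scan paired with a strict downstream rule is deliberate: the
scan must be inclusive for the all-propensities-equal case to have a
sensible answer (the single candidate then denotes the all-positive
prediction), while the strict rule follows the stated binarisation
convention; with continuous propensities the boundary value has measure
zero, so the pairing is consequence-free in practice.

## Function models and the alignment guarantee

Each of the four disorder functions gets its own random forest, trained
only on residues the disorder model called disordered: positives are
residues inside a region annotated with that function, negatives are
all other predicted-disordered residues (the natural negative set once
the training universe is "inside putative IDRs"). Hyper-parameters
(trees in {100, 250, 500}, depth in {5, 10, unlimited}) are chosen by
mean ROC-AUC under 3-fold cross-validation, the winning point is refit
on all rows, and the threshold is selected on the winning point's
out-of-fold predictions. At prediction time, function propensities are
computed only inside predicted IDRs; outside them the propensity is
reported as 0 and the binary as 0. This masking is the package's
central consistency guarantee: **no residue can be function-positive
while being called structured**, enforced both by construction and by
the `PredictionResult` validity check. Reporting 0 rather than omitting
outside-IDR values keeps the prediction CSV rectangular; the binary
track carries the same information.

## Evaluation protocol

Metrics are computed over residues pooled across proteins (a
per-protein-averaged variant exists but is flagged non-default). The
ROC is traced by thresholding at every unique propensity value the
predictor produced; grouping tied propensities at one threshold is
equivalent to giving half credit to tied positive–negative pairs, and
the implementation is tested against an exhaustive pair-ordering
oracle. MCC with a zero denominator is reported as 0 with an explicit
flag instead of NaN.

A protein is *fully disordered* when disordered residues cover at least
95% of its chain; the same rule on predicted binaries gives the
predicted status. Published phrasings of the rule differ between "over"
and "at least", so the comparator is configurable; the default is
$\ge$, which makes a 19-of-20 protein fully disordered.

Two predictors are compared by resampling half the proteins without
replacement 10 times — the same half for both predictors, a paired
design — recomputing the metric per replicate, and testing the 10
paired differences: Anderson–Darling at 0.05 decides between a paired
t-test (normal) and a Wilcoxon signed-rank test, two-sided. All-zero
differences (a predictor against itself) give p = 1 with a flag.
Replicates on which the metric is undefined (a single-class half) are
redrawn and the redraw count recorded.

One subtlety matters for calibration studies of this procedure. A
*frozen* pair of random predictors genuinely differs on any fixed
dataset — their full-dataset AUC gap is a real, resampling-robust
offset — and the test correctly detects it far more often than 5%.
The ≈5% null therefore requires predictors that are *stochastic at
evaluation time*, so the replicate differences are mean-zero; the API
accordingly accepts function-valued predictors that are queried afresh
on each replicate, and the calibration test in the suite uses them
(measured rejection ≈ 4% over hundreds of null comparisons).

## Ablation machinery

Six configurations each remove exactly one component from the full
disorder encoder: the function-predictor channels, the protein level,
the window level, the residue level, the PSSM channels, or the IUPred
channels. Group removals drop the group's channels from all levels
(hence cost $(r + 2) \times |\text{group}|$ columns); level removals
drop the block. The PSSM ablation removes the 20 raw substitution-score
channels and leaves the derived conservation channel in place —
conservation is a one-number summary that a deployment could cache even
where raw PSSM columns are unavailable — giving the closed-form count
$318 - 7 \times 20 = 178$ (and $318 - 48 = 270$ for the protein-level
removal). Each ablated model is retrained from scratch with the same
training configuration and seed regime, never weight-masked, and
compared to the full model with the resampling test.

## The synthetic generator

The generator emulates the statistical skeleton of curated
disorder data: chain lengths uniform in a range; a two-state Markov
disorder track (stay probabilities 0.95/0.95 by default, i.e. geometric
segments of mean length 20 and a stationary disorder fraction of 0.5);
a configurable fraction of fully disordered chains (default 5%, the
class of interest for fully-disordered calling); informative channels
generated as `clip01(effect * label + bias + noise)` where `bias` is a
per-protein Normal(0, sd) offset shared across informative channels and
`noise` is residue-level Gaussian; nuisance channels iid Uniform(0, 1);
function regions carved as random contiguous sub-intervals of
disordered segments (so function annotations are always subsets of
disorder, as in curated data); sequences uniform over the 20 letters.
Clipping (rather than a logistic squash) preserves the linear effect
structure, which is what makes the deep network and the logistic twin
comparable on these data.

Four named fixtures define the study conditions used throughout the
test suite:

* **separable** (200 proteins): effect 1.0 on one channel, noise 0.1 —
  both model kinds must exceed held-out AUC 0.95;
* **null** (100 proteins): no effects — trained models must stay within
  AUC [0.4, 0.6];
* **protein_level_signal** (150 proteins): the main signal channel is
  buried in heavy residue noise (sd 0.35) on top of a per-protein bias
  (sd 0.2), with small side-effects in the PSSM, IUPred and
  function-predictor groups. Individual residue values are weak, while
  the whole-chain mean cleanly estimates each protein's bias and
  disorder load — so removing the protein-level block must hurt most.
  This design was chosen over a low-noise variant in which the
  residue-level block (225 of 318 columns) dominated instead; with the
  noise-buried signal the intended ordering is stable across generator
  seeds. The ablation analysis on this fixture caps training at 60
  epochs, which is past convergence at this data size;
* **function_toy** (150 proteins): one dedicated channel per disorder
  function plus a disorder channel.

What these fixtures deliberately do **not** emulate: amino-acid
compositional bias of real IDRs, realistic PSSM score distributions,
inter-channel correlations of real profile tools, and annotation
incompleteness. Passing tests on them demonstrates that the machinery
learns what it is pointed at, recovers planted structure, and honours
its invariants — not that any particular accuracy level carries over to
curated data.

## Numerical and degenerate-input choices

* MCC denominator 0 → value 0 plus flag; F1 with no positives
  anywhere → 0 plus flag.
* Single-class truth sets make protein-level MCC undefined: reported
  as NA with a warning, F1 still returned.
* Thresholds: selection is inclusive, binarisation strict (see above).
* Length-1 chains encode to their own values at every window slot
  (mean-fill degenerates to the single residue's values).
* Anderson–Darling is undefined on constant samples: constant non-zero
  differences fall back to the Wilcoxon branch with a flag; all-zero
  differences short-circuit to p = 1.
* All grid ties (network and forest) break toward the earlier, smaller
  configuration so reruns are stable.

## Problem sizes

The shipped study sizes are the fixture sizes above: disorder-model
checks train on the 200-protein separable fixture (~12k residues × 318
features), the ablation analysis trains seven networks on the
150-protein bias fixture, the calibration study runs 200 null
comparisons of 10 replicates each, and the oracle checks enumerate
ROC inputs exhaustively up to 12 residues. These sizes were chosen so
the full suite demonstrates every claim at desk scale while each
individual check remains statistically decisive (margins of several
standard errors in the stochastic assertions).

## Known limitations

* The package consumes profile tables; it neither runs nor emulates
  the numeric distributions of the upstream tools that would produce
  them for real proteins.
* The 45-channel membership is a documented default consistent with
  the 318-feature input, not a uniquely determined fact.
* Function forests are serialised with R's native serialisation inside
  model directories; the disorder model directory is plain text.
* Training the deep network is single-threaded, vectorised base R —
  adequate at the shipped sizes, not tuned for large-scale retraining.
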