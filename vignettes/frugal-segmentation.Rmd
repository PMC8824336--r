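---
title: "Training multi-class segmentation networks on partially labeled data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training multi-class segmentation networks on partially labeled data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biomedical segmentation datasets are frequently *heterogeneously* labeled:
different images carry ground-truth masks for different subsets of the
classes, because labels were added in stages, by different groups, or only
where an expert was confident. Standard supervised training assumes every
sample is labeled for every class, so heterogeneous data is usually discarded
or truncated to the common label subset.

frugalseg trains a softmax encoder–decoder on such data directly. Each sample
carries, besides its image $x$ and ground truth $\tilde Y \in \{0,1\}^{w
\times h \times C}$, a binary mask vector $m \in \{0,1\}^C$ flagging which
class masks exist. Two loss components consume this triple:

* **Masked Dice loss** (channel-wise, "horizontal" optimization). With the
  soft Dice coefficient
  $$DSC_c = \frac{2\sum_{u,v}\tilde y_{u,v,c}\,\hat y_{u,v,c} + \epsilon}
                 {\sum_{u,v}\tilde y_{u,v,c} + \sum_{u,v}\hat y_{u,v,c} + \epsilon},
  \qquad \epsilon = 10^{-7},$$
  the loss averages $1 - DSC_c$ over the *labeled* channels only:
  $L_{DSC} = \sum_c m_c (1 - DSC_c) / \sum_c m_c$. The $\epsilon$ sits in
  both numerator and denominator, so an empty channel predicted empty scores
  a perfect 1. A sample with no labeled channel at all is rejected with an
  error rather than silently contributing $0/0$.

* **Class-asymmetric loss** (per-pixel, "vertical" optimization).
  Segmentation classes are mutually exclusive: a pixel known to belong to
  labeled class $c$ cannot belong to any unlabeled class. CAL charges the
  activated probability mass that the prediction places in unlabeled channels
  at such pixels:
  $$CAL_c = \sum_{u,v} \tilde y_{u,v,c} \sum_{z \neq c} f(\hat y_{u,v,z})(1 - m_z),
  \qquad L_{CAL} = \sum_c m_c\, CAL_c,$$
  with $f$ the logistic sigmoid by default. Note $f(0) = 0.5$: an unlabeled
  channel contributes $0.5$ per labeled pixel even at probability zero, a
  constant offset that does not affect gradients' sign but keeps $L_{CAL}$
  positive.

The combined objective is $L = (1-\alpha) L_{DSC} + \alpha L_{CAL}$ with
$\alpha \in [0,1)$; $\alpha = 1$ is rejected because CAL alone says nothing
about labeled channels.

**Background handling.** When the background class is defined as "none of the
foreground classes", a partially labeled sample cannot distinguish background
from unlabeled foreground. The background channel is therefore excluded from
CAL — from the outer sum and equally from the inner sum over $z$, where the
same ambiguity would otherwise re-enter. The loss configuration takes the
background index explicitly; nothing is inferred from channel contents.

**CAL scale.** As written, $CAL_c$ is a pixel-count sum: on a $256 \times
256$ image it is $O(10^3)$–$O(10^4)$ while $L_{DSC} < 1$, so a mid-range
$\alpha$ would make the combined gradient essentially pure CAL.
`loss_config(cal_normalize = TRUE)` divides by $w \cdot h$, putting both
components on comparable scales; the plain sum remains the default evaluator
semantics, but every training harness in this package normalizes. The
`alpha = 0.4` harness default follows the loss-weighting experiment's
optimum.

**Per-sample batching.** The losses are defined per sample, and the mask
vector varies within a batch. The training loop computes $L$ per sample with
that sample's $m$ and averages over the batch, which keeps the
$\sum_c m_c$ normalization correct for every sample.

## The Performance Frugality Ratio

$PFR(M) = M / n$ divides a statistic $M$ (mean DSC, mean IoU) by the number
of available labels $n = S - P$ ($S$ sample–label pairs, $P$ dropped labels).
Two models with equal DSC differ in PFR if one needed fewer labels. When
classes lose different label counts (transfer, merging), the package uses the
mean per-class drop count for $P$.

## The heterogeneous-label generator

`heterogeneous_view()` turns a fully labeled dataset into a partially labeled
one *online*: for each class in the eligible set, exactly $P =
\mathrm{round}(\rho S)$ samples (rounding half away from zero) lose that
class's mask, drawn independently per class and deterministically from the
seed. Access goes through `apply_drops()`, which zeroes dropped channels,
sets $m$, and recomputes the background channel as the complement of the
*present* foreground masks — reproducing the real pathology that background
"grows" when labels are missing. A strict mode instead marks the background
unavailable whenever a foreground mask is missing. A sample memory records
each sample's realized masks at first access, so repeated queries within one
iteration (oversampling) are bit-identical; `reset_memory()` starts the next
iteration.

Two persistence modes interpret "iteration": `per_epoch` redraws the dropped
subset every epoch (the online-generator reading), `whole_training` fixes one
plan for the whole run, behaving like a static partially labeled dataset. The
experiment harnesses use `whole_training` so that a configuration's label
budget is a fixed, auditable quantity; the loss dynamics were checked under
both modes and the qualitative results do not differ. The drop share is
specified relatively ($\rho$) rather than absolutely, since online use cannot
assume a known dataset size; the plan is drawn over the sorted sample ids so
it is independent of presentation order and identical across processes for a
fixed seed.

## Network and optimization

`build_network()` constructs a symmetric convolutional encoder–decoder:
3×3 'same' convolutions with instance normalization and ReLU, 2×2 max
pooling, nearest-neighbor upsampling with skip-connection concatenation, and
a 1×1 convolution + per-pixel softmax head. The default configuration (depth
4, base width 64, two convolutions per stage, 256×256 input) carries about
$3.1 \times 10^7$ parameters; `tiny_network_config()` (depth 2, base width 8,
one convolution per stage, 64×64 input) is the desk-scale variant used
throughout the tests.

Two choices matter for stability and deserve explanation:

* **Instance normalization.** Soft Dice through a softmax has *absorbing
  states*: if a channel's probability reaches (numerically) zero at some
  pixels, its gradient there vanishes and it can never recover. Without
  normalization the activation scale grows across stages, logit gaps reach
  $O(10)$ within an epoch, and under conflicting supervision — exactly what
  heterogeneous labels produce, since a sample missing class $c$ labels
  $c$'s pixels as background — whole classes die irreversibly. Per-channel
  instance normalization bounds the activations, and a near-zero-scale
  initialization of the softmax head starts all channels alive at a
  near-uniform prediction. A small decoupled weight decay (default $10^{-3}$)
  additionally discourages logit drift.
* **Adam, learning rate.** `train_config()` defaults follow the common
  protocol for this problem family (Adam at $10^{-3}$, batch size 11, early
  stopping on the validation Dice loss with patience 5 and best-weight
  restoration, at most 50 epochs). Validation is monitored on held-out
  training samples with their full labels — the monitor should measure
  segmentation quality, not the dropping artifact. The experiment harnesses
  instead use a fixed-epoch budget (8 epochs, batch 10, learning rate
  $5\times10^{-3}$, no validation split), trading early stopping for exact
  reproducibility and a predictable runtime at desk scale.

The gradient of $L$ in the prediction is analytic
(`combined_loss_grad()`) and finite-difference checked in the tests, as is
the full backpropagation through the network. One subtlety: the
"gradient masking" property — unlabeled channels receive no gradient when
$\alpha = 0$ — holds exactly for derivatives *in the prediction values*. It
cannot hold for logits under a softmax head, where any logit perturbation
moves the labeled channels' probabilities through the normalization; the
package states and tests the property in prediction space.

## The synthetic benchmark

`synth_config()` generates RGB images containing three adjacent, pairwise
disjoint ellipses on a dark background — a schematic of a three-chamber
cardiac segmentation task (atrium, ventricle, bulbus + background), with the
third class smaller and thinner to emulate a hardest class. Adjacency is
deliberate: CAL only acts where a labeled class's pixels could be confused
with an unlabeled channel, so the shapes must be near each other. Appearance
varies in two ways: per-sample uniform color jitter (half-width 0.12, the
analogue of chambers appearing differently depending on blood fill) and
per-pixel Gaussian noise (sd 0.12). The jitter is not cosmetic — without
within-class appearance variability the task is linearly separable, the
network saturates within an epoch, and the remaining gradient comes entirely
from the mislabeled background of partially labeled samples, collapsing the
dropped class at any drop share. That regime does not resemble real data;
with the variability, moderate drop shares train essentially as well as full
labels and heavy drop shares collapse, matching what full-scale experiments
on real recordings report.

The benchmark does *not* emulate texture, shape variability beyond ellipses,
occlusion, temporal correlation between frames of a recording, or annotation
noise. Passing trend tests on it therefore demonstrates the mechanics of the
objective and the generator, not performance on real imagery.

Default study conditions, chosen once for all desk-scale runs: 200 images of
64×64 pixels, 20% test split, three foreground classes (two for the
transfer/merge/loss-weight designs, which mirror the two-class reduction of
those experiments), three runs per configuration.

## Experiment designs

* **Ablation** (`run_ablation`): drop labels of all foreground classes
  equally at each $\rho$ in the sweep (which must include the $\rho = 0$
  baseline). Performance stays near baseline for moderate $\rho$ and
  collapses at high $\rho$, where the network converges to predicting the
  (over-represented) background everywhere.
* **Transfer** (`run_transfer`): one class fully labeled, the "new" class
  partially labeled; the retained class's performance should be flat across
  the sweep.
* **Merge** (`run_merge`): the training set is split into two single-class
  datasets at a proportion; both sides are drawn at equal rates per epoch,
  oversampling the minority side with replacement, and the sampler keeps an
  audit of per-side draw counts.
* **Loss-weight sweep** (`run_alpha_sweep`): the transfer setup at a fixed
  drop share (default 0.5), sweeping $\alpha$ with the dataset and drop plan
  paired across $\alpha$ values within a run.

Statistics (per-class DSC and IoU on argmax masks, foreground means, and
mean PFR) are always computed on the fully labeled test split;
heterogenization never touches test labels. Result tables carry mean and
standard deviation over the configured runs, with per-run rows attached for
reproducibility from the logged seeds.

## Numerical conventions and degenerate inputs

* Arrays are `(h, w, C)`; the background channel is last by convention in
  all pipelines, but every function takes the index explicitly.
* Mask PNGs are binarized at half intensity (128 on 8-bit files) on read and
  written as exact 0/255.
* Argmax ties break toward the lowest class index.
* Empty-vs-empty overlaps: DSC 1 (via $\epsilon$), IoU 1 (by definition).
* Augmentation applies one shared geometric transform per draw to the image
  (bilinear) and all masks (nearest, hence still binary and mutually
  exclusive), with edge-replicating fill; with all ranges zero it is exactly
  the identity. The unusual printed ranges (rotations up to 0.3 degrees,
  shear up to 0.05 degrees) are reproduced as configured defaults.
* An all-background sample (every foreground mask dropped) is still emitted
  in default mode — its background channel remains a valid (if
  over-inclusive) label — and skipped in strict mode.

## Limitations

The trainer is a plain-R/Rcpp implementation intended for method study at
desk scale, not a GPU training stack; full-size configurations are provided
for parameter-count fidelity, not for routine training. PFR compares
configurations within one dataset; it is not comparable across datasets of
different sizes. No pseudo-labeling of dropped masks is attempted.
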