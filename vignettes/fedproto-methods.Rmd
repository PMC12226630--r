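---
title: "Prototype-guided federated denoising: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototype-guided federated denoising: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fedproto)
```

## The problem

Automated recognition of fetal ultrasound standard planes (abdomen, brain,
femur, thorax) is a four-class image classification task. When several
institutions train a model collaboratively by federated learning (FL), two
practical obstacles dominate: the clients have very different dataset sizes
(here a ~10:1 ratio), and their labels are noisy — annotation quality
varies, and a fraction of images carries the wrong plane label. Classical
centralized noise-filtering cannot be applied because raw images never
leave a client.

`fedproto` implements a two-step strategy around these constraints:

1. **On the large ("representative") client**: self-supervised contrastive
   pretraining (SimCLR-style) of an encoder `f(.)`; the latent structure of
   the resulting embeddings is then used to clean that client's labels by a
   thresholded k-nearest-neighbour consensus rule.
2. **For the small client**: the pretrained backbone and one mean embedding
   per class (a *prototype*) are shared — `n_classes x embedding_dim`
   numbers, no per-sample data. The small client discards its own labels
   entirely and re-labels each image by embedding several augmented views
   and letting each view vote for its nearest prototype's class.

FedAvg then trains a classifier across both clients with the cleaned /
pseudo-labels.

## Models and their parameters

### Contrastive pretraining

Two random transforms of an image give views $x_i, x_j$; the encoder and a
projection head map them to vectors, and the NT-Xent loss

$$\ell_i \;=\; -\log
 \frac{\exp(\mathrm{sim}(z_i, z_j)/\tau)}
      {\sum_{r \ne i} \exp(\mathrm{sim}(z_i, z_r)/\tau)}$$

(cosine similarity, temperature $\tau = 0.5$, averaged over all $2N$
anchors of a batch) pulls view pairs together against in-batch negatives.
`nt_xent_loss()` evaluates this with log-sum-exp stabilization; for a
single pair (no negatives) it is exactly 0.

The desk-scale encoder (`tinycnn`) is three 3x3 stride-2 convolution + ReLU
blocks followed by global average pooling; the pooled activation is the
embedding $z = f(x)$ (default length 64). All later stages consume these
backbone embeddings, not projection-head outputs: the head exists only for
the loss. The projection head is the standard SimCLR shape
Linear-ReLU-Linear. We do not use a ReLU-only output head: a ReLU-only
output can be exactly zero for some inputs, which leaves cosine similarity
undefined, and we observed precisely that failure during pretraining.

Two pretraining choices differ deliberately from the supervised recipe
below and are worth stating:

* **Optimizer.** Pretraining uses Adam (lr `1e-3`). SGD with momentum —
  stable for the supervised phase — converged erratically on the
  unnormalized tinycnn: on some seeds the contrastive loss barely moved
  and the downstream filter degraded badly. Large-scale contrastive
  training has the same issue and solves it with adaptive scaling (LARS);
  Adam is the desk-scale analogue. `contrastive_config(optimizer = "sgd")`
  restores plain SGD.
* **View family.** Contrastive views default to rotations up to 180
  degrees (plus flips, shifts up to 8 px, brightness/contrast 0.7–1.3).
  Plane orientation in ultrasound is arbitrary, and with ±15-degree views
  only, the encoder stays orientation-sensitive: a class whose instances
  appear at arbitrary angles (the femur bar) forms a multi-modal cluster
  whose mean is a poor prototype. Full-rotation views make the embedding
  pose-invariant; a random centred zoom (0.75–1.3, the resized-crop
  analogue) adds scale invariance for the same reason.

### k-NN consensus label cleaning

For every sample, `knn_consensus_filter()` finds its `k = 50` nearest
other samples by Euclidean distance in embedding space (self excluded;
distance ties broken by lower index, so results are deterministic). The
sample is kept iff at least `th = 40` percent of those neighbours carry
its own current label; otherwise it is discarded. Two readings of the rule
exist — keep/discard versus re-label to the neighbourhood majority — and
both are implemented (`mode = "consensus_keep"`, the default used in
experiments, and `"relabel_majority"`). `threshold_sweep()` reproduces the
threshold-selection protocol: thresholds 40–70 in steps of 10 at 0%, 20%
and 50% injected noise, reporting preserved% and residual-noise%.

The threshold is a trade-off: preserved% is provably non-increasing in
`th` (the keep condition only tightens), while residual noise decreases.
`th = 40` is the smallest value that still demands a clear consensus among
4 classes.

### Prototypes and augmented-view voting

The prototype of class $c$ is the arithmetic mean of the clean embeddings
labelled $c$:
$p_c = \tfrac{1}{|D_c|} \sum_{z \in D_c} z.$
The small client builds, for each image, the ensemble
$A(x) = \{R_1(x) = x, R_2(x), \ldots, R_T(x)\}$ (identity first,
$T = 8$ by default — the ensemble size is not pinned by the method, 8
balances cost and vote stability), embeds every view, assigns each view
the class of its nearest prototype, and takes the majority vote.
Vote ties break by the smallest summed view-to-prototype distance, then by
lowest class id; voting is unthresholded, so every sample receives a label
and nothing is discarded.

Two desk-scale choices:

* **Matching space.** The experiment pipeline L2-normalizes embeddings
  before computing prototypes and distances (cosine matching,
  `l2_normalize_rows()`). Cross-site acquisition shift is mostly
  photometric and moves embedding *magnitudes*; on the unit sphere the
  assignment is insensitive to that component, which raised cross-client
  pseudo-label accuracy substantially in our experiments. Raw Euclidean
  matching remains the API default (`view_ensemble_config(normalize =
  FALSE)`).
* **Voting views.** The ensemble uses photometric views only (horizontal
  flips plus brightness/contrast 0.85–1.15). Geometric voting views
  (rotations/shifts) consistently *lowered* vote accuracy at 64x64: the
  encoder is already pose-invariant, so they add only border-fill
  artifacts. Photometric views target exactly the nuisance the ensemble
  is meant to marginalize.

### Federated training

`run_federation()` implements FedAvg: every round broadcasts the global
parameters, each client runs 20 local epochs (desk default 5) of SGD
(momentum 0.9) on softmax cross-entropy, and the server aggregates with
weights $n_k / \sum_k n_k$ (client sizes counted after denoising /
pseudo-labelling). The learning rate follows a cosine-annealing
warm-restart schedule from 0.05 down to 1e-5 across each round's epochs,
restarting at every round boundary:
`lr(e) = lr_min + (lr_init - lr_min)(1 + cos(pi (e mod L) / L)) / 2`.
Linear mix-up ($\alpha = 0.5$, one Beta draw per minibatch, one-hot labels
mixed convexly) regularizes; batch size is 16. Momentum 0.9 and zero
weight decay are free parameters (the recipe does not state them).

Each client holds out a stratified 20% validation split; the returned
model is the aggregate of the round with minimum mean validation loss.
A single-client federation is bit-for-bit identical to centralized
training of that client (FedAvg of one update is the identity), which the
tests verify against an independent training loop.

### Evaluation

`f1_scores()` computes one-vs-rest per-class F1 ($2PR/(P+R)$, 0 when
$P+R=0$) and the unweighted macro mean over classes present in the test
split; scores are reported per country tag plus a federation mean.
`run_experiment()` reproduces the ablation grid: `local_train`,
`simple_fl`, `baseline` (denoised large client, small client keeps noisy
labels), `proto_baseline` (single-view prototype labels), `proto_views`
(no FL; the small client is classified directly by view voting),
`proposed` (denoise + view-ensemble pseudo-labels + FedAvg) and
`pretrained_weights` (train on the clean large client only).

## The synthetic-data generator

No external imaging data is required: `gen_plane_image()` draws 64x64
grayscale images whose dominant geometric primitive mimics each plane's
discriminative geometry — abdomen: a filled ellipse (intensity 0.45) with
a bright internal dot; brain: a bright elliptical ring; femur: a thin
bright bar at a uniformly random angle; thorax: a brighter ellipse (0.8)
containing 2–4 dark chamber blobs. Position (±0.1), scale (0.9–1.1) and
orientation are jittered per image. The intensity levels and jitter ranges
were fixed once so that the classes are genuinely learnable at desk scale:
a raw-pixel nearest-centroid classifier reaches ~0.98 accuracy on 100/100
images per class, satisfying the learnability contract the test-suite
asserts (at the earlier, more muted contrast the thorax and abdomen
classes collapsed in pixel space).

Client acquisition shift (`client_shift()`) is additive brightness, a
contrast gain and multiplicative Gaussian speckle, re-clipped to [0, 1].
The default shift of the small client, `default_norepr_shift()`
(brightness +0.03, gain 1.05, speckle 0.03), models a moderate
cross-vendor difference: strong enough that raw-Euclidean prototype
matching visibly degrades, mild enough that cosine matching plus voting
keeps pseudo-label error well below the 20% injected label noise. The
magnitudes are free parameters — no quantitative characterization of the
real inter-continental shift exists to calibrate against — and were frozen
at these values.

Label noise is symmetric: `inject_label_noise()` selects exactly
`round(rate * n)` positions by sampling without replacement (so the
realized rate equals the nominal rate and tests can assert exact counts)
and replaces each selected label uniformly — by default excluding the true
class (`symmetric_exclusive`), optionally including it
(`symmetric_inclusive`). `gen_embedding_clusters()` provides the
latent-space fixture: one isotropic Gaussian per class with equidistant
means (orthogonal-axis construction, pairwise distance exactly
`separation`). Note that at separation $6\sigma$ the Bayes error is not
negligible: each competing class contributes $\Phi(-3) \approx 0.00135$,
so nearest-true-mean accuracy is ~0.996, not 1.

What the generator does *not* emulate: speckle statistics of real
ultrasound (attenuation, beamforming), anatomical variability, intrinsic
(non-injected) label noise, and class imbalance. Passing tests therefore
show that the pipeline's mechanisms work as specified on separable,
controllably corrupted data — not that the reported F1 levels transfer to
clinical images.

## Problem sizes and numerical choices

The test-suite and acceptance script run at desk scale, chosen as the
package's standard study conditions: two clients of 2000 and 200 images
(the ~10:1 ratio), 64x64 pixels, the tinycnn encoder (embedding 64), 12
contrastive epochs at batch 64, and 3 federated rounds of 5 local epochs
with batch 16; the paired-seed ordering experiment repeats this over 5
seeds. The full-scale recipe (ResNet-50, 2048-length embeddings, batch
256, 5 rounds x 20 epochs) is expressed in the same configuration objects
(`default_run_config()`) but no ResNet-50 implementation ships at desk
scale — `pretrain_encoder(arch = "resnet50")` rejects explicitly rather
than silently substituting.

Other numerical conventions, all deterministic: distance ties in k-NN
break by lower sample index; prototype-assignment ties by lower class id;
vote ties by summed distance then class id; every stochastic stage draws
its seed from a single base seed through `derive_seed()`, so identical
configurations reproduce bit-identical artifacts (model training included
— the only numerics are BLAS matrix products and the package's own C++
convolution kernels).

## Known limitations

* The synthetic benchmark is near ceiling at the default conditions: with
  20% symmetric noise all three federated variants frequently reach
  perfect test F1, so the expected ordering (`proposed` at least as good
  as `simple_fl` and as a noisy small client) often holds as a tie rather
  than a strict gap. Differences widen under stronger shift or noise.
* The ensemble vote helps most when the identity view is unreliable;
  under the mild default shift it is roughly neutral relative to
  single-view assignment (both are > 0.9 accurate), and the package makes
  no claim that `proto_views` dominates `proto_baseline` in every
  configuration.
* The consensus filter assumes the noise is label noise over a fixed
  class set with locally coherent clusters; asymmetric or class-dependent
  noise and aggregation schemes beyond FedAvg are out of scope.
* At desk scale the encoder is far smaller than a production backbone;
  absolute F1 values from the synthetic benchmark are not comparable to
  results on real imaging data.
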