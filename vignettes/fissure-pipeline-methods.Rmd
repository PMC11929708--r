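---
title: "Keypoint-based fissure segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keypoint-based fissure segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fissurept)
```

## The problem and the sparse representation

Pulmonary fissures separate the lung lobes and matter clinically because
they can limit the spread of disease; segmenting them enables lobe-wise
analysis and surface visualization. As thin sheets they occupy well under a
percent of a thorax CT, so dense voxel-wise 3D segmentation spends almost
all of its computation on background. `fissurept` instead abstracts the
volume into a sparse cloud of candidate points, labels the cloud with
geometric deep-learning models, and densifies the labeled points back into
surface meshes. This vignette records the models, their parameters, and
the design decisions behind the implementation.

## Keypoint extraction

**Foerstner keypoints** are fissure-agnostic: the structure tensor
`S = G_{sigma_t} * (grad I grad I^T)` is built from Gaussian-derivative
gradients at scale `sigma_grad` (default 1 voxel) and smoothed at
`sigma_tensor` (default 1.5 voxels); the distinctiveness
`D = 1/trace((S + eps I)^{-1})` is evaluated in closed form and local
maxima over 5×5×5 neighborhoods inside the lung mask become candidates.
Ties on plateaus are admitted, which guarantees a non-empty candidate set
for any non-empty mask — the property that makes this path robust. When
more than `K_max` (default 20 000) candidates exist, the top `K_max` by
distinctiveness are kept.

**CNN keypoints** are fissure-specific: a MobileNetV3-Large encoder with
every 2D convolution inflated to 3D (kernel sizes and channel widths kept)
feeds a 1×1×1 segmentation head that is trilinearly upsampled back to the
input resolution; the head width is frozen so the network carries 3.6 M
trainable parameters. Training such a pre-segmentation wants high recall
on the heavily imbalanced fissure classes, so the cross-entropy is weighted
per class by the false-negative rate of the current batch
(`w_c = FN_c/(FN_c + TP_c)`, recomputed every batch and treated as a
constant with respect to the logits). Inference tiles the volume with
128^3 patches at ≥50 % overlap and averages softmax outputs uniformly; K
foreground voxels are then sampled uniformly. An empty prediction is a
valid, flagged outcome (the n.a. pathway), not an error.

Every keypoint carries the flattened 5×5×5 patch of intensity around it,
windowed to [-1000, 600] HU and scaled to [0, 1]. The fixed window keeps
features comparable across cases; patch borders are filled by edge
replication so the lung boundary introduces no artificial step; the
x-fastest flattening order is a frozen convention. Coordinates are the
voxel lattice mapped to `[-1,1]` per axis (`c = 2 i/(n-1) - 1`); physical
spacing re-enters only when distances are reported in millimetres.

## Point segmentation networks

Three families are implemented, all mapping `(n×3 coords, n×125 features)`
to `n×4` logits and all exactly permutation-equivariant:

* **PointNet**: shared per-point MLPs (64, 64, 64, 128, 1024), global
  max-pool, and a head on the concatenated local (64) and global (1024)
  features. The spatial transformer is omitted — structures in CT are
  roughly aligned already.
* **DGCNN**: three EdgeConv layers on a kNN graph (k = 40) built once from
  the coordinates only and reused by all layers (the "dynamic" graph
  recomputation is deliberately disabled), a 1024-wide embedding,
  max-pool, and a head on global + concatenated EdgeConv features. The
  per-edge linear map on `[x_i, x_j - x_i]` is factored as
  `x_i (W_a - W_b) + x_j W_b` so the matrix products run over points, not
  edges.
* **PointTransformer**: a five-stage U-shaped encoder-decoder
  (widths 32–512, farthest-point-sampling downsampling by 4, nearest-
  neighbor interpolation up with skip connections) whose blocks apply
  vector self-attention in k = 16 neighborhoods: per-channel attention
  weights from an MLP on `q_i - k_j + delta_ij`, with the learned position
  encoding `delta_ij = theta(p_i - p_j)` added to both the attention input
  and the aggregated values.

Hidden widths are frozen so the default configurations reproduce the
published budgets — PointNet 0.48 M, DGCNN 0.65 M, PointTransformer
7.77 M parameters — which serve as the surviving architecture oracle; the
segmentation head widths were solved for those targets once and hard-coded.

Training samples N = 2048 points per pass (without replacement; smaller
clouds are upsampled), applies one random rigid transform per cloud
(rotations ±15° per axis, translation ±0.1, scale 0.9–1.1 — ranges chosen
here, configurable), and minimizes cross-entropy plus soft Dice
(smoothing 1e-5) with Adam (lr 1e-3, weight decay 1e-5) under cosine
annealing from lr to 0.05·lr across the run. Inference runs 50 passes of
N points, drawing not-yet-covered points first so every point is scored,
and sums softmax probabilities; the accumulated argmax (ties to the lowest
class index, i.e. background wins) labels the cloud. Scores are softmax
probabilities rather than raw logits — bounded per-round contributions make
the accumulation insensitive to one overconfident pass.

All trainable models run on a small tape-based reverse-mode automatic
differentiation engine written for this package (dense-matrix primitives:
matmul, gather/scatter, blockwise max/sum/softmax, elementwise ops),
validated against central finite differences in the test suite. Training
is bit-reproducible for a fixed seed and BLAS configuration.

## Surface reconstruction

**Poisson path.** Normals are estimated by PCA over 30 neighbors and
sign-consistently oriented by propagation along a minimum spanning tree of
the kNN graph (weights `1 - |n_i·n_j|`). The oriented samples are splatted
onto a regular `2^depth` grid (depth 6 by default) over the padded
bounding box, lightly smoothed, and the Poisson equation for the indicator
is solved spectrally; marching tetrahedra extract the level set through
the mean indicator value at the samples. Because the indicator settles
near that level away from the data, the raw surface is trimmed by sample
density (faces farther than 6 cells from every sample are dropped — the
counterpart of the density trimming established Poisson implementations
expose). Fissure topology then comes from post-processing: every triangle
with any vertex outside the lung mask is removed (the stricter reading of
"vertices outside the mask") and only the face-connected component with
the most faces survives. Clipping a closed reconstruction this way yields
the intended open surface with a boundary. Inputs with fewer than 50
points or degenerate (collinear) geometry raise a reconstruction-failure
condition that callers convert into an n.a. flag.

**Ground truth from label maps** mirrors the same chain: per class the
label mask is reduced to a one-voxel medial surface by topology-preserving
thinning (sequential 6-direction sweeps deleting simple points — one
26-connected foreground component in the 26-neighborhood and one
6-connected background component in the 18-neighborhood — with voxels
already one voxel thick along an axis protected, so a thin sheet is a
fixpoint), and the surviving voxel centers go through the normal/Poisson/
clip chain. The `sample10k` ablation skips thinning and samples up to
10 000 class voxels uniformly instead.

**PC-AE path.** The autoencoder encodes exactly N = 2048 points (farthest
point sampling when more, random-offset padding with sigma 0.05 when
fewer — sparse segmented clouds are a density domain shift the padding
mitigates) with a DGCNN (k = 16, coordinates only) into a 512-dimensional
latent code, and decodes by two residual shared MLPs that displace a
planar template: a 45×45 vertex grid over [-0.3, 0.3]^2 (the square number
closest to N), 3 872 triangles with a fixed diagonal split. Vertex order
is preserved, so vertex i corresponds to the same template position across
shapes. The loss is chamfer distance (squared distances, mean per
direction, summed — a frozen convention) between decoded vertices and the
input points, plus normal consistency (mean `1 - cos` over adjacent-face
normals), edge length (mean squared), and Laplacian smoothness (mean
squared uniform-Laplacian norm), weighted 1, 0.1, 1, 0.1. Means rather
than sums keep the terms scale-stable; degenerate faces are excluded from
normal consistency; without the normal-consistency term the decoder is
free to fold the sheet, which the weight hooks allow ablating. The total
encoder+decoder budget is 1.42 M parameters (decoder MLP width solved for
the target once).

## Evaluation

Both surfaces are sampled with 10 000 area-weighted points by default;
every sample's exact point-to-triangle distance to the other mesh is
computed; the pooled distances of both directions give ASSD (mean), SDSD
(standard deviation) and HD (maximum). Using one sampling seed for both
meshes makes the report exactly symmetric under swapping its arguments.
Fissures without a reconstructed surface are reported n.a. and excluded
from aggregates, with the n.a. count reported alongside — reconstruction
and distances are simply impossible there. For model comparisons on the
synthetic benchmark the package's tests instead score an n.a. fissure with
the case diagonal, so that failing to produce a surface is worse than
producing a bad one; this convention only affects the comparison tests,
not the reported metrics.

## The synthetic study conditions

`generate_case()` builds cubic volumes (64^3 for tests, 128^3 for demos)
containing two ellipsoidal "lungs" (semi-axes 0.17/0.28/0.47 of the edge)
on a soft-tissue background (+50 HU): lung parenchyma at -850 HU with
30 HU Gaussian noise, one sheet in the left lung and two non-intersecting
sheets (vertical gap ≥ 3 voxels) in the right, each a random low-order
height field `z = a + b·u + c·v + d·u² + e·v² + g·u·v` clipped to its
lung. Sheets appear as bright Gaussian-profile ridges (amplitude 400 HU,
width 1 voxel) whose contrast is modulated along the sheet by two random
plane waves (depth 0.7, 5–9 cycles per semi-axis) — fissure appearance in
CT varies along the surface, and the modulation gives the corner-seeking
distinctiveness operator genuine in-plane structure to respond to.
Ellipsoidal distractor blobs (4 per lung, the same amplitude as the
ridges) make local appearance alone ambiguous, so architectures that
exchange neighborhood information retain an advantage over purely
point-wise ones. Labels mark voxels within half a voxel (vertically) of a
sheet; the exact reference meshes are triangulated analytically from the
height fields, not derived from the voxelization, so metric checks have an
independent target. At the 128^3 demo scale the labeled fraction of the
lung is below 2 % — the thin-structure regime that motivates the sparse
representation; at 64^3 the fraction is proportionally larger because a
one-voxel band is thicker relative to the lung.

For training data, `make_dataset()` extracts Foerstner clouds at toy-scale
settings (sigma_grad 0.5, sigma_tensor 0.4, suppression window 3,
K_max 1000 — lighter smoothing and a tighter window than the clinical
defaults because every structure is a few voxels across) and labels
keypoints by nearest analytic sheet within 2 voxels. These settings were
fixed once as the package's study conditions; with them a cloud holds
roughly 50–90 keypoints per fissure, mirroring the sparse-per-fissure
regime of the clinical pipeline.

What the generator does not emulate: anatomically shaped lobes and
incomplete fissures, scanner-dependent noise texture and resolution
anisotropy, vessels and airways as structured (rather than blob-like)
distractors, and pathology. Passing the synthetic benchmark therefore
demonstrates that the pipeline's machinery — detection, learning,
reconstruction, metrics — works end-to-end on thin curved sheets; it does
not certify clinical accuracy.

## Numerical choices and degenerate inputs

* Argmax ties in labeling go to the lowest class index (background wins) —
  conservative.
* kNN distance ties break toward the lower point index; farthest point
  sampling starts deterministically (index 0 at the API, the point
  farthest from the centroid inside the PointTransformer so downsampling
  is permutation-stable).
* Soft-Dice smoothing 1e-5 in numerator and denominator; normal
  normalizations guarded by 1e-12.
* Empty point sets, empty predictions and too-small reconstruction inputs
  all flow through n.a. flags rather than exceptions; only malformed
  inputs raise.
* All randomness is seeded explicitly; helpers restore the caller's RNG
  state.

## Scale of the shipped experiments

The test suite and the acceptance script run reduced-scale versions of the
full protocol chosen to exercise every mechanism at desk scale: 64^3
volumes, clouds of ~1000 points, 256 points per training pass, 50-epoch
training on 8 cases with 2 held out (3 seeds for model comparisons), a
200-step single-shape autoencoder overfit at N = 1024, and 2000-sample
surface metrics. The full-scale defaults (2048 points per pass, 1000
epochs, 50 inference rounds, 10 000 metric samples) remain the package
defaults.

## Known limitations

* The grid Poisson solver resolves at `2^depth` uniformly; very elongated
  point sets lose resolution along their long axis compared to an
  octree-adaptive solver.
* The pre-segmentation CNN ships untrained (building and applying it is in
  scope; training it to clinical accuracy is not); the CNN keypoint path
  is exercised with synthetic or caller-provided probability maps.
* Training on the built-in engine is single-threaded CPU; it is meant for
  the reduced-scale experiments above, not for clinical-scale training.
* The PC-AE fits one template topology (an open sheet); objects not
  homeomorphic to a plane are out of scope.
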