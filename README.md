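# fissurept

Sparse keypoint segmentation of pulmonary fissures from thoracic CT.

The pulmonary fissures — left oblique, right oblique and right horizontal —
are the thin boundary surfaces between the lung lobes. They occupy a tiny
fraction of a CT volume, which makes dense 3D convolutional segmentation
wasteful. `fissurept` implements a sparse alternative:

1. **Keypoint abstraction.** The volume is reduced to at most
   K = 20 000 candidate points inside the lung mask, either with the
   Foerstner distinctiveness operator
   (`D = 1 / trace((S + eps I)^{-1})` on the image structure tensor `S`,
   local maxima in 5×5×5 neighborhoods) or with a lightweight 3D
   MobileNetV3-Large pre-segmentation CNN trained with a
   false-negative-rate-weighted cross-entropy for high recall. Each point
   carries its normalized coordinates in `[-1,1]^3` and a flattened 5×5×5
   patch of windowed image intensity (125 features).
2. **Point-cloud segmentation.** Geometric deep-learning models assign one
   of 4 classes (background + 3 fissures) to every point: a PointNet
   (shared per-point MLPs + global max-pool, no T-Net), a DGCNN (EdgeConv
   stack on a fixed kNN graph, k = 40) and a PointTransformer (U-shaped
   encoder-decoder with vector self-attention in k = 16 neighborhoods).
   Training uses N = 2048 points per pass, a combined cross-entropy + soft
   Dice loss, Adam (lr 1e-3, weight decay 1e-5) under cosine annealing to
   0.05 of the initial rate, and random rigid augmentation. Inference
   accumulates softmax scores over 50 coverage-first passes so every point
   is labeled. All models run on the package's own reverse-mode autodiff
   engine — no external deep-learning runtime is required.
3. **Surface reconstruction.** Dense open fissure surfaces come either
   from Poisson surface reconstruction (PCA normals with MST-consistent
   orientation, a spectral indicator solve on a `2^6` grid, marching
   tetrahedra, density trimming, lung-mask clipping and largest-component
   selection) or from a point-cloud-to-mesh autoencoder (PC-AE): a DGCNN
   encoder produces a 512-dimensional latent code and two residual
   per-vertex MLPs deform a planar template mesh
   (`V1 = V0 + f1(Z, V0)`, `V2 = V1 + f2(Z, V1)`), trained with a
   regularized mesh loss
   `w_CD·CD + w_NC·NC + w_EL·EL + w_LS·LS` (weights 1, 0.1, 1, 0.1).
4. **Evaluation.** Average symmetric surface distance (ASSD), standard
   deviation of surface distances (SDSD) and Hausdorff distance (HD) in mm
   from pooled exact point-to-triangle distances, with non-assigned (n.a.)
   accounting for fissures without segmented points.

A deterministic synthetic-case generator (ellipsoidal "lungs" with thin
curved bright sheets, contrast modulation and distractor blobs, plus exact
analytic ground-truth meshes) makes the whole pipeline testable without
clinical data.

## Worked example

```r
library(fissurept)

# one synthetic case + a labeled training set of Foerstner keypoint clouds
ds    <- make_dataset(8, seed = 7)          # 64^3 cases, ~1000 points each
train <- ds[1:6]; held <- ds[[7]]

model <- train_seg(build_seg_model("dgcnn", seed = 1), train,
                   seg_train_config(epochs = 50, n_points = 256, seed = 2))$model

scores <- infer_full_cloud(model, held$cloud, rounds = 8, n_points = 256)
sets   <- split_by_label(held$cloud, scores)
rec    <- reconstruct_from_segmentation(sets$points, held$case$lung_mask)

shape <- rep(held$case$size, 3)
gt_mm  <- lapply(held$case$gt_meshes, mesh_to_mm, shape = shape, spacing = c(1, 1, 1))
rec_mm <- list(meshes = lapply(rec$meshes, function(m)
                 if (is.null(m)) NULL else mesh_to_mm(m, shape, c(1, 1, 1))),
               na = rec$na)
ev <- evaluate_case(rec_mm, gt_mm)
round(ev$summary$assd, 2)
#> [1] 3.56
ev$n_na
#> [1] 2
```

`assd` is the average symmetric surface distance in millimetres between
the reconstructed fissure surfaces and the analytic ground-truth sheets of
the held-out case (voxel size 1 mm), averaged over the fissures that could
be reconstructed; `n_na` counts non-assigned fissures, for which too few
points were segmented to reconstruct a surface. At this deliberately tiny
training scale (6 cases, 50 epochs, 256 points per pass) the model
resolves one fissure to a few millimetres and misses two; the package's
acceptance checks run the same protocol with 8 training cases and 3
seeds and verify that the trained model beats its random-weight twin on
held-out surface distance.

A command-line front end over the same functions is installed at
`inst/scripts/fissure_pipeline.R` (subcommands `synth`, `train-seg`, `run`).

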