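# Foerstner keypoint detection and recall-weighted pre-segmentation losses.

gaussian_kernel <- function(sigma, derivative = FALSE) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (derivative) {
    k <- -x / sigma^2 * g
    # enforce exact unit response to a unit ramp
    k <- k / sum(-x * k)
    return(k)
  }
  g
}

# 1D convolution along one axis of a 3D array, borders replicated.
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, d)
  for (t in seq_along(kernel)) {
    off <- t - r - 1L
    idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    shifted <- switch(axis,
                      a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE],
                      a[, , idx, drop = FALSE])
    out <- out + kernel[t] * shifted
  }
  out
}

gaussian_smooth3 <- function(a, sigma) {
  k <- gaussian_kernel(sigma)
  conv_axis(conv_axis(conv_axis(a, k, 1L), k, 2L), k, 3L)
}

# Gaussian-derivative gradient along one axis (smoothing on the other two).
gaussian_gradient <- function(a, sigma, axis) {
  g <- gaussian_kernel(sigma)
  dg <- gaussian_kernel(sigma, derivative = TRUE)
  out <- a
  for (ax in 1:3) {
    out <- conv_axis(out, if (ax == axis) dg else g, ax)
  }
  out
}

#' Image structure tensor
#'
#' Computes the Gaussian-smoothed outer product of Gaussian-derivative image
#' gradients. The six independent channels of the symmetric tensor are
#' returned as a named list of 3D arrays (`xx, yy, zz, xy, xz, yz`).
#'
#' @param vol a [new_volume()].
#' @param sigma_grad gradient filter scale in voxels.
#' @param sigma_tensor tensor smoothing scale in voxels.
#' @return list of six 3D arrays.
#' @export
structure_tensor <- function(vol, sigma_grad = 1, sigma_tensor = 1.5) {
  stopifnot(inherits(vol, "fissure_volume"),
            sigma_grad > 0, sigma_tensor > 0)
  a <- vol$voxels
  if (any(dim(a) < 2 * ceiling(3 * max(sigma_grad, sigma_tensor)) + 1)) {
    stop_fmt("volume smaller than the filter support")
  }
  gx <- gaussian_gradient(a, sigma_grad, 1L)
  gy <- gaussian_gradient(a, sigma_grad, 2L)
  gz <- gaussian_gradient(a, sigma_grad, 3L)
  sm <- function(x) gaussian_smooth3(x, sigma_tensor)
  list(xx = sm(gx * gx), yy = sm(gy * gy), zz = sm(gz * gz),
       xy = sm(gx * gy), xz = sm(gx * gz), yz = sm(gy * gz))
}

#' Foerstner distinctiveness field
#'
#' Distinctiveness of each voxel from its structure tensor `S`:
#' `D = 1 / trace((S + eps I)^-1) = det(S + eps I) / trace(adj(S + eps I))`,
#' evaluated in closed form for the symmetric 3x3 tensor. High `D` marks
#' corner- or blob-like voxels where the gradient spans all directions.
#'
#' @param S structure tensor field from [structure_tensor()].
#' @param eps regularizer added to the diagonal to guard singular tensors.
#' @return 3D array of non-negative distinctiveness values.
#' @export
foerstner_distinctiveness <- function(S, eps = 1e-6) {
  a <- S$xx + eps; b <- S$yy + eps; c <- S$zz + eps
  d <- S$xy; e <- S$xz; f <- S$yz
  det <- a * (b * c - f * f) - d * (d * c - f * e) + e * (d * f - b * e)
  # trace of the adjugate = sum of principal 2x2 minors
  tr_adj <- (b * c - f * f) + (a * c - e * e) + (a * b - d * d)
  D <- det / tr_adj
  D[!is.finite(D) | D < 0] <- 0
  D
}

#' Non-maximum suppression over a cubic window
#'
#' Selects voxels that attain the maximum of the distinctiveness field over
#' their `window^3` neighborhood and lie inside the mask. Plateau ties all
#' qualify, so a non-empty mask always yields at least one candidate.
#'
#' @param D 3D distinctiveness array.
#' @param mask 3D binary array of the same shape.
#' @param window odd window edge length (default 5).
#' @return matrix of 0-based voxel indices, sorted lexicographically.
#' @export
nms_select <- function(D, mask, window = 5L) {
  stopifnot(window %% 2L == 1L, window >= 3L)
  if (!any(mask > 0)) stop_fmt("empty mask in nms_select")
  if (!all(dim(D) == dim(mask))) stop_fmt("mask/field shape mismatch")
  r <- (window - 1L) %/% 2L
  mx <- D
  for (axis in 1:3) {
    cur <- mx
    for (off in c(-r:-1, 1:r)) {
      idx <- pmin(pmax(seq_len(dim(D)[axis]) + off, 1L), dim(D)[axis])
      shifted <- switch(axis,
                        mx[idx, , , drop = FALSE],
                        mx[, idx, , drop = FALSE],
                        mx[, , idx, drop = FALSE])
      cur <- pmax(cur, shifted)
    }
    mx <- cur
  }
  sel <- which(mask > 0 & D >= mx, arr.ind = TRUE) - 1L
  sel <- sel[order(sel[, 1], sel[, 2], sel[, 3]), , drop = FALSE]
  colnames(sel) <- c("x", "y", "z")
  unname(sel)
}

#' Foerstner keypoint extraction
#'
#' Full fissure-agnostic keypoint chain: structure tensor, distinctiveness,
#' non-maximum suppression inside the lung mask, top-K selection by
#' distinctiveness, and 5x5x5 intensity patch features. Because plateau ties
#' qualify in the suppression step, the candidate cloud is never empty for a
#' non-empty mask.
#'
#' @param vol a [new_volume()]; raw HU volumes are windowed internally with
#'   [normalize_intensity()] defaults.
#' @param mask 3D binary lung mask.
#' @param K_max maximum number of keypoints (default 20000).
#' @param sigma_grad,sigma_tensor filter scales in voxels.
#' @param window suppression window (default 5).
#' @param eps distinctiveness regularizer.
#' @return a `keypoint_cloud`: list with `coords` (normalized, in
#'   `[-1,1]^3`), `voxel_indices` (0-based), `features` (n x 125),
#'   `distinctiveness`, `source`, `shape`, `spacing`.
#' @export
foerstner_keypoints <- function(vol, mask, K_max = 20000L,
                                sigma_grad = 1, sigma_tensor = 1.5,
                                window = 5L, eps = 1e-6) {
  stopifnot(inherits(vol, "fissure_volume"))
  if (!any(mask > 0)) stop_fmt("empty lung mask")
  rng <- range(vol$voxels)
  nvol <- if (rng[1] < 0 || rng[2] > 1) normalize_intensity(vol) else vol
  S <- structure_tensor(nvol, sigma_grad, sigma_tensor)
  D <- foerstner_distinctiveness(S, eps)
  idx <- nms_select(D, mask, window)
  dv <- D[idx + 1L]
  if (nrow(idx) > K_max) {
    ord <- order(-dv, idx[, 1], idx[, 2], idx[, 3])[seq_len(K_max)]
    idx <- idx[ord, , drop = FALSE]
    dv <- dv[ord]
  }
  new_keypoint_cloud(idx, nvol, source = "foerstner",
                     distinctiveness = dv)
}

new_keypoint_cloud <- function(voxel_indices, nvol, source,
                               distinctiveness = NULL) {
  shape <- dim(nvol$voxels)
  coords <- voxel_to_norm(voxel_indices, shape)
  feats <- if (nrow(voxel_indices) > 0) {
    extract_patch_features(nvol, voxel_indices)
  } else matrix(0, 0, 125)
  structure(list(coords = coords, voxel_indices = voxel_indices,
                 features = feats, distinctiveness = distinctiveness,
                 source = source, shape = shape, spacing = nvol$spacing),
            class = "keypoint_cloud")
}

#' @export
print.keypoint_cloud <- function(x, ...) {
  cat(sprintf("<keypoint_cloud %d points (%s), grid %s>\n",
              nrow(x$coords), x$source, paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Per-class false-negative-rate loss weights
#'
#' Computes `w_c = FN_c / (FN_c + TP_c)` from hard predictions against the
#' reference labels of the current batch. Classes absent from the reference
#' get weight 0. Weighting the cross-entropy by these rates pushes a
#' pre-segmentation toward high recall.
#'
#' @param pred_labels integer labels (0-based classes), any shape.
#' @param true_labels reference labels, same shape.
#' @param n_classes number of classes (default 4).
#' @return numeric vector of `n_classes` weights in `[0, 1]`.
#' @export
fnr_weights <- function(pred_labels, true_labels, n_classes = 4L) {
  stopifnot(length(pred_labels) == length(true_labels))
  w <- numeric(n_classes)
  for (c in seq_len(n_classes) - 1L) {
    pos <- true_labels == c
    if (!any(pos)) next
    tp <- sum(pred_labels[pos] == c)
    fn <- sum(pos) - tp
    w[c + 1L] <- fn / (fn + tp)
  }
  w
}

#' False-negative-rate weighted cross-entropy
#'
#' Cross-entropy over voxels where each voxel's contribution is scaled by the
#' current false-negative rate of its reference class (recomputed per batch,
#' treated as a constant with respect to the logits).
#'
#' @param logits n x C matrix (or array with trailing class dimension) of
#'   unnormalized scores.
#' @param true_labels integer 0-based class labels, length n.
#' @param n_classes number of classes.
#' @return scalar loss, `>= 0`; 0 for a perfect hard prediction.
#' @export
fnr_weighted_ce <- function(logits, true_labels, n_classes = 4L) {
  if (!is.matrix(logits)) {
    d <- dim(logits)
    logits <- matrix(logits, ncol = d[length(d)])
  }
  true_labels <- as.integer(true_labels)
  if (nrow(logits) != length(true_labels)) stop_fmt("logit/label mismatch")
  pred <- max.col(logits, ties.method = "first") - 1L
  w <- fnr_weights(pred, true_labels, n_classes)
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  nll <- lse - logits[cbind(seq_len(nrow(logits)), true_labels + 1L)]
  mean(w[true_labels + 1L] * nll)
}
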