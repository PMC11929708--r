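# Lightweight 3D pre-segmentation CNN: MobileNetV3-Large with every 2D
# convolution inflated to 3D (kernel sizes and channel widths kept), plus a
# small upsampling segmentation head. Used to propose fissure-specific
# keypoints; trained elsewhere, here instantiated and applied.

mnv3_rows <- function() {
  # k, exp, out, SE, activation, stride -- the MobileNetV3-Large schedule
  list(
    list(k = 3, exp = 16,  out = 16,  se = FALSE, act = "relu", s = 1),
    list(k = 3, exp = 64,  out = 24,  se = FALSE, act = "relu", s = 2),
    list(k = 3, exp = 72,  out = 24,  se = FALSE, act = "relu", s = 1),
    list(k = 5, exp = 72,  out = 40,  se = TRUE,  act = "relu", s = 2),
    list(k = 5, exp = 120, out = 40,  se = TRUE,  act = "relu", s = 1),
    list(k = 5, exp = 120, out = 40,  se = TRUE,  act = "relu", s = 1),
    list(k = 3, exp = 240, out = 80,  se = FALSE, act = "hs",   s = 2),
    list(k = 3, exp = 200, out = 80,  se = FALSE, act = "hs",   s = 1),
    list(k = 3, exp = 184, out = 80,  se = FALSE, act = "hs",   s = 1),
    list(k = 3, exp = 184, out = 80,  se = FALSE, act = "hs",   s = 1),
    list(k = 3, exp = 480, out = 112, se = TRUE,  act = "hs",   s = 1),
    list(k = 3, exp = 672, out = 112, se = TRUE,  act = "hs",   s = 1),
    list(k = 5, exp = 672, out = 160, se = TRUE,  act = "hs",   s = 2),
    list(k = 5, exp = 960, out = 160, se = TRUE,  act = "hs",   s = 1),
    list(k = 5, exp = 960, out = 160, se = TRUE,  act = "hs",   s = 1)
  )
}

make_divisible <- function(v, d = 8L) {
  nv <- max(d, round(v / d) * d)
  if (nv < 0.9 * v) nv <- nv + d
  as.integer(nv)
}

cnn_conv_init <- function(params, name, fan_in, n) {
  params[[name]] <- matrix(rnorm(n, sd = sqrt(2 / fan_in)), nrow = fan_in)
  params
}

cnn_bn_init <- function(params, name, C) {
  params[[paste0(name, ".gamma")]] <- matrix(1, 1, C)
  params[[paste0(name, ".beta")]] <- matrix(0, 1, C)
  params
}

#' Build the 3D pre-segmentation CNN
#'
#' MobileNetV3-Large inflated to 3D (2D kernels `k x k` become
#' `k x k x k`; channel schedule unchanged) with a 1x1x1 segmentation head
#' applied to the stride-32 feature map and trilinearly upsampled back to
#' the input resolution. Head width is frozen so the default configuration
#' carries 3.6 M trainable parameters.
#'
#' @param in_channels input channels (default 1).
#' @param n_classes output classes (default 4).
#' @param head_width hidden width of the segmentation head.
#' @param seed weight initialization seed.
#' @return a `preseg_cnn` model.
#' @export
build_preseg_cnn <- function(in_channels = 1L, n_classes = 4L,
                             head_width = 310L, seed = 1L) {
  rows <- mnv3_rows()
  params <- list()
  with_seed(seed, {
    params <- cnn_conv_init(params, "stem.W", 27L * in_channels, 27L *
                              in_channels * 16L)
    params <- cnn_bn_init(params, "stem.bn", 16L)
    cin <- 16L
    for (i in seq_along(rows)) {
      r <- rows[[i]]
      nm <- paste0("b", i)
      if (r$exp != cin) {
        params <- cnn_conv_init(params, paste0(nm, ".expand.W"), cin,
                                cin * r$exp)
        params <- cnn_bn_init(params, paste0(nm, ".expand.bn"), r$exp)
      }
      params[[paste0(nm, ".dw.W")]] <-
        matrix(rnorm(r$k^3 * r$exp, sd = sqrt(2 / r$k^3)), r$k^3, r$exp)
      params <- cnn_bn_init(params, paste0(nm, ".dw.bn"), r$exp)
      if (r$se) {
        sec <- make_divisible(r$exp / 4)
        params <- cnn_conv_init(params, paste0(nm, ".se.fc1.W"), r$exp,
                                r$exp * sec)
        params[[paste0(nm, ".se.fc1.b")]] <- matrix(0, 1, sec)
        params <- cnn_conv_init(params, paste0(nm, ".se.fc2.W"), sec,
                                sec * r$exp)
        params[[paste0(nm, ".se.fc2.b")]] <- matrix(0, 1, r$exp)
      }
      params <- cnn_conv_init(params, paste0(nm, ".project.W"), r$exp,
                              r$exp * r$out)
      params <- cnn_bn_init(params, paste0(nm, ".project.bn"), r$out)
      cin <- r$out
    }
    params <- cnn_conv_init(params, "last.W", cin, cin * 960L)
    params <- cnn_bn_init(params, "last.bn", 960L)
    params <- cnn_conv_init(params, "head.fc1.W", 960L, 960L * head_width)
    params <- cnn_bn_init(params, "head.fc1.bn", head_width)
    params <- cnn_conv_init(params, "head.out.W", head_width,
                            head_width * n_classes)
    params[["head.out.b"]] <- matrix(0, 1, n_classes)
  })
  structure(list(params = params, rows = rows, in_channels = in_channels,
                 n_classes = n_classes, head_width = head_width),
            class = "preseg_cnn")
}

#' @export
print.preseg_cnn <- function(x, ...) {
  cat(sprintf("<preseg_cnn MobileNetV3-Large-3D, %.1f M parameters>\n",
              count_parameters(x) / 1e6))
  invisible(x)
}

hardswish <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6
hardsigmoid <- function(x) pmin(pmax(x + 3, 0), 6) / 6

cnn_act <- function(x, act) if (act == "hs") hardswish(x) else pmax(x, 0)

bn_apply <- function(x4, gamma, beta) {
  d <- dim(x4)
  m <- matrix(x4, ncol = d[4])
  m <- sweep(sweep(m, 2, as.numeric(gamma), `*`), 2, as.numeric(beta), `+`)
  array(m, d)
}

# 1x1x1 convolution as a channel matmul.
pw_conv <- function(x4, W) {
  d <- dim(x4)
  out <- matrix(x4, ncol = d[4]) %*% W
  array(out, c(d[1:3], ncol(W)))
}

conv_out_positions <- function(n, stride) seq(1L, n, by = stride)

# Depthwise 3D convolution via shifted accumulation; zero padding, odd k.
dw_conv <- function(x4, Wk, k, stride) {
  d <- dim(x4)
  r <- (k - 1L) %/% 2L
  C <- d[4]
  pad <- array(0, c(d[1:3] + 2L * r, C))
  pad[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3]), ] <- x4
  px <- conv_out_positions(d[1], stride)
  py <- conv_out_positions(d[2], stride)
  pz <- conv_out_positions(d[3], stride)
  out <- array(0, c(length(px), length(py), length(pz), C))
  t <- 1L
  for (dz in 0:(k - 1L)) for (dy in 0:(k - 1L)) for (dx in 0:(k - 1L)) {
    sl <- pad[px + dx, py + dy, pz + dz, , drop = FALSE]
    out <- out + sweep(sl, 4, Wk[t, ], `*`)
    t <- t + 1L
  }
  out
}

# Full (non-depthwise) k^3 convolution used only by the stem (1 -> 16).
stem_conv <- function(x3, W, k, stride) {
  d <- dim(x3)
  r <- (k - 1L) %/% 2L
  pad <- array(0, d + 2L * r)
  pad[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- x3
  px <- conv_out_positions(d[1], stride)
  py <- conv_out_positions(d[2], stride)
  pz <- conv_out_positions(d[3], stride)
  nvox <- length(px) * length(py) * length(pz)
  col <- matrix(0, nvox, k^3)
  t <- 1L
  for (dz in 0:(k - 1L)) for (dy in 0:(k - 1L)) for (dx in 0:(k - 1L)) {
    col[, t] <- pad[px + dx, py + dy, pz + dz]
    t <- t + 1L
  }
  array(col %*% W, c(length(px), length(py), length(pz), ncol(W)))
}

se_apply <- function(x4, params, nm) {
  d <- dim(x4)
  m <- matrix(x4, ncol = d[4])
  s <- colMeans(m)
  h <- pmax(s %*% params[[paste0(nm, ".se.fc1.W")]] +
              params[[paste0(nm, ".se.fc1.b")]], 0)
  g <- hardsigmoid(h %*% params[[paste0(nm, ".se.fc2.W")]] +
                     params[[paste0(nm, ".se.fc2.b")]])
  array(sweep(m, 2, as.numeric(g), `*`), d)
}

# Trilinear upsampling of a 4D feature map to target spatial dims.
upsample3d <- function(x4, target) {
  d <- dim(x4)
  C <- d[4]
  m <- matrix(x4, ncol = C)
  src <- function(n_t, n_s) {
    if (n_s == 1) {
      return(list(i0 = rep(1, n_t), i1 = rep(1, n_t), t = rep(0, n_t)))
    }
    if (n_t == 1) return(list(i0 = 1, i1 = 2, t = 0))
    # align corners
    pos <- (seq_len(n_t) - 1) * (n_s - 1) / (n_t - 1)
    i0 <- pmin(floor(pos), n_s - 2) + 1
    list(i0 = i0, i1 = i0 + 1, t = pos - (i0 - 1))
  }
  sx <- src(target[1], d[1]); sy <- src(target[2], d[2])
  sz <- src(target[3], d[3])
  gx0 <- rep(sx$i0, times = target[2] * target[3])
  gx1 <- rep(sx$i1, times = target[2] * target[3])
  tx <- rep(sx$t, times = target[2] * target[3])
  gy0 <- rep(rep(sy$i0, each = target[1]), times = target[3])
  gy1 <- rep(rep(sy$i1, each = target[1]), times = target[3])
  ty <- rep(rep(sy$t, each = target[1]), times = target[3])
  gz0 <- rep(sz$i0, each = target[1] * target[2])
  gz1 <- rep(sz$i1, each = target[1] * target[2])
  tz <- rep(sz$t, each = target[1] * target[2])
  lin <- function(ix, iy, iz) ix + d[1] * (iy - 1) + d[1] * d[2] * (iz - 1)
  out <- matrix(0, length(gx0), C)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (if (cx) tx else 1 - tx) * (if (cy) ty else 1 - ty) *
      (if (cz) tz else 1 - tz)
    idx <- lin(if (cx) gx1 else gx0, if (cy) gy1 else gy0,
               if (cz) gz1 else gz0)
    out <- out + w * m[idx, , drop = FALSE]
  }
  array(out, c(target, C))
}

#' Forward pass of the pre-segmentation CNN
#'
#' @param model a [build_preseg_cnn()].
#' @param vol3 3D array of normalized intensities in `[0, 1]`; each axis
#'   must be at least 32 voxels.
#' @return 4D array of per-voxel class logits, spatial shape equal to the
#'   input shape.
#' @export
preseg_forward <- function(model, vol3) {
  stopifnot(length(dim(vol3)) == 3L, all(dim(vol3) >= 32L))
  p <- model$params
  x <- stem_conv(vol3, p[["stem.W"]], 3L, 2L)
  x <- cnn_act(bn_apply(x, p[["stem.bn.gamma"]], p[["stem.bn.beta"]]), "hs")
  cin <- 16L
  for (i in seq_along(model$rows)) {
    r <- model$rows[[i]]
    nm <- paste0("b", i)
    res_in <- x
    h <- x
    if (r$exp != cin) {
      h <- pw_conv(h, p[[paste0(nm, ".expand.W")]])
      h <- cnn_act(bn_apply(h, p[[paste0(nm, ".expand.bn.gamma")]],
                            p[[paste0(nm, ".expand.bn.beta")]]), r$act)
    }
    h <- dw_conv(h, p[[paste0(nm, ".dw.W")]], r$k, r$s)
    h <- cnn_act(bn_apply(h, p[[paste0(nm, ".dw.bn.gamma")]],
                          p[[paste0(nm, ".dw.bn.beta")]]), r$act)
    if (r$se) h <- se_apply(h, p, nm)
    h <- pw_conv(h, p[[paste0(nm, ".project.W")]])
    h <- bn_apply(h, p[[paste0(nm, ".project.bn.gamma")]],
                  p[[paste0(nm, ".project.bn.beta")]])
    if (r$s == 1L && r$out == cin) h <- h + res_in
    x <- h
    cin <- r$out
  }
  x <- pw_conv(x, p[["last.W"]])
  x <- cnn_act(bn_apply(x, p[["last.bn.gamma"]], p[["last.bn.beta"]]), "hs")
  x <- pw_conv(x, p[["head.fc1.W"]])
  x <- cnn_act(bn_apply(x, p[["head.fc1.bn.gamma"]],
                        p[["head.fc1.bn.beta"]]), "hs")
  x <- upsample3d(x, dim(vol3))
  d <- dim(x)
  out <- sweep(matrix(x, ncol = d[4]) %*% p[["head.out.W"]], 2,
               as.numeric(p[["head.out.b"]]), `+`)
  array(out, c(d[1:3], model$n_classes))
}

#' Sliding-window inference over a large volume
#'
#' Applies the CNN to overlapping cubic patches (at least the requested
#' overlap) and averages the per-patch softmax outputs uniformly; smaller
#' volumes are zero-padded up to one patch. Per-voxel probabilities sum
#' to 1.
#'
#' @param model a [build_preseg_cnn()].
#' @param vol a normalized-intensity [new_volume()].
#' @param patch cubic patch edge (default 128).
#' @param overlap minimum fractional overlap between neighboring patches.
#' @return 4D array of class probabilities.
#' @export
sliding_window_predict <- function(model, vol, patch = 128L, overlap = 0.5) {
  v <- vol$voxels
  d0 <- dim(v)
  d <- pmax(d0, patch)
  if (any(d > d0)) {
    vv <- array(0, d)
    vv[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- v
    v <- vv
  }
  stride <- max(1L, as.integer(floor(patch * (1 - overlap))))
  starts <- function(n) {
    if (n == patch) return(1L)
    s <- seq(1L, n - patch, by = stride)
    if (tail(s, 1) != n - patch + 1L) s <- c(s, n - patch + 1L)
    s
  }
  acc <- array(0, c(d, model$n_classes))
  cnt <- array(0, d)
  for (sx in starts(d[1])) for (sy in starts(d[2])) for (sz in starts(d[3])) {
    sub <- v[sx + 0:(patch - 1), sy + 0:(patch - 1), sz + 0:(patch - 1)]
    lg <- preseg_forward(model, sub)
    dm <- dim(lg)
    m <- matrix(lg, ncol = dm[4])
    m <- exp(m - apply(m, 1, max))
    m <- m / rowSums(m)
    pr <- array(m, dm)
    xr <- sx + 0:(patch - 1); yr <- sy + 0:(patch - 1)
    zr <- sz + 0:(patch - 1)
    acc[xr, yr, zr, ] <- acc[xr, yr, zr, , drop = FALSE] + pr
    cnt[xr, yr, zr] <- cnt[xr, yr, zr] + 1
  }
  acc <- acc / as.vector(cnt)
  acc[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), , drop = FALSE]
}

#' Fissure-specific keypoints from a CNN probability map
#'
#' Takes every voxel whose argmax class is foreground and lies inside the
#' lung mask; when more than `K_max` qualify, `K_max` are sampled uniformly
#' without replacement (seeded). An empty prediction yields an empty cloud
#' (the n.a. pathway), not an error.
#'
#' @param probmap 4D class-probability array.
#' @param mask 3D binary lung mask.
#' @param vol the normalized-intensity volume (for patch features).
#' @param K_max keypoint budget (default 20000).
#' @param seed sampling seed.
#' @return a `keypoint_cloud` with `source = "cnn"`; zero rows when no
#'   fissure voxels are predicted.
#' @export
cnn_keypoints <- function(probmap, mask, vol, K_max = 20000L, seed = 1L) {
  d <- dim(probmap)
  stopifnot(length(d) == 4L, d[4] == 4L, all(d[1:3] == dim(mask)))
  m <- matrix(probmap, ncol = d[4])
  cls <- max.col(m, ties.method = "first") - 1L
  fg <- array(cls > 0L, d[1:3]) & mask > 0
  idx <- which(fg, arr.ind = TRUE) - 1L
  if (nrow(idx) > K_max) {
    idx <- with_seed(seed, idx[sample(nrow(idx), K_max), , drop = FALSE])
  }
  rng <- range(vol$voxels)
  nvol <- if (rng[1] < 0 || rng[2] > 1) normalize_intensity(vol) else vol
  new_keypoint_cloud(idx, nvol, source = "cnn")
}
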