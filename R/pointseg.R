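# Point-cloud segmentation networks (PointNet, DGCNN, PointTransformer),
# their training loop, and accumulated full-cloud inference.

#' k-nearest-neighbor graph on point coordinates
#'
#' Euclidean kNN on coordinates only (image features are ignored for graph
#' construction). Self-loops are excluded; distance ties break toward the
#' lower point index. The graph is built once per cloud and reused by every
#' EdgeConv layer.
#'
#' @param coords n x 3 matrix, n >= 2.
#' @param k neighbor count; effective count is `min(k, n - 1)`.
#' @return list with `k` and `neighbors`, an n x k matrix of 1-based indices.
#' @export
knn_graph <- function(coords, k) {
  coords <- rbind(coords)
  if (nrow(coords) < 2L) stop_fmt("knn_graph needs at least 2 points")
  nb <- cpp_knn(coords, as.integer(k))
  list(k = ncol(nb), neighbors = nb)
}

# Frozen hidden widths, tuned so instantiating each architecture with
# c_in = 128 reproduces the published trainable-parameter budgets.
seg_arch_config <- function(arch) {
  switch(arch,
    pointnet = list(
      point_dims = c(64, 64, 64, 128, 1024),  # local tap after layer 2
      local_at = 2L,
      head_dims = c(256, 128, 96)),
    dgcnn = list(
      ec_dims = c(64, 64, 64),
      emb_dim = 1024,
      head_dims = c(312, 128),
      k = 40L),
    pointtransformer = list(
      dims = c(32, 64, 128, 256, 512),
      blocks = c(1L, 1L, 2L, 4L, 2L),   # encoder blocks per stage
      k = 16L,
      down_ratio = 4L,
      head_hidden = 32L),
    stop_fmt("unknown architecture '%s'", arch))
}

#' Build a point segmentation network
#'
#' Instantiates one of three geometric deep-learning families mapping a
#' point cloud (coordinates plus intensity-patch features) to per-point
#' class logits:
#' * `pointnet`: shared per-point MLPs, a global max-pool, and a
#'   segmentation head on concatenated local and global features; no
#'   spatial transformer.
#' * `dgcnn`: a stack of EdgeConv graph convolutions on a fixed input kNN
#'   graph (`k = 40`); the graph is built once from the coordinates and kept
#'   for all layers.
#' * `pointtransformer`: a U-shaped encoder-decoder applying vector
#'   self-attention in `k = 16` neighborhoods with a learned position
#'   encoding added to both the attention logits and the aggregated values.
#'
#' Hidden widths are frozen so the default configuration (`c_in = 128`)
#' reproduces the published parameter budgets (0.48 M / 0.65 M / 7.77 M).
#'
#' @param arch one of `"pointnet"`, `"dgcnn"`, `"pointtransformer"`.
#' @param c_in input channels (3 coordinates + 125 patch features).
#' @param n_classes output classes (background + 3 fissures).
#' @param seed RNG seed for weight initialization.
#' @return a `seg_model` object.
#' @export
build_seg_model <- function(arch = c("pointnet", "dgcnn", "pointtransformer"),
                            c_in = 128L, n_classes = 4L, seed = 1L) {
  arch <- match.arg(arch)
  cfg <- seg_arch_config(arch)
  params <- list()
  with_seed(seed, {
    if (arch == "pointnet") {
      dims <- c(c_in, cfg$point_dims)
      params <- nn_init_mlp(params, "pt", dims)
      head_in <- cfg$point_dims[cfg$local_at] + tail(cfg$point_dims, 1L)
      params <- nn_init_mlp(params, "head",
                            c(head_in, cfg$head_dims, n_classes))
    } else if (arch == "dgcnn") {
      in_dims <- c(c_in, cfg$ec_dims[-length(cfg$ec_dims)])
      for (i in seq_along(cfg$ec_dims)) {
        params <- nn_init_linear(params, paste0("ec", i),
                                 2L * in_dims[i], cfg$ec_dims[i])
      }
      cat_dim <- sum(cfg$ec_dims)
      params <- nn_init_linear(params, "emb", cat_dim, cfg$emb_dim)
      params <- nn_init_mlp(params, "head",
                            c(cfg$emb_dim + cat_dim, cfg$head_dims, n_classes))
    } else {
      d <- cfg$dims
      params <- nn_init_mlp(params, "embed", c(c_in, d[1], d[1]))
      for (b in seq_len(cfg$blocks[1])) {
        params <- pt_block_init(params, paste0("enc1.", b), d[1])
      }
      for (s in 2:5) {
        params <- nn_init_linear(params, paste0("down", s), d[s - 1], d[s])
        for (b in seq_len(cfg$blocks[s])) {
          params <- pt_block_init(params, paste0("enc", s, ".", b), d[s])
        }
      }
      for (s in 4:1) {
        params <- nn_init_linear(params, paste0("up", s), d[s + 1], d[s])
        params <- nn_init_linear(params, paste0("skip", s), d[s], d[s])
        params <- pt_block_init(params, paste0("dec", s), d[s])
      }
      params <- nn_init_mlp(params, "head",
                            c(d[1], cfg$head_hidden, n_classes))
    }
  })
  structure(list(arch = arch, c_in = c_in, n_classes = n_classes,
                 cfg = cfg, params = params),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model %s, %d -> %d, %.2f M parameters>\n", x$arch,
              x$c_in, x$n_classes, count_parameters(x) / 1e6))
  invisible(x)
}

pt_block_init <- function(params, name, d) {
  for (nm in c("q", "k", "v", "in", "out")) {
    params <- nn_init_linear(params, paste0(name, ".", nm), d, d)
  }
  params <- nn_init_mlp(params, paste0(name, ".pos"), c(3L, d, d))
  params <- nn_init_mlp(params, paste0(name, ".gamma"), c(d, d, d))
  params
}

# EdgeConv: per-edge linear on [x_i, x_j - x_i] then max over neighbors.
# The edge map is factored as x_i (W_a - W_b) + x_j W_b so the matrix
# products run over the n points, not the n*k edges.
edgeconv_fwd <- function(tape, pn, name, x, neighbors) {
  n <- nrow(ad_val(x)); k <- ncol(neighbors)
  ctr <- rep(seq_len(n), each = k)
  nbr <- as.vector(t(neighbors))
  W <- pn[[paste0(name, ".W")]]
  C <- nrow(ad_val(W)) %/% 2L
  Wa <- ad_slice_rows(tape, W, seq_len(C))
  Wb <- ad_slice_rows(tape, W, C + seq_len(C))
  A <- ad_matmul(tape, x, ad_sub(tape, Wa, Wb))
  B <- ad_matmul(tape, x, Wb)
  h <- ad_add(tape, ad_gather(tape, A, ctr), ad_gather(tape, B, nbr))
  h <- ad_relu(tape, ad_add(tape, h, pn[[paste0(name, ".b")]]))
  ad_group_max(tape, h, k)
}

# Vector self-attention block in kNN neighborhoods with learned position
# encoding; pre/post linear projections and a residual connection.
pt_block_fwd <- function(tape, pn, name, x, coords, neighbors) {
  n <- nrow(coords); k <- ncol(neighbors)
  ctr <- rep(seq_len(n), each = k)
  nbr <- as.vector(t(neighbors))
  h <- nn_linear(tape, pn, paste0(name, ".in"), x)
  q <- nn_linear(tape, pn, paste0(name, ".q"), h)
  kk <- nn_linear(tape, pn, paste0(name, ".k"), h)
  v <- nn_linear(tape, pn, paste0(name, ".v"), h)
  rel <- coords[ctr, , drop = FALSE] - coords[nbr, , drop = FALSE]
  pos <- nn_mlp(tape, pn, paste0(name, ".pos"), rel, 2L)
  att_in <- ad_add(tape,
                   ad_sub(tape, ad_gather(tape, q, ctr),
                          ad_gather(tape, kk, nbr)),
                   pos)
  logits <- nn_mlp(tape, pn, paste0(name, ".gamma"), att_in, 2L)
  w <- ad_group_softmax(tape, logits, k)
  val <- ad_add(tape, ad_gather(tape, v, nbr), pos)
  agg <- ad_group_sum(tape, ad_mul(tape, w, val), k)
  out <- nn_linear(tape, pn, paste0(name, ".out"), ad_relu(tape, agg))
  ad_add(tape, out, x)
}

knn_neighbors <- function(coords, k) {
  k <- min(k, nrow(coords) - 1L)
  cpp_knn(coords, as.integer(k))
}

# Deterministic, permutation-stable FPS start: the point farthest from the
# cloud centroid.
fps_geom_start <- function(coords) {
  ctr <- colMeans(coords)
  d2 <- rowSums(sweep(coords, 2, ctr)^2)
  which.max(d2)
}

pointtransformer_fwd <- function(tape, model, pn, coords, x) {
  cfg <- model$cfg
  d <- cfg$dims
  x <- nn_mlp(tape, pn, "embed", x, 2L, act_last = TRUE)
  pts <- list(coords)
  feats <- list()
  nb <- knn_neighbors(coords, cfg$k)
  for (b in seq_len(cfg$blocks[1])) {
    x <- pt_block_fwd(tape, pn, paste0("enc1.", b), x, coords, nb)
  }
  feats[[1]] <- x
  for (s in 2:5) {
    prev <- pts[[s - 1]]
    n_s <- max(1L, nrow(prev) %/% cfg$down_ratio)
    sel <- fps(prev, n_s, start = fps_geom_start(prev))
    cur <- prev[sel, , drop = FALSE]
    # pool features from the k nearest previous-level points
    kp <- min(cfg$k, nrow(prev))
    pool_nb <- t(vapply(seq_len(nrow(cur)), function(i) {
      d2 <- rowSums(sweep(prev, 2, cur[i, ])^2)
      order(d2)[seq_len(kp)]
    }, integer(kp)))
    h <- nn_linear(tape, pn, paste0("down", s), x)
    h <- ad_relu(tape, h)
    hg <- ad_gather(tape, h, as.vector(t(pool_nb)))
    x <- ad_group_max(tape, hg, kp)
    if (nrow(cur) >= 2L) {
      nb <- knn_neighbors(cur, cfg$k)
      for (b in seq_len(cfg$blocks[s])) {
        x <- pt_block_fwd(tape, pn, paste0("enc", s, ".", b), x, cur, nb)
      }
    }
    pts[[s]] <- cur
    feats[[s]] <- x
  }
  for (s in 4:1) {
    fine <- pts[[s]]; coarse <- pts[[s + 1]]
    up_idx <- cpp_nn(fine, coarse)$idx
    up <- nn_linear(tape, pn, paste0("up", s), ad_gather(tape, x, up_idx))
    skip <- nn_linear(tape, pn, paste0("skip", s), feats[[s]])
    x <- ad_relu(tape, ad_add(tape, up, skip))
    if (nrow(fine) >= 2L) {
      nb <- knn_neighbors(fine, cfg$k)
      x <- pt_block_fwd(tape, pn, paste0("dec", s), x, fine, nb)
    }
  }
  nn_mlp(tape, pn, "head", x, 2L)
}

seg_forward_tape <- function(tape, model, pn, coords, features, graph = NULL) {
  x_in <- cbind(coords, features)
  if (model$arch == "pointnet") {
    h <- x_in
    local <- NULL
    for (i in seq_along(model$cfg$point_dims)) {
      h <- ad_relu(tape, nn_linear(tape, pn, paste0("pt", i), h))
      if (i == model$cfg$local_at) local <- h
    }
    glob <- ad_tile_rows(tape, ad_colmax(tape, h), nrow(coords))
    h <- ad_cbind(tape, glob, local)
    nn_mlp(tape, pn, "head", h, length(model$cfg$head_dims) + 1L)
  } else if (model$arch == "dgcnn") {
    if (is.null(graph)) stop_fmt("dgcnn requires a knn graph")
    h <- x_in
    taps <- list()
    for (i in seq_along(model$cfg$ec_dims)) {
      h <- edgeconv_fwd(tape, pn, paste0("ec", i), h, graph$neighbors)
      taps[[i]] <- h
    }
    cat <- taps[[1]]
    for (i in seq_along(taps)[-1]) cat <- ad_cbind(tape, cat, taps[[i]])
    emb <- ad_relu(tape, nn_linear(tape, pn, "emb", cat))
    glob <- ad_tile_rows(tape, ad_colmax(tape, emb), nrow(coords))
    h <- ad_cbind(tape, glob, cat)
    nn_mlp(tape, pn, "head", h, length(model$cfg$head_dims) + 1L)
  } else {
    pointtransformer_fwd(tape, model, pn, coords, x_in)
  }
}

#' Forward pass of a point segmentation network
#'
#' Deterministic given weights and inputs, and permutation-equivariant:
#' permuting the input rows (with a consistently relabeled graph) permutes
#' the output logits identically.
#'
#' @param model a [build_seg_model()] object.
#' @param coords n x 3 normalized coordinates.
#' @param features n x 125 patch features.
#' @param graph kNN graph from [knn_graph()] (required for `dgcnn`).
#' @return n x `n_classes` logit matrix.
#' @export
seg_forward <- function(model, coords, features, graph = NULL) {
  stopifnot(inherits(model, "seg_model"),
            nrow(coords) == nrow(features))
  tape <- ad_tape()
  pn <- nn_param_nodes(tape, model$params)
  ad_val(seg_forward_tape(tape, model, pn, coords, features, graph))
}

# Cross-entropy + soft Dice on the tape (used in training).
ce_dice_tape <- function(tape, logits, labels, n_classes = 4L,
                         delta = 1e-5) {
  n <- nrow(ad_val(logits))
  onehot <- matrix(0, n, n_classes)
  onehot[cbind(seq_len(n), labels + 1L)] <- 1
  logp <- ad_log_softmax(tape, logits)
  ce <- ad_scale(tape, ad_sum(tape, ad_mul(tape, logp, onehot)), -1 / n)
  p <- ad_exp(tape, logp)
  ones <- matrix(1, 1, n)
  inter <- ad_matmul(tape, ones, ad_mul(tape, p, onehot))   # 1 x C
  psum <- ad_matmul(tape, ones, p)
  ysum <- matrix(colSums(onehot), 1L)
  num <- ad_add(tape, ad_scale(tape, inter, 2), matrix(delta, 1, n_classes))
  den <- ad_add(tape, ad_add(tape, psum, ysum),
                matrix(delta, 1, n_classes))
  dice <- ad_div(tape, num, den)
  dice_loss <- ad_sub(tape, matrix(1, 1, 1), ad_mean(tape, dice))
  ad_add(tape, ce, dice_loss)
}

#' Combined cross-entropy and soft Dice loss
#'
#' `CE + mean_c (1 - Dice_c)` with soft Dice smoothed by `delta = 1e-5` in
#' numerator and denominator. Non-negative and minimized by a confident
#' correct prediction.
#'
#' @param logits n x C logit matrix.
#' @param labels 0-based integer class labels.
#' @param n_classes number of classes.
#' @param delta Dice smoothing term.
#' @return scalar loss.
#' @export
ce_dice_loss <- function(logits, labels, n_classes = 4L, delta = 1e-5) {
  stopifnot(nrow(logits) == length(labels), all(labels >= 0),
            all(labels < n_classes))
  tape <- ad_tape()
  as.numeric(ad_val(ce_dice_tape(tape, ad_node(tape, logits),
                                 as.integer(labels), n_classes, delta)))
}

#' Random rigid augmentation of point coordinates
#'
#' Applies one seeded similarity transform `s * R * x + t` to all points of
#' a cloud: per-axis rotations within `±rot_deg`, isotropic scale within
#' `scale`, translation within `±trans`.
#'
#' @param coords n x 3 matrix.
#' @param seed RNG seed (NULL: use current RNG state).
#' @param rot_deg per-axis rotation range in degrees.
#' @param trans translation range in normalized units.
#' @param scale length-2 scale range.
#' @return transformed n x 3 matrix.
#' @export
rigid_augment <- function(coords, seed = NULL, rot_deg = 15,
                          trans = 0.1, scale = c(0.9, 1.1)) {
  with_seed(seed, {
    ang <- runif(3, -rot_deg, rot_deg) * pi / 180
    s <- runif(1, scale[1], scale[2])
    tr <- runif(3, -trans, trans)
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    R <- Rz %*% Ry %*% Rx
    sweep(s * coords %*% t(R), 2, tr, `+`)
  })
}

#' Training configuration for point segmentation networks
#'
#' @param epochs training epochs (default 1000).
#' @param lr initial Adam learning rate.
#' @param weight_decay Adam weight decay.
#' @param lr_floor cosine annealing floor as a fraction of `lr`.
#' @param n_points points sampled per forward pass (default 2048).
#' @param augment list of [rigid_augment()] ranges, or NULL to disable.
#' @param seed RNG seed governing sampling, augmentation and shuffling.
#' @return a `seg_train_config` list.
#' @export
seg_train_config <- function(epochs = 1000L, lr = 1e-3, weight_decay = 1e-5,
                             lr_floor = 0.05, n_points = 2048L,
                             augment = list(rot_deg = 15, trans = 0.1,
                                            scale = c(0.9, 1.1)),
                             seed = 1L) {
  stopifnot(lr_floor > 0, lr_floor <= 1, n_points >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay, lr_floor = lr_floor,
                 n_points = as.integer(n_points), augment = augment,
                 seed = seed),
            class = "seg_train_config")
}

#' Train a point segmentation network
#'
#' Adam with cosine-annealed learning rate. Every step draws `n_points`
#' points uniformly without replacement from one case (with replacement if
#' the case is smaller), applies a random rigid augmentation to the
#' coordinates, and minimizes the combined cross-entropy/Dice loss. Fully
#' seeded.
#'
#' @param model a [build_seg_model()] object.
#' @param cases list of cases, each a list with elements `cloud`
#'   (a `keypoint_cloud`) and `labels` (0-based per-point classes).
#' @param config a [seg_train_config()].
#' @return list with the trained `model` and a per-epoch `loss_history`.
#' @export
train_seg <- function(model, cases, config = seg_train_config()) {
  stopifnot(inherits(model, "seg_model"), length(cases) >= 1)
  params <- model$params
  state <- adam_init(params)
  history <- numeric(config$epochs)
  gk <- if (model$arch == "dgcnn") model$cfg$k else NULL
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs) - 1L) {
      lr <- cosine_lr(ep, config$epochs, config$lr, config$lr_floor)
      losses <- numeric(length(cases))
      for (ci in sample(seq_along(cases))) {
        cs <- cases[[ci]]
        K <- nrow(cs$cloud$coords)
        sel <- if (K >= config$n_points) {
          sample(K, config$n_points)
        } else sample(K, config$n_points, replace = TRUE)
        co <- cs$cloud$coords[sel, , drop = FALSE]
        fe <- cs$cloud$features[sel, , drop = FALSE]
        la <- as.integer(cs$labels[sel])
        if (!is.null(config$augment)) {
          co <- rigid_augment(co, seed = NULL,
                              rot_deg = config$augment$rot_deg,
                              trans = config$augment$trans,
                              scale = config$augment$scale)
        }
        graph <- if (!is.null(gk)) knn_graph(co, gk) else NULL
        tape <- ad_tape()
        pn <- nn_param_nodes(tape, params)
        logits <- seg_forward_tape(tape, model, pn, co, fe, graph)
        loss <- ce_dice_tape(tape, logits, la, model$n_classes)
        ad_backward(tape, loss)
        grads <- nn_grads(pn, params)
        upd <- adam_step(params, grads, state, lr,
                         weight_decay = config$weight_decay)
        params <- upd$params
        state <- upd$state
        losses[ci] <- as.numeric(ad_val(loss))
      }
      history[ep + 1L] <- mean(losses)
    }
  })
  model$params <- params
  list(model = model, loss_history = history)
}

#' Accumulated full-cloud inference
#'
#' Runs the forward pass `rounds` times on seeded random subsets of
#' `n_points` points and sums the per-round softmax scores. Subsets are
#' drawn coverage-first: not-yet-covered points are exhausted before covered
#' points are resampled, so every point is scored at least once. Labels are
#' the argmax of the accumulated scores (ties go to the lowest class index).
#'
#' @param model trained [build_seg_model()].
#' @param cloud a `keypoint_cloud`.
#' @param rounds forward passes (default 50).
#' @param n_points points per pass (default 2048).
#' @param seed RNG seed for subset selection.
#' @return a `point_scores` list: `scores` (n x C), `labels` (0-based),
#'   `coverage`, `na` (TRUE for an empty cloud).
#' @export
infer_full_cloud <- function(model, cloud, rounds = 50L, n_points = 2048L,
                             seed = 1L) {
  K <- nrow(cloud$coords)
  if (K == 0L) {
    return(structure(list(scores = matrix(0, 0, model$n_classes),
                          labels = integer(0), coverage = integer(0),
                          na = TRUE), class = "point_scores"))
  }
  scores <- matrix(0, K, model$n_classes)
  coverage <- integer(K)
  N <- min(n_points, K)
  gk <- if (model$arch == "dgcnn") model$cfg$k else NULL
  with_seed(seed, {
    for (r in seq_len(rounds)) {
      uncov <- which(coverage == 0L)
      sel <- if (length(uncov) >= N) {
        if (length(uncov) == 1L) uncov else sample(uncov, N)
      } else {
        rest <- setdiff(seq_len(K), uncov)
        extra <- if (length(rest) == 1L) rest else {
          sample(rest, N - length(uncov))
        }
        c(uncov, extra)
      }
      co <- cloud$coords[sel, , drop = FALSE]
      fe <- cloud$features[sel, , drop = FALSE]
      graph <- if (!is.null(gk) && length(sel) >= 2L) {
        knn_graph(co, gk)
      } else NULL
      logits <- seg_forward(model, co, fe, graph)
      m <- apply(logits, 1, max)
      p <- exp(logits - m)
      p <- p / rowSums(p)
      scores[sel, ] <- scores[sel, ] + p
      coverage[sel] <- coverage[sel] + 1L
    }
    # guarantee coverage even if rounds * N < K
    while (any(coverage == 0L)) {
      uncov <- which(coverage == 0L)
      sel <- head(uncov, N)
      if (length(sel) < N) {
        sel <- c(sel, sample(seq_len(K), N - length(sel)))
      }
      co <- cloud$coords[sel, , drop = FALSE]
      fe <- cloud$features[sel, , drop = FALSE]
      graph <- if (!is.null(gk) && length(sel) >= 2L) {
        knn_graph(co, gk)
      } else NULL
      logits <- seg_forward(model, co, fe, graph)
      m <- apply(logits, 1, max)
      p <- exp(logits - m)
      scores[sel, ] <- scores[sel, ] + p / rowSums(p)
      coverage[sel] <- coverage[sel] + 1L
    }
  })
  labels <- max.col(scores, ties.method = "first") - 1L
  structure(list(scores = scores, labels = labels, coverage = coverage,
                 na = FALSE), class = "point_scores")
}

#' Split a labeled cloud into per-fissure point sets
#'
#' @param cloud a `keypoint_cloud`.
#' @param scores a `point_scores` from [infer_full_cloud()] (or a plain
#'   0-based label vector).
#' @return list with `points` (list of 3 coordinate matrices for classes
#'   1..3) and `na` (logical length 3; TRUE where a class is empty).
#' @export
split_by_label <- function(cloud, scores) {
  labels <- if (inherits(scores, "point_scores")) scores$labels else scores
  stopifnot(length(labels) == nrow(cloud$coords))
  pts <- lapply(1:3, function(c) {
    cloud$coords[labels == c, , drop = FALSE]
  })
  list(points = pts, na = vapply(pts, function(p) nrow(p) == 0L, logical(1)))
}

#' Save / load a segmentation model checkpoint
#'
#' Single-file checkpoint with the architecture configuration embedded.
#' @param model a `seg_model`.
#' @param path checkpoint path.
#' @export
save_seg_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_seg_model
#' @export
load_seg_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "seg_model"))
  m
}
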