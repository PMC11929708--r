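# Point-cloud-to-mesh autoencoder: a DGCNN encoder compresses a point cloud
# to a latent code; the decoder deforms a fissure-homeomorphic template
# plane by two residual per-vertex MLP steps. Trained with a regularized
# mesh loss (chamfer + normal consistency + edge length + Laplacian
# smoothness).

#' Planar template mesh
#'
#' Regular grid of `sqrt(M) x sqrt(M)` vertices on the z = 0 plane with
#' `x, y` sampled over `[-0.3, 0.3]`, `M` being the square number closest to
#' `N`. Quads are split into two triangles along a fixed diagonal, giving
#' `2 (sqrt(M) - 1)^2` faces.
#'
#' @param N target number of input points (default 2048, giving M = 2025).
#' @return a `surface_mesh` with attribute `grid_n`.
#' @export
make_template <- function(N = 2048L) {
  stopifnot(N >= 4L)
  s0 <- floor(sqrt(N))
  s <- if (abs(s0^2 - N) <= abs((s0 + 1)^2 - N)) s0 else s0 + 1L
  s <- as.integer(s)
  g <- seq(-0.3, 0.3, length.out = s)
  xy <- expand.grid(x = g, y = g)          # x fastest
  V <- cbind(xy$x, xy$y, 0)
  vid <- function(i, j) (j - 1L) * s + i   # i along x, j along y
  faces <- matrix(0L, 2L * (s - 1L)^2, 3L)
  f <- 1L
  for (j in seq_len(s - 1L)) {
    for (i in seq_len(s - 1L)) {
      v00 <- vid(i, j); v10 <- vid(i + 1L, j)
      v01 <- vid(i, j + 1L); v11 <- vid(i + 1L, j + 1L)
      faces[f, ] <- c(v00, v10, v11)
      faces[f + 1L, ] <- c(v00, v11, v01)
      f <- f + 2L
    }
  }
  m <- new_mesh(V, faces, frame = "normalized")
  attr(m, "grid_n") <- s
  m
}

#' Farthest point sampling
#'
#' Greedy subset selection: starting from `start`, each added point
#' maximizes the minimum distance to the already-chosen set (ties resolved
#' toward the lower index). Deterministic.
#'
#' @param points n x 3 matrix.
#' @param N subset size; all indices are returned when `N >= n`.
#' @param start 1-based start index (default 1).
#' @return integer vector of selected indices in selection order.
#' @export
fps <- function(points, N, start = 1L) {
  points <- rbind(points)
  n <- nrow(points)
  if (N >= n) return(seq_len(n))
  sel <- integer(N)
  sel[1L] <- start
  mind <- rowSums(sweep(points, 2, points[start, ])^2)
  for (i in seq_len(N - 1L)) {
    nxt <- which.max(mind)
    sel[i + 1L] <- nxt
    mind <- pmin(mind, rowSums(sweep(points, 2, points[nxt, ])^2))
  }
  sel
}

#' Pad a point cloud to a fixed size with randomly offset duplicates
#'
#' Keeps the original points and appends `N - n` copies of uniformly chosen
#' originals perturbed by isotropic Gaussian offsets. Used to diminish the
#' density domain shift when sparse segmented clouds are fed to the
#' autoencoder.
#'
#' @param points n x 3 matrix with `1 <= n <= N`.
#' @param N target size.
#' @param sigma_pad offset standard deviation in normalized units.
#' @param seed RNG seed.
#' @return N x 3 matrix whose first n rows are the input points.
#' @export
pad_cloud <- function(points, N, sigma_pad = 0.05, seed = 1L) {
  points <- rbind(points)
  n <- nrow(points)
  if (n > N) stop_fmt("pad_cloud: n (%d) > N (%d); use fps instead", n, N)
  if (n == N) return(points)
  with_seed(seed, {
    src <- sample(n, N - n, replace = TRUE)
    offs <- matrix(rnorm(3 * (N - n), sd = sigma_pad), ncol = 3)
    rbind(points, points[src, , drop = FALSE] + offs)
  })
}

#' Chamfer distance between point sets
#'
#' Sum of the two directed mean squared nearest-neighbor distances:
#' `mean_a min_b |a-b|^2 + mean_b min_a |a-b|^2`. Symmetric, non-negative,
#' zero iff the sets cover each other exactly.
#'
#' @param A,B non-empty point matrices (n x 3).
#' @return scalar distance.
#' @export
chamfer <- function(A, B) {
  A <- rbind(A); B <- rbind(B)
  if (nrow(A) == 0L || nrow(B) == 0L) stop_fmt("chamfer: empty point set")
  mean(cpp_nn(A, B)$d2) + mean(cpp_nn(B, A)$d2)
}

# Unique undirected edges of a triangle mesh (E x 2, sorted pairs).
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Pairs of faces sharing an edge (P x 2 face indices).
face_adjacency <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_len(nrow(faces)), times = 3)
  grp <- split(fid, key)
  prs <- grp[lengths(grp) >= 2]
  if (length(prs) == 0) return(matrix(0L, 0, 2))
  do.call(rbind, lapply(prs, function(fs) {
    fs <- sort(fs)
    t(utils::combn(fs, 2))
  }))
}

face_normals <- function(V, faces) {
  a <- V[faces[, 1], , drop = FALSE]
  b <- V[faces[, 2], , drop = FALSE]
  c <- V[faces[, 3], , drop = FALSE]
  u <- b - a; w <- c - a
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

#' Mesh regularizers: normal consistency, edge length, Laplacian smoothness
#'
#' * `nc`: mean over adjacent-face pairs of `1 - cos` of the angle between
#'   face normals (degenerate zero-area faces excluded);
#' * `el`: mean squared edge length over unique edges;
#' * `ls`: mean squared norm of the uniform graph Laplacian applied to the
#'   vertices (neighbor mean minus vertex).
#'
#' All three are non-negative; `nc` is scale-invariant while `el` and `ls`
#' scale with the squared mesh size.
#'
#' @param mesh a `surface_mesh`.
#' @return named numeric vector `c(nc, el, ls)`.
#' @export
mesh_regularizers <- function(mesh) {
  V <- mesh$vertices; faces <- mesh$faces
  nrm <- face_normals(V, faces)
  len <- sqrt(rowSums(nrm^2))
  adj <- face_adjacency(faces)
  if (nrow(adj) > 0) {
    ok <- len[adj[, 1]] > 1e-12 & len[adj[, 2]] > 1e-12
    adj <- adj[ok, , drop = FALSE]
  }
  nc <- if (nrow(adj) == 0) 0 else {
    cosang <- rowSums(nrm[adj[, 1], , drop = FALSE] *
                        nrm[adj[, 2], , drop = FALSE]) /
      (len[adj[, 1]] * len[adj[, 2]])
    mean(1 - cosang)
  }
  ed <- mesh_edges(faces)
  el <- mean(rowSums((V[ed[, 1], , drop = FALSE] -
                        V[ed[, 2], , drop = FALSE])^2))
  L <- uniform_laplacian(nrow(V), ed)
  ls <- mean(rowSums((L %*% V)^2))
  c(nc = nc, el = el, ls = ls)
}

# Dense uniform graph Laplacian: (mean of neighbors) - vertex.
uniform_laplacian <- function(M, edges) {
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = M)
  L <- matrix(0, M, M)
  w1 <- 1 / deg[edges[, 1]]
  w2 <- 1 / deg[edges[, 2]]
  L[cbind(edges[, 1], edges[, 2])] <- w1
  L[cbind(edges[, 2], edges[, 1])] <- w2
  diag(L) <- -1
  L
}

#' Autoencoder configuration
#'
#' @param N input points per forward pass (default 2048).
#' @param h latent dimension (default 512).
#' @param k encoder kNN graph size.
#' @param w_cd,w_nc,w_el,w_ls loss term weights (defaults 1, 0.1, 1, 0.1).
#' @param epochs training epochs.
#' @param lr,weight_decay,lr_floor Adam / cosine schedule settings.
#' @param sigma_pad padding offset scale for sparse inputs.
#' @param seed RNG seed.
#' @return a `pcae_config` list.
#' @export
pcae_config <- function(N = 2048L, h = 512L, k = 16L,
                        w_cd = 1, w_nc = 0.1, w_el = 1, w_ls = 0.1,
                        epochs = 200L, lr = 1e-3, weight_decay = 1e-5,
                        lr_floor = 0.05, sigma_pad = 0.05, seed = 1L) {
  stopifnot(N >= 4, all(c(w_cd, w_nc, w_el, w_ls) >= 0))
  structure(list(N = as.integer(N), h = as.integer(h), k = as.integer(k),
                 w_cd = w_cd, w_nc = w_nc, w_el = w_el, w_ls = w_ls,
                 epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay, lr_floor = lr_floor,
                 sigma_pad = sigma_pad, seed = seed),
            class = "pcae_config")
}

# Frozen widths: EdgeConv stack (64, 64, 128), embedding 512, decoder MLPs
# (h+3) -> 576 -> 576 -> 3; with h = 512 the total is 1.42 M parameters.
#' Build the point-cloud-to-mesh autoencoder
#'
#' @param cfg a [pcae_config()].
#' @param seed weight initialization seed.
#' @return a `pcae_model`.
#' @export
build_pcae <- function(cfg = pcae_config(), seed = 1L) {
  params <- list()
  dec_w <- 576L
  with_seed(seed, {
    params <- nn_init_linear(params, "ec1", 6L, 64L)
    params <- nn_init_linear(params, "ec2", 128L, 64L)
    params <- nn_init_linear(params, "ec3", 128L, 128L)
    params <- nn_init_linear(params, "emb", 256L, cfg$h)
    params <- nn_init_mlp(params, "f1.", c(cfg$h + 3L, dec_w, dec_w, 3L))
    params <- nn_init_mlp(params, "f2.", c(cfg$h + 3L, dec_w, dec_w, 3L))
  })
  structure(list(params = params, cfg = cfg,
                 template = make_template(cfg$N)),
            class = "pcae_model")
}

#' @export
print.pcae_model <- function(x, ...) {
  cat(sprintf("<pcae_model N=%d h=%d, %.2f M parameters>\n",
              x$cfg$N, x$cfg$h, count_parameters(x) / 1e6))
  invisible(x)
}

pcae_encode_tape <- function(tape, model, pn, points) {
  cfg <- model$cfg
  nb <- knn_neighbors(points, cfg$k)
  h <- points
  taps <- list()
  for (i in 1:3) {
    h <- edgeconv_fwd(tape, pn, paste0("ec", i), h, nb)
    taps[[i]] <- h
  }
  cat <- ad_cbind(tape, ad_cbind(tape, taps[[1]], taps[[2]]), taps[[3]])
  emb <- ad_relu(tape, nn_linear(tape, pn, "emb", cat))
  ad_colmax(tape, emb)   # 1 x h latent code
}

pcae_decode_tape <- function(tape, model, pn, z) {
  M <- nrow(model$template$vertices)
  Z <- ad_tile_rows(tape, z, M)
  V0 <- model$template$vertices
  d1 <- nn_mlp(tape, pn, "f1.", ad_cbind(tape, Z, V0), 3L)
  V1 <- ad_add(tape, d1, V0)
  d2 <- nn_mlp(tape, pn, "f2.", ad_cbind(tape, Z, V1), 3L)
  ad_add(tape, d2, V1)
}

#' Encode a point cloud to a latent code
#'
#' EdgeConv feature stack followed by a global max-pool; permutation
#' invariant.
#'
#' @param model a [build_pcae()] model.
#' @param points exactly `N` x 3 coordinates (use [fps()] / [pad_cloud()]
#'   to reach `N`).
#' @return latent vector of length `h`.
#' @export
pcae_encode <- function(model, points) {
  points <- rbind(points)
  if (nrow(points) != model$cfg$N) {
    stop_fmt("pcae_encode expects exactly %d points, got %d",
             model$cfg$N, nrow(points))
  }
  tape <- ad_tape()
  pn <- nn_param_nodes(tape, model$params)
  as.numeric(ad_val(pcae_encode_tape(tape, model, pn, points)))
}

#' Decode a latent code to a deformed template mesh
#'
#' The latent code is copied to every template vertex, concatenated with the
#' current vertex coordinates, and two shared per-vertex MLPs predict
#' residual displacements: `V1 = V0 + f1(Z, V0)`, `V2 = V1 + f2(Z, V1)`.
#' The output keeps the template connectivity and vertex order, so vertex i
#' corresponds to the same template grid position across shapes.
#'
#' @param model a [build_pcae()] model.
#' @param z latent vector of length `h`.
#' @return a `surface_mesh` with the template's faces.
#' @export
pcae_decode <- function(model, z) {
  tape <- ad_tape()
  pn <- nn_param_nodes(tape, model$params)
  zn <- ad_node(tape, matrix(z, 1L))
  V2 <- ad_val(pcae_decode_tape(tape, model, pn, zn))
  new_mesh(V2, model$template$faces, frame = "normalized")
}

# Regularized mesh loss on the tape. Chamfer uses fixed nearest-neighbor
# assignments recomputed every step (standard subgradient).
pcae_loss_tape <- function(tape, model, Vnode, target, cfg) {
  V <- ad_val(Vnode)
  faces <- model$template$faces
  total <- ad_node(tape, matrix(0, 1, 1))
  if (cfg$w_cd > 0) {
    ia <- cpp_nn(V, target)$idx
    ib <- cpp_nn(target, V)$idx
    dA <- ad_sub(tape, Vnode, target[ia, , drop = FALSE])
    dB <- ad_sub(tape, ad_gather(tape, Vnode, ib), target)
    cd <- ad_add(tape,
                 ad_scale(tape, ad_sum(tape, ad_square(tape, dA)), 1 / nrow(V)),
                 ad_scale(tape, ad_sum(tape, ad_square(tape, dB)),
                          1 / nrow(target)))
    total <- ad_add(tape, total, ad_scale(tape, cd, cfg$w_cd))
  }
  ed <- attr(model$template, "edges") %||% mesh_edges(faces)
  if (cfg$w_el > 0) {
    d <- ad_sub(tape, ad_gather(tape, Vnode, ed[, 1]),
                ad_gather(tape, Vnode, ed[, 2]))
    el <- ad_scale(tape, ad_sum(tape, ad_square(tape, d)), 1 / nrow(ed))
    total <- ad_add(tape, total, ad_scale(tape, el, cfg$w_el))
  }
  if (cfg$w_ls > 0) {
    L <- attr(model$template, "laplacian") %||%
      uniform_laplacian(nrow(V), ed)
    lv <- ad_matmul(tape, L, Vnode)
    ls <- ad_scale(tape, ad_sum(tape, ad_square(tape, lv)), 1 / nrow(V))
    total <- ad_add(tape, total, ad_scale(tape, ls, cfg$w_ls))
  }
  if (cfg$w_nc > 0) {
    adj <- attr(model$template, "face_adj") %||% face_adjacency(faces)
    nrm <- function(fcol) ad_gather(tape, Vnode, faces[, fcol])
    a <- nrm(1); b <- nrm(2); c <- nrm(3)
    u <- ad_sub(tape, b, a); w <- ad_sub(tape, c, a)
    cx <- function(m, i) ad_slice_cols(tape, m, i)
    cross <- ad_cbind(tape, ad_cbind(tape,
      ad_sub(tape, ad_mul(tape, cx(u, 2), cx(w, 3)),
             ad_mul(tape, cx(u, 3), cx(w, 2))),
      ad_sub(tape, ad_mul(tape, cx(u, 3), cx(w, 1)),
             ad_mul(tape, cx(u, 1), cx(w, 3)))),
      ad_sub(tape, ad_mul(tape, cx(u, 1), cx(w, 2)),
             ad_mul(tape, cx(u, 2), cx(w, 1))))
    n1 <- ad_gather(tape, cross, adj[, 1])
    n2 <- ad_gather(tape, cross, adj[, 2])
    dot <- ad_rowsum(tape, ad_mul(tape, n1, n2))
    l1 <- ad_sqrt(tape, ad_rowsum(tape, ad_square(tape, n1)), eps = 1e-12)
    l2 <- ad_sqrt(tape, ad_rowsum(tape, ad_square(tape, n2)), eps = 1e-12)
    cosang <- ad_div(tape, dot, ad_mul(tape, l1, l2))
    nc <- ad_sub(tape, matrix(1, 1, 1), ad_mean(tape, cosang))
    total <- ad_add(tape, total, ad_scale(tape, nc, cfg$w_nc))
  }
  total
}

#' Regularized mesh loss
#'
#' `w_cd * CD(vertices, targets) + w_nc * NC + w_el * EL + w_ls * LS`, with
#' the decoded vertices compared directly against the input points.
#'
#' @param mesh decoded `surface_mesh`.
#' @param target_points n x 3 target point set.
#' @param cfg a [pcae_config()] carrying the weights.
#' @return scalar loss.
#' @export
pcae_loss <- function(mesh, target_points, cfg = pcae_config()) {
  reg <- mesh_regularizers(mesh)
  cd <- if (cfg$w_cd > 0) chamfer(mesh$vertices, rbind(target_points)) else 0
  unname(cfg$w_cd * cd + cfg$w_nc * reg["nc"] + cfg$w_el * reg["el"] +
           cfg$w_ls * reg["ls"])
}

#' Train the point-cloud autoencoder
#'
#' Every step samples `N` area-weighted surface points from one ground-truth
#' fissure mesh (all fissure classes pooled), encodes them, decodes the
#' template, and minimizes the regularized mesh loss with Adam under a
#' cosine learning rate schedule. Fully seeded.
#'
#' @param gt_meshes list of `surface_mesh` objects.
#' @param cfg a [pcae_config()].
#' @param model optionally a pre-built [build_pcae()] model to continue.
#' @return list with trained `model` and `loss_history` (one entry per step).
#' @export
train_pcae <- function(gt_meshes, cfg = pcae_config(), model = NULL) {
  stopifnot(length(gt_meshes) >= 1)
  if (is.null(model)) model <- build_pcae(cfg, seed = cfg$seed)
  # cache template combinatorics for the loss
  attr(model$template, "edges") <- mesh_edges(model$template$faces)
  attr(model$template, "laplacian") <-
    uniform_laplacian(nrow(model$template$vertices),
                      attr(model$template, "edges"))
  attr(model$template, "face_adj") <- face_adjacency(model$template$faces)
  params <- model$params
  state <- adam_init(params)
  history <- numeric(0)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs) - 1L) {
      lr <- cosine_lr(ep, cfg$epochs, cfg$lr, cfg$lr_floor)
      for (mi in sample(seq_along(gt_meshes))) {
        target <- sample_surface(gt_meshes[[mi]], cfg$N, seed = NULL)
        tape <- ad_tape()
        pn <- nn_param_nodes(tape, params)
        z <- pcae_encode_tape(tape, model, pn, target)
        V2 <- pcae_decode_tape(tape, model, pn, z)
        loss <- pcae_loss_tape(tape, model, V2, target, cfg)
        ad_backward(tape, loss)
        upd <- adam_step(params, nn_grads(pn, params), state, lr,
                         weight_decay = cfg$weight_decay)
        params <- upd$params
        state <- upd$state
        history <- c(history, as.numeric(ad_val(loss)))
      }
    }
  })
  model$params <- params
  list(model = model, loss_history = history)
}

#' Reconstruct fissure meshes with the autoencoder
#'
#' One forward pass per fissure: point sets larger than `N` are reduced with
#' [fps()], smaller ones padded with [pad_cloud()]; empty sets yield an
#' n.a. flag and no mesh.
#'
#' @param point_sets list of 3 coordinate matrices (classes 1..3), e.g. from
#'   [split_by_label()].
#' @param model trained [build_pcae()] model.
#' @param seed RNG seed for padding.
#' @return list with `meshes` (list of 3, NULL where n.a.) and `na` flags.
#' @export
reconstruct_with_pcae <- function(point_sets, model, seed = 1L) {
  cfg <- model$cfg
  meshes <- vector("list", 3L)
  na <- logical(3L)
  for (i in 1:3) {
    pts <- rbind(point_sets[[i]])
    if (is.null(pts) || nrow(pts) == 0L) {
      na[i] <- TRUE
      next
    }
    if (nrow(pts) > cfg$N) {
      pts <- pts[fps(pts, cfg$N), , drop = FALSE]
    } else if (nrow(pts) < cfg$N) {
      pts <- pad_cloud(pts, cfg$N, cfg$sigma_pad,
                       seed = child_seed(seed, i))
    }
    z <- pcae_encode(model, pts)
    meshes[[i]] <- pcae_decode(model, z)
  }
  list(meshes = meshes, na = na)
}

#' Save / load an autoencoder checkpoint
#' @param model a `pcae_model`.
#' @param path checkpoint path.
#' @export
save_pcae <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pcae
#' @export
load_pcae <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "pcae_model"))
  m
}
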