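# Deterministic generator of toy lung cases: two ellipsoidal lungs, thin
# curved fissure sheets as low-order height fields with a bright Gaussian
# ridge profile, distractor blobs with the same local appearance, plus
# exact analytic ground-truth meshes and label maps. Every pipeline stage
# is testable on these cases without clinical data.

default_synth_params <- function() {
  list(
    lung_hu = -850,        # aerated lung background
    outside_hu = 50,       # soft tissue outside the lungs
    noise_sd = 30,         # additive Gaussian noise, HU
    ridge_amplitude = 400, # fissure ridge height above lung background, HU
    ridge_width = 1.0,     # Gaussian cross-profile sigma, voxels
    ridge_mod = 0.7,       # in-plane contrast modulation depth (fissure
                           # appearance varies along the sheet in CT)
    ridge_mod_freq = c(5, 9), # modulation cycles per lung semi-axis
    n_blobs = 4,           # bright ellipsoidal distractors per lung
    blob_amplitude = 400,  # distractor peak, HU (same as the ridge:
                           # local appearance alone cannot separate them)
    blob_radius = c(2, 5)  # blob sigma range, voxels
  )
}

# Ellipsoid geometry of the two "lungs" for a cubic volume of edge `size`.
lung_geometry <- function(size) {
  list(
    left = list(center = size * c(0.28, 0.5, 0.5),
                semi = size * c(0.17, 0.28, 0.47)),
    right = list(center = size * c(0.72, 0.5, 0.5),
                 semi = size * c(0.17, 0.28, 0.47))
  )
}

# Random low-order height field z = f(x, y) in lung-relative units.
draw_sheet_coefs <- function(w0_range, slope = 0.3, quad = 0.2) {
  c(w0 = runif(1, w0_range[1], w0_range[2]),
    b = runif(1, -slope, slope), c = runif(1, -slope, slope),
    d = runif(1, -quad, quad), e = runif(1, -quad, quad),
    g = runif(1, -quad, quad))
}

sheet_height <- function(coefs, u, v) {
  coefs["w0"] + coefs["b"] * u + coefs["c"] * v +
    coefs["d"] * u^2 + coefs["e"] * v^2 + coefs["g"] * u * v
}

# Triangulated analytic sheet clipped to the lung ellipsoid (normalized
# coordinates; exact, independent of the voxelized label map).
sheet_mesh <- function(coefs, lung, size) {
  ctr <- lung$center; sa <- lung$semi
  xs <- seq(ceiling(ctr[1] - sa[1]), floor(ctr[1] + sa[1]))
  ys <- seq(ceiling(ctr[2] - sa[2]), floor(ctr[2] + sa[2]))
  nx <- length(xs); ny <- length(ys)
  u <- (xs - ctr[1]) / sa[1]
  v <- (ys - ctr[2]) / sa[2]
  U <- matrix(u, nx, ny); V <- matrix(v, nx, ny, byrow = TRUE)
  W <- matrix(sheet_height(coefs, as.vector(U), as.vector(V)), nx, ny)
  valid <- U^2 + V^2 + W^2 <= 0.98
  Z <- ctr[3] + sa[3] * W
  vid <- matrix(0L, nx, ny)
  vid[valid] <- seq_len(sum(valid))
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  verts <- cbind(X[valid], Y[valid], Z[valid])
  faces <- list()
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      q <- c(vid[i, j], vid[i + 1, j], vid[i + 1, j + 1], vid[i, j + 1])
      if (all(q[c(1, 2, 3)] > 0)) faces[[length(faces) + 1]] <- q[c(1, 2, 3)]
      if (all(q[c(1, 3, 4)] > 0)) faces[[length(faces) + 1]] <- q[c(1, 3, 4)]
    }
  }
  faces <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), 0, 3)
  vn <- voxel_to_norm(verts, rep(size, 3L))
  new_mesh(vn, faces, frame = "normalized")
}

#' Generate a synthetic lung case
#'
#' Builds a cubic volume containing two ellipsoidal "lungs" on a soft-tissue
#' background, one fissure sheet in the left lung and two non-intersecting
#' sheets in the right lung. Sheets are random low-order height fields; the
#' volume carries lung background HU plus Gaussian noise, a bright Gaussian
#' ridge along each sheet, and bright ellipsoidal distractor blobs whose
#' local appearance matches the ridge. Labels mark voxels within half a
#' voxel (vertically) of their sheet; ground-truth meshes are triangulated
#' directly from the analytic height fields. Fully reproducible per seed.
#'
#' @param seed RNG seed.
#' @param size cubic edge length in voxels (>= 32; default 64).
#' @param params generator parameters, see `default_synth_params()` in the
#'   sources; entries can be overridden selectively.
#' @return a `synthetic_case`: `volume`, `lung_mask`, `labels`,
#'   `gt_meshes` (3 `surface_mesh`es: left oblique, right oblique, right
#'   horizontal), `params`, `seed`.
#' @export
generate_case <- function(seed = 1L, size = 64L, params = list()) {
  if (size < 32L) stop_fmt("size must be >= 32, got %d", size)
  p <- utils::modifyList(default_synth_params(), params)
  geo <- lung_geometry(size)
  with_seed(seed, {
    co <- seq_len(size) - 1L
    X <- array(co, c(size, size, size))
    Y <- aperm(X, c(2, 1, 3))
    Z <- aperm(X, c(3, 2, 1))
    rel <- function(lung) {
      list(u = (X - lung$center[1]) / lung$semi[1],
           v = (Y - lung$center[2]) / lung$semi[2],
           w = (Z - lung$center[3]) / lung$semi[3])
    }
    rl <- rel(geo$left); rr <- rel(geo$right)
    in_left <- rl$u^2 + rl$v^2 + rl$w^2 <= 1
    in_right <- rr$u^2 + rr$v^2 + rr$w^2 <= 1
    mask <- in_left | in_right
    # sheets: left oblique; right oblique (lower) + right horizontal (upper)
    coefs <- list(
      lo = draw_sheet_coefs(c(-0.15, 0.15)),
      ro = draw_sheet_coefs(c(-0.45, -0.2)),
      rh = draw_sheet_coefs(c(0.2, 0.35), slope = 0.12, quad = 0.08)
    )
    # enforce a vertical gap of >= 3 voxels between the two right sheets
    gap_u <- seq(-1, 1, length.out = 41)
    gd <- expand.grid(u = gap_u, v = gap_u)
    gsep <- (sheet_height(coefs$rh, gd$u, gd$v) -
               sheet_height(coefs$ro, gd$u, gd$v)) * geo$right$semi[3]
    deficit <- 3 - min(gsep)
    if (deficit > 0) coefs$rh["w0"] <- coefs$rh["w0"] +
        deficit / geo$right$semi[3]
    vol <- array(p$outside_hu, rep(size, 3L))
    vol[mask] <- p$lung_hu
    vol <- vol + array(rnorm(size^3, sd = p$noise_sd), rep(size, 3L))
    labels <- array(0L, rep(size, 3L))
    sheets <- list(
      list(coefs = coefs$lo, lung = geo$left, inl = in_left, r = rl, cls = 1L),
      list(coefs = coefs$ro, lung = geo$right, inl = in_right, r = rr,
           cls = 2L),
      list(coefs = coefs$rh, lung = geo$right, inl = in_right, r = rr,
           cls = 3L))
    for (sh in sheets) {
      W <- sheet_height(sh$coefs, sh$r$u, sh$r$v)
      F <- sh$lung$center[3] + sh$lung$semi[3] * W
      foot <- sh$r$u^2 + sh$r$v^2 + W^2 <= 0.98
      dz <- Z - F
      # in-plane contrast modulation (two random plane waves)
      f1 <- runif(1, p$ridge_mod_freq[1], p$ridge_mod_freq[2])
      f2 <- runif(1, p$ridge_mod_freq[1], p$ridge_mod_freq[2])
      ph <- runif(2, 0, 2 * pi)
      modf <- 1 + p$ridge_mod * (sin(2 * pi * f1 * sh$r$u + ph[1]) +
                                   sin(2 * pi * f2 * sh$r$v + ph[2]))
      ridge <- p$ridge_amplitude * modf *
        exp(-dz^2 / (2 * p$ridge_width^2))
      sel <- sh$inl & foot
      vol[sel] <- vol[sel] + ridge[sel]
      labels[sel & abs(dz) <= 0.5] <- sh$cls
    }
    # distractor blobs inside each lung
    for (lung in geo) {
      for (b in seq_len(p$n_blobs)) {
        repeat {
          c_uvw <- runif(3, -0.7, 0.7)
          if (sum(c_uvw^2) <= 0.7^2) break
        }
        bc <- lung$center + lung$semi * c_uvw
        br <- runif(3, p$blob_radius[1], p$blob_radius[2])
        blob <- p$blob_amplitude *
          exp(-((X - bc[1])^2 / (2 * br[1]^2) +
                  (Y - bc[2])^2 / (2 * br[2]^2) +
                  (Z - bc[3])^2 / (2 * br[3]^2)))
        vol[mask] <- vol[mask] + blob[mask]
      }
    }
    gt <- list(sheet_mesh(coefs$lo, geo$left, size),
               sheet_mesh(coefs$ro, geo$right, size),
               sheet_mesh(coefs$rh, geo$right, size))
    structure(list(volume = new_volume(vol, spacing = c(1, 1, 1)),
                   lung_mask = array(as.integer(mask), rep(size, 3L)),
                   labels = labels, gt_meshes = gt,
                   params = p, seed = seed, size = size),
              class = "synthetic_case")
  })
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf(
    "<synthetic_case %d^3, seed %d, %d lung voxels, %.2f%% labeled>\n",
    x$size, x$seed, sum(x$lung_mask),
    100 * sum(x$labels > 0) / max(1, sum(x$lung_mask))))
  invisible(x)
}

#' Label keypoints against the analytic sheets
#'
#' Assigns each keypoint the class of the nearest ground-truth sheet if its
#' exact distance to that mesh is below `threshold` voxels, else background.
#'
#' @param cloud a `keypoint_cloud` on the case's grid.
#' @param case a [generate_case()] result.
#' @param threshold assignment distance in voxel units (default 1).
#' @return integer vector of 0-based labels.
#' @export
label_keypoints <- function(cloud, case, threshold = 1.0) {
  n <- nrow(cloud$coords)
  if (n == 0) return(integer(0))
  thr_norm <- threshold * 2 / (case$size - 1)
  d <- vapply(case$gt_meshes, function(m) {
    cpp_point_tri_min_dist(cloud$coords, m$vertices, m$faces)
  }, numeric(n))
  d <- matrix(d, nrow = n)
  best <- max.col(-d, ties.method = "first")
  lab <- ifelse(d[cbind(seq_len(n), best)] <= thr_norm, best, 0L)
  as.integer(lab)
}

#' Generate a labeled synthetic dataset
#'
#' Generates `n_cases` cases, extracts Foerstner keypoint clouds, and
#' derives per-keypoint ground-truth labels by nearest-sheet assignment
#' within a distance threshold.
#'
#' @param n_cases number of cases (>= 1).
#' @param seed base seed; case i uses a derived child seed.
#' @param size volume edge length.
#' @param K_max keypoint budget per case (the budget binds, so the
#'   distinctiveness ranking concentrates points near the sheets).
#' @param threshold keypoint labeling distance, voxels.
#' @param sigma_grad,sigma_tensor,window Foerstner settings at toy scale:
#'   lighter smoothing and a tighter suppression window than the clinical
#'   defaults, matching the smaller structures of the generated volumes.
#' @return list of entries `list(case, cloud, labels)`.
#' @export
make_dataset <- function(n_cases, seed = 1L, size = 64L, K_max = 1000L,
                         threshold = 2.0, sigma_grad = 0.5,
                         sigma_tensor = 0.4, window = 3L) {
  stopifnot(n_cases >= 1)
  lapply(seq_len(n_cases), function(i) {
    cs <- generate_case(seed = child_seed(seed, i), size = size)
    cloud <- foerstner_keypoints(cs$volume, cs$lung_mask, K_max = K_max,
                                 sigma_grad = sigma_grad,
                                 sigma_tensor = sigma_tensor,
                                 window = window)
    list(case = cs, cloud = cloud,
         labels = label_keypoints(cloud, cs, threshold))
  })
}

#' Write a synthetic case in the pipeline's on-disk layout
#'
#' NIfTI volume, lung mask and label map, plus the three ground-truth
#' meshes as PLY with a JSON sidecar.
#'
#' @param case a [generate_case()] result.
#' @param dir output directory.
#' @export
save_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_volume(case$volume, file.path(dir, "image.nii.gz"))
  save_volume(new_volume(case$lung_mask + 0, case$volume$spacing),
              file.path(dir, "lung_mask.nii.gz"))
  save_volume(new_volume(case$labels + 0, case$volume$spacing),
              file.path(dir, "fissure_labels.nii.gz"))
  save_fissure_meshes(list(meshes = case$gt_meshes, na = rep(FALSE, 3)),
                      file.path(dir, "gt_meshes"))
  invisible(dir)
}
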