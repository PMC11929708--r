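# Dense surface reconstruction: PCA normal estimation with MST-consistent
# orientation, a regular-grid Poisson indicator solve with marching
# tetrahedra, fissure-topology post-processing (mask clipping + largest
# component), and topology-preserving binary thinning for label maps.

#' Construct a triangle surface mesh
#'
#' @param vertices M x 3 numeric matrix.
#' @param faces T x 3 integer matrix of 1-based vertex indices.
#' @param frame coordinate frame tag, `"normalized"` (unit cube per axis) or
#'   `"mm"`.
#' @return a `surface_mesh`.
#' @export
new_mesh <- function(vertices, faces, frame = "normalized") {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop_fmt("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces, frame = frame),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh %d vertices, %d faces (%s)>\n",
              nrow(x$vertices), nrow(x$faces), x$frame))
  invisible(x)
}

#' Number of boundary edges of a mesh
#'
#' Edges used by exactly one face. A watertight mesh has none; an open
#' fissure sheet has at least one.
#'
#' @param mesh a `surface_mesh`.
#' @return integer count.
#' @export
count_boundary_edges <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0L)
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sum(table(key) == 1L)
}

#' Convert a normalized-frame mesh to millimetres
#'
#' Normalized coordinates index the voxel lattice of `shape`; physical
#' positions are `origin + index * spacing`.
#'
#' @param mesh a `surface_mesh` in the normalized frame.
#' @param shape,spacing,origin the carrier volume geometry.
#' @return a `surface_mesh` in mm.
#' @export
mesh_to_mm <- function(mesh, shape, spacing, origin = c(0, 0, 0)) {
  stopifnot(mesh$frame == "normalized")
  idx <- sweep(sweep(mesh$vertices, 2, 1, `+`), 2, (shape - 1) / 2, `*`)
  mm <- sweep(sweep(idx, 2, spacing, `*`), 2, origin, `+`)
  new_mesh(mm, mesh$faces, frame = "mm")
}

#' Estimate consistently oriented point normals
#'
#' Per-point normals are the smallest-eigenvalue eigenvectors of the local
#' covariance over `k_n` neighbors; global sign consistency is obtained by
#' propagating orientation along a minimum spanning tree of the kNN graph
#' (weights `1 - |n_i . n_j|`), flipping a normal when it disagrees with its
#' tree parent.
#'
#' @param points n x 3 matrix, `n >= 3`.
#' @param k_n neighborhood size (default 30; clamped to `n - 1`).
#' @return an `oriented_points` list: `points`, unit `normals`.
#' @export
estimate_oriented_normals <- function(points, k_n = 30L) {
  points <- rbind(points)
  n <- nrow(points)
  if (n < 3L) stop_fmt("normal estimation needs >= 3 points")
  k <- min(k_n, n - 1L)
  nb <- cpp_knn(points, k)
  normals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    P <- points[c(i, nb[i, ]), , drop = FALSE]
    cv <- stats::cov(P)
    ev <- eigen(cv, symmetric = TRUE)
    normals[i, ] <- ev$vectors[, 3]
  }
  normals <- normals / sqrt(rowSums(normals^2))
  # orientation propagation over the MST of the kNN graph
  from <- rep(seq_len(n), times = k)
  to <- as.vector(nb)
  w <- 1 - abs(rowSums(normals[from, , drop = FALSE] *
                         normals[to, , drop = FALSE]))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = pmax(w, 1e-12)),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  g <- igraph::simplify(g, edge.attr.comb = "min")
  mst <- igraph::mst(g)
  comp <- igraph::components(mst)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    root <- members[1]
    bfs <- igraph::bfs(mst, root = root, unreachable = FALSE,
                       father = TRUE)
    ord <- as.integer(bfs$order)
    ord <- ord[!is.na(ord)]
    fathers <- as.integer(bfs$father)
    for (v in ord) {
      p <- fathers[v]
      if (is.na(p) || p <= 0) next
      if (sum(normals[v, ] * normals[p, ]) < 0) {
        normals[v, ] <- -normals[v, ]
      }
    }
  }
  structure(list(points = points, normals = normals),
            class = "oriented_points")
}

reconstruction_error <- function(msg) {
  stop(structure(class = c("reconstruction_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Trilinear splat of per-point vectors onto a grid; returns list of arrays.
splat_vectors <- function(points, vecs, gmin, h, res) {
  fx <- (points[, 1] - gmin[1]) / h
  fy <- (points[, 2] - gmin[2]) / h
  fz <- (points[, 3] - gmin[3]) / h
  ix <- pmin(pmax(floor(fx), 0), res - 2)
  iy <- pmin(pmax(floor(fy), 0), res - 2)
  iz <- pmin(pmax(floor(fz), 0), res - 2)
  tx <- fx - ix; ty <- fy - iy; tz <- fz - iz
  out <- list(array(0, c(res, res, res)), array(0, c(res, res, res)),
              array(0, c(res, res, res)))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    wgt <- (if (cx) tx else 1 - tx) * (if (cy) ty else 1 - ty) *
      (if (cz) tz else 1 - tz)
    lin <- (ix + cx + 1) + res * (iy + cy) + res * res * (iz + cz)
    for (d in 1:3) {
      acc <- rowsum(vecs[, d] * wgt, group = lin, reorder = FALSE)
      out[[d]][as.numeric(rownames(acc))] <-
        out[[d]][as.numeric(rownames(acc))] + acc
    }
  }
  out
}

trilinear_sample <- function(arr, points, gmin, h) {
  res <- dim(arr)[1]
  fx <- (points[, 1] - gmin[1]) / h
  fy <- (points[, 2] - gmin[2]) / h
  fz <- (points[, 3] - gmin[3]) / h
  ix <- pmin(pmax(floor(fx), 0), res - 2)
  iy <- pmin(pmax(floor(fy), 0), res - 2)
  iz <- pmin(pmax(floor(fz), 0), res - 2)
  tx <- fx - ix; ty <- fy - iy; tz <- fz - iz
  val <- 0
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    wgt <- (if (cx) tx else 1 - tx) * (if (cy) ty else 1 - ty) *
      (if (cz) tz else 1 - tz)
    lin <- (ix + cx + 1) + res * (iy + cy) + res * res * (iz + cz)
    val <- val + wgt * arr[lin]
  }
  val
}

#' Poisson surface reconstruction on a regular grid
#'
#' Solves the Poisson equation for the object indicator whose gradient
#' matches the oriented point normals: normals are splatted onto a
#' `2^depth` regular grid, lightly smoothed, their divergence is computed
#' with central differences, the Poisson equation is solved spectrally
#' (FFT), and the iso-surface through the mean indicator value at the input
#' samples is extracted with marching tetrahedra. Away from the grid
#' boundary the result is a closed, watertight surface; fissure topology is
#' produced afterwards by [clip_and_largest_component()].
#'
#' Away from the samples the indicator settles near the iso level, so the
#' raw iso-surface is trimmed by sample density: faces farther than
#' `trim` grid cells from every input point are dropped (the same
#' density-based trimming established Poisson implementations expose).
#'
#' @param cloud an [estimate_oriented_normals()] result.
#' @param depth grid resolution exponent (default 6, i.e. a 64^3 grid).
#' @param pad fractional bounding-box padding.
#' @param trim density trim radius in grid cells.
#' @return a `surface_mesh` in the input coordinate frame.
#' @export
poisson_reconstruct <- function(cloud, depth = 6L, pad = 0.2, trim = 6) {
  pts <- cloud$points
  if (nrow(pts) < 50L) {
    reconstruction_error(sprintf(
      "too few points for reconstruction (%d < 50)", nrow(pts)))
  }
  sv <- svd(sweep(pts, 2, colMeans(pts)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300)) {
    reconstruction_error("degenerate (collinear) point set")
  }
  res <- 2L^depth
  bbmin <- apply(pts, 2, min)
  bbmax <- apply(pts, 2, max)
  ext <- max(bbmax - bbmin)
  ctr <- (bbmin + bbmax) / 2
  size <- ext * (1 + 2 * pad)
  h <- size / (res - 1)
  gmin <- ctr - size / 2
  V <- splat_vectors(pts, cloud$normals, gmin, h, res)
  V <- lapply(V, gaussian_smooth3, sigma = 1)
  cdiff <- function(a, axis) {
    d <- dim(a)[axis]
    ip <- c(2:d, d); im <- c(1, 1:(d - 1))
    p <- switch(axis, a[ip, , ], a[, ip, ], a[, , ip])
    m <- switch(axis, a[im, , ], a[, im, ], a[, , im])
    (p - m) / (2 * h)
  }
  div <- cdiff(V[[1]], 1) + cdiff(V[[2]], 2) + cdiff(V[[3]], 3)
  # spectral solve of the periodic finite-difference Laplacian
  k <- 0:(res - 1)
  lam1 <- (2 * cos(2 * pi * k / res) - 2) / h^2
  lam <- outer(outer(lam1, lam1, `+`), lam1, `+`)
  dh <- fft(div)
  lam[1, 1, 1] <- 1
  ch <- dh / lam
  ch[1, 1, 1] <- 0
  chi <- Re(fft(ch, inverse = TRUE)) / res^3
  iso <- mean(trilinear_sample(chi, pts, gmin, h))
  mt <- cpp_marching_tets(as.numeric(chi), dim(chi), iso)
  if (nrow(mt$vertices) == 0) {
    reconstruction_error("empty iso-surface")
  }
  Vw <- sweep(mt$vertices * h, 2, gmin, `+`)
  mesh <- new_mesh(Vw, mt$faces, frame = "normalized")
  if (is.finite(trim) && nrow(mesh$faces) > 0) {
    dv <- sqrt(cpp_nn(mesh$vertices, pts)$d2)
    vok <- dv <= trim * h
    keep <- vok[mesh$faces[, 1]] | vok[mesh$faces[, 2]] |
      vok[mesh$faces[, 3]]
    mesh <- drop_faces(mesh, keep)
  }
  if (nrow(mesh$faces) == 0) reconstruction_error("empty trimmed surface")
  mesh
}

# Keep the flagged faces and prune unreferenced vertices.
drop_faces <- function(mesh, keep) {
  faces <- mesh$faces[keep, , drop = FALSE]
  if (nrow(faces) == 0) {
    return(new_mesh(mesh$vertices[0, , drop = FALSE],
                    matrix(integer(0), 0, 3), frame = mesh$frame))
  }
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  new_mesh(mesh$vertices[used, , drop = FALSE],
           matrix(remap[faces], ncol = 3), frame = mesh$frame)
}

#' Clip a mesh to a mask and keep the largest connected component
#'
#' Drops every triangle with at least one vertex in a background voxel of
#' the mask (or outside the grid), then keeps the face-connected component
#' with the most faces (ties resolved toward the component containing the
#' lowest face index) and prunes unreferenced vertices. Clipping a closed
#' reconstruction this way yields the open-surface fissure topology.
#'
#' @param mesh a `surface_mesh` in the normalized frame of `mask`.
#' @param mask 3D binary array.
#' @return a `surface_mesh`; may have zero faces (n.a. pathway).
#' @export
clip_and_largest_component <- function(mesh, mask) {
  if (nrow(mesh$faces) == 0) return(mesh)
  shape <- dim(mask)
  idx <- sweep(sweep(mesh$vertices, 2, 1, `+`), 2, (shape - 1) / 2, `*`)
  idx <- round(idx)
  inside <- idx[, 1] >= 0 & idx[, 1] <= shape[1] - 1 &
    idx[, 2] >= 0 & idx[, 2] <= shape[2] - 1 &
    idx[, 3] >= 0 & idx[, 3] <= shape[3] - 1
  vok <- logical(nrow(mesh$vertices))
  lin <- idx[inside, 1] + 1 + shape[1] * idx[inside, 2] +
    shape[1] * shape[2] * idx[inside, 3]
  vok[inside] <- mask[lin] > 0
  keep <- vok[mesh$faces[, 1]] & vok[mesh$faces[, 2]] & vok[mesh$faces[, 3]]
  faces <- mesh$faces[keep, , drop = FALSE]
  if (nrow(faces) == 0) {
    return(new_mesh(mesh$vertices[0, , drop = FALSE],
                    matrix(integer(0), 0, 3), frame = mesh$frame))
  }
  adj <- face_adjacency(faces)
  g <- igraph::graph_from_edgelist(
    if (nrow(adj) > 0) adj else matrix(1L, 0, 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(faces) - igraph::vcount(g)))
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie: component containing the lowest face index
    first_face <- vapply(best, function(b) {
      min(which(comp$membership == b))
    }, numeric(1))
    best <- best[which.min(first_face)]
  }
  faces <- faces[comp$membership == best, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  new_mesh(mesh$vertices[used, , drop = FALSE],
           matrix(remap[faces], ncol = 3), frame = mesh$frame)
}

#' Topology-preserving 3D binary thinning
#'
#' Iteratively removes border voxels whose deletion preserves local
#' topology (simple-point test: one 26-connected foreground component in
#' the 26-neighborhood and one 6-connected background component in the
#' 18-neighborhood), sweeping the six face directions until a fixpoint.
#' Voxels already one voxel thick along some axis are never removed, so
#' slab-like structures reduce to one-voxel-thick medial surfaces and a
#' thin sheet is a fixpoint. Output is a subset of the input with the same
#' 26-connectivity component count.
#'
#' @param mask 3D binary array.
#' @return thinned 3D binary array of the same shape.
#' @export
binary_thinning <- function(mask) {
  d <- dim(mask)
  out <- cpp_thin3d(as.integer(mask > 0), as.integer(d))
  array(out, d)
}

#' Reconstruct ground-truth style meshes from a label map
#'
#' Per fissure class: either thin the class mask to a medial surface
#' (`mode = "thinning"`) or uniformly sample up to 10 000 class voxels
#' (`mode = "sample10k"`, seeded); then treat the voxel centers (in
#' normalized coordinates) as a point cloud and run normal estimation,
#' Poisson reconstruction, and mask clipping. Empty classes are flagged
#' n.a.
#'
#' @param labels 3D integer array with classes 0 (background) to 3.
#' @param mask 3D binary lung mask, same shape.
#' @param mode `"thinning"` or `"sample10k"`.
#' @param depth Poisson grid depth.
#' @param k_n normal estimation neighborhood.
#' @param n_sample sample budget for `"sample10k"`.
#' @param seed RNG seed for sampling.
#' @return list with `meshes` (3, NULL where n.a.) and `na` flags.
#' @export
labelmap_to_meshes <- function(labels, mask, mode = c("thinning", "sample10k"),
                               depth = 6L, k_n = 30L, n_sample = 10000L,
                               seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(dim(labels) == dim(mask)))
  shape <- dim(labels)
  meshes <- vector("list", 3L)
  na <- logical(3L)
  for (cls in 1:3) {
    m <- labels == cls
    if (!any(m)) {
      na[cls] <- TRUE
      next
    }
    if (mode == "thinning") {
      m <- binary_thinning(m)
      vi <- which(m > 0, arr.ind = TRUE) - 1L
    } else {
      vi <- which(m, arr.ind = TRUE) - 1L
      if (nrow(vi) > n_sample) {
        vi <- with_seed(child_seed(seed, cls), {
          vi[sample(nrow(vi), n_sample), , drop = FALSE]
        })
      }
    }
    pts <- voxel_to_norm(vi, shape)
    mesh <- tryCatch({
      op <- estimate_oriented_normals(pts, k_n)
      clip_and_largest_component(poisson_reconstruct(op, depth), mask)
    }, reconstruction_error = function(e) NULL)
    if (is.null(mesh) || nrow(mesh$faces) == 0) {
      na[cls] <- TRUE
    } else {
      meshes[[cls]] <- mesh
    }
  }
  list(meshes = meshes, na = na)
}

#' Reconstruct dense fissure surfaces from segmented point sets
#'
#' Per fissure: normal estimation, Poisson reconstruction at the given
#' depth, and mask clipping with largest-component selection. Empty or
#' too-small point sets are flagged n.a. without raising; other fissures
#' are unaffected.
#'
#' @param point_sets list of 3 coordinate matrices in normalized
#'   coordinates (classes 1..3).
#' @param mask 3D binary lung mask.
#' @param depth Poisson grid depth (default 6).
#' @param k_n normal estimation neighborhood.
#' @return list with `meshes` (3, NULL where n.a.) and `na` flags.
#' @export
reconstruct_from_segmentation <- function(point_sets, mask, depth = 6L,
                                          k_n = 30L) {
  meshes <- vector("list", 3L)
  na <- logical(3L)
  for (i in 1:3) {
    pts <- point_sets[[i]]
    if (is.null(pts) || nrow(rbind(pts)) < 50L) {
      na[i] <- TRUE
      next
    }
    mesh <- tryCatch({
      op <- estimate_oriented_normals(rbind(pts), k_n)
      clip_and_largest_component(poisson_reconstruct(op, depth), mask)
    }, reconstruction_error = function(e) NULL)
    if (is.null(mesh) || nrow(mesh$faces) == 0) {
      na[i] <- TRUE
    } else {
      meshes[[i]] <- mesh
    }
  }
  list(meshes = meshes, na = na)
}

# --- mesh I/O ---------------------------------------------------------------

#' Read and write triangle meshes (ASCII PLY / OBJ)
#'
#' @param mesh a `surface_mesh`.
#' @param path file path; format chosen by extension (`.ply` or `.obj`).
#' @param frame frame tag recorded on load.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  V <- mesh$vertices; F <- mesh$faces
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(F)),
                 "property list uchar int vertex_indices", "end_header"),
               con)
    if (nrow(V)) {
      writeLines(paste(format(V[, 1], digits = 9, trim = TRUE),
                       format(V[, 2], digits = 9, trim = TRUE),
                       format(V[, 3], digits = 9, trim = TRUE)), con)
    }
    if (nrow(F)) writeLines(paste(3, F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L),
                            con)
  } else if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(V)) writeLines(paste("v", V[, 1], V[, 2], V[, 3]), con)
    if (nrow(F)) writeLines(paste("f", F[, 1], F[, 2], F[, 3]), con)
  } else stop_fmt("unsupported mesh format '.%s'", ext)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, frame = "normalized") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    lines <- readLines(path)
    hdr_end <- which(lines == "end_header")[1]
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)[1]))
    vlines <- lines[hdr_end + seq_len(nv)]
    V <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    flines <- lines[hdr_end + nv + seq_len(nf)]
    F <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(x) {
      as.integer(x[2:4]) + 1L
    }))
    if (nf == 0) F <- matrix(integer(0), 0, 3)
    if (nv == 0) V <- matrix(numeric(0), 0, 3)
  } else if (ext == "obj") {
    lines <- readLines(path)
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) {
      as.numeric(x[2:4])
    }))
    F <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
      as.integer(sub("/.*", "", x[2:4]))
    }))
    if (is.null(V)) V <- matrix(numeric(0), 0, 3)
    if (is.null(F)) F <- matrix(integer(0), 0, 3)
  } else stop_fmt("unsupported mesh format '.%s'", ext)
  new_mesh(V, F, frame = frame)
}

#' Save / load a per-case fissure mesh set
#'
#' Writes `fissure_LO.ply`, `fissure_RO.ply`, `fissure_RH.ply` plus a JSON
#' sidecar (`meshes.json`) carrying the coordinate frame and n.a. flags.
#'
#' @param rec a reconstruction result (`meshes` + `na`).
#' @param dir output directory (created if needed).
#' @export
save_fissure_meshes <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names3 <- c("fissure_LO.ply", "fissure_RO.ply", "fissure_RH.ply")
  frame <- "normalized"
  for (i in 1:3) {
    if (!rec$na[i] && !is.null(rec$meshes[[i]])) {
      frame <- rec$meshes[[i]]$frame
      write_mesh(rec$meshes[[i]], file.path(dir, names3[i]))
    }
  }
  jsonlite::write_json(list(frame = frame, na = rec$na),
                       file.path(dir, "meshes.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_fissure_meshes
#' @export
load_fissure_meshes <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "meshes.json"),
                              simplifyVector = TRUE)
  names3 <- c("fissure_LO.ply", "fissure_RO.ply", "fissure_RH.ply")
  meshes <- vector("list", 3L)
  for (i in 1:3) {
    p <- file.path(dir, names3[i])
    if (!side$na[i] && file.exists(p)) {
      meshes[[i]] <- read_mesh(p, frame = side$frame)
    }
  }
  list(meshes = meshes, na = as.logical(side$na))
}
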