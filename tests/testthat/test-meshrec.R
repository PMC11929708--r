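test_that("PCA normals are unit length and consistently oriented", {
  set.seed(21)
  # coplanar points: all normals +/- the plane normal, mutually consistent
  pl <- cbind(runif(60), runif(60), 0.2)
  op <- estimate_oriented_normals(pl, k_n = 10)
  expect_equal(rowSums(op$normals^2), rep(1, 60), tolerance = 1e-9)
  expect_true(all(abs(op$normals[, 3]) > 0.999))
  dots <- op$normals %*% t(op$normals)
  expect_true(all(dots > 0.99))
  # sphere samples: neighbor orientation agreement after propagation
  sp <- sphere_points(600, r = 1, seed = 4)
  ops <- estimate_oriented_normals(sp, k_n = 12)
  nb <- knn_graph(sp, 6)$neighbors
  agree <- mean(rowSums(ops$normals * ops$normals[nb[, 1], ]) > 0)
  expect_gt(agree, 0.95)
  # outward or inward as a whole (sign coherent with radial direction)
  radial <- sp / sqrt(rowSums(sp^2))
  expect_gt(abs(mean(rowSums(ops$normals * radial))), 0.9)
  expect_error(estimate_oriented_normals(pl[1:2, ]), ">= 3")
})

test_that("Poisson reconstruction meets the sphere accuracy contract", {
  pts <- sphere_points(3000, r = 0.5, seed = 8)
  op <- estimate_oriented_normals(pts, 30)
  mesh <- poisson_reconstruct(op, depth = 6)
  expect_equal(count_boundary_edges(mesh), 0L)  # watertight
  sm <- sample_surface(mesh, 4000, seed = 1)
  assd <- mean(abs(sqrt(rowSums(sm^2)) - 0.5))
  expect_lt(assd, 0.05 * 0.5)
  # failure signals
  expect_error(poisson_reconstruct(list(points = pts[1:10, ],
                                        normals = pts[1:10, ])),
               class = "reconstruction_error")
  line <- cbind(seq(0, 1, length.out = 100), 0, 0)
  expect_error(
    poisson_reconstruct(list(points = line,
                             normals = matrix(rep(c(0, 0, 1), 100), ncol = 3,
                                              byrow = TRUE))),
    class = "reconstruction_error")
})

test_that("flat sheet reconstruction stays close to the plane after clipping", {
  set.seed(5)
  n <- 3000
  pts <- cbind(runif(n, -0.5, 0.5), runif(n, -0.5, 0.5), 0)
  op <- estimate_oriented_normals(pts, 30)
  mesh <- poisson_reconstruct(op, depth = 6)
  mask <- array(1L, rep(32, 3))
  cl <- clip_and_largest_component(mesh, mask)
  sm <- sample_surface(cl, 3000, seed = 2)
  # mean distance from the reconstruction to the analytic unit square,
  # within 0.05 of the edge length
  sq <- square_mesh(0)
  sq$vertices[, 1:2] <- sq$vertices[, 1:2] - 0.5
  d <- fissurept:::cpp_point_tri_min_dist(sm, sq$vertices, sq$faces)
  expect_lt(mean(d), 0.05)
})

test_that("mask clipping drops outside faces and keeps the largest part", {
  # all vertices inside: unchanged face count
  sq <- square_mesh(z = 0)
  sq$vertices <- sq$vertices * 0.2 + 0.1
  mask1 <- array(1L, rep(16, 3))
  expect_equal(nrow(clip_and_largest_component(sq, mask1)$faces), 2L)
  # two disjoint patches: union-find oracle size kept
  set.seed(6)
  big <- make_template(25)          # 5x5 grid, 32 faces
  small <- square_mesh(z = 0.5)
  small$vertices[, 1:2] <- small$vertices[, 1:2] * 0.1 - 0.6
  comb <- new_mesh(rbind(big$vertices, small$vertices),
                   rbind(big$faces, small$faces + nrow(big$vertices)))
  kept <- clip_and_largest_component(comb, mask1)
  expect_equal(nrow(kept$faces), oracle_largest_component(comb$faces))
  # clipping a closed sphere with a half-space mask opens the surface
  pts <- sphere_points(2000, r = 0.5, seed = 9)
  mesh <- poisson_reconstruct(estimate_oriented_normals(pts, 30), 6)
  half <- array(0L, rep(32, 3))
  half[, , 1:16] <- 1L
  cl <- clip_and_largest_component(mesh, half)
  expect_gt(count_boundary_edges(cl), 0L)
  expect_lt(nrow(cl$faces), nrow(mesh$faces))
})

test_that("binary thinning reduces slabs to one-voxel sheets, preserving topology", {
  slab <- array(0L, c(20, 20, 20))
  slab[3:18, 3:18, 9:11] <- 1L
  th <- binary_thinning(slab)
  expect_true(all(slab[th > 0] == 1L))       # subset
  expect_identical(binary_thinning(th), th)  # idempotent
  # thickness along z reduced to 1 in the interior
  interior <- th[6:15, 6:15, ]
  expect_true(all(apply(interior, c(1, 2), sum) == 1))
  # component count preserved (one component before and after)
  cc <- function(a) {
    v <- which(a > 0, arr.ind = TRUE)
    if (nrow(v) == 0) return(0L)
    g <- igraph::graph_from_edgelist(matrix(integer(0), 0, 2),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, nrow(v))
    d <- as.matrix(dist(v, method = "maximum"))
    e <- which(d <= 1 & upper.tri(d), arr.ind = TRUE)
    if (nrow(e)) g <- igraph::add_edges(g, t(e))
    igraph::components(g)$no
  }
  expect_equal(cc(th), 1L)
  # a one-voxel-thick plane is a fixpoint
  p1 <- array(0L, c(10, 10, 10))
  p1[2:9, 2:9, 5] <- 1L
  expect_identical(binary_thinning(p1), p1)
  # empty in, empty out
  expect_equal(sum(binary_thinning(array(0L, c(8, 8, 8)))), 0L)
  # two separated slabs stay two components
  two <- array(0L, c(24, 12, 12))
  two[2:10, 3:10, 5:7] <- 1L
  two[14:22, 3:10, 5:7] <- 1L
  expect_equal(cc(binary_thinning(two)), 2L)
})

test_that("label maps reconstruct to meshes near the analytic sheets", {
  cs <- generate_case(seed = 17, size = 48)
  lm <- labelmap_to_meshes(cs$labels, cs$lung_mask, mode = "thinning")
  expect_false(any(lm$na))
  vox_mm <- 1
  for (i in 1:3) {
    gt <- mesh_to_mm(cs$gt_meshes[[i]], rep(48L, 3), rep(vox_mm, 3))
    pm <- mesh_to_mm(lm$meshes[[i]], rep(48L, 3), rep(vox_mm, 3))
    r <- surface_distances(pm, gt, n = 2000, seed = 3)
    expect_lt(r$assd, 2 * vox_mm)
    expect_gt(count_boundary_edges(lm$meshes[[i]]), 0L)  # open surfaces
  }
  # absent class: n.a.
  lbl2 <- cs$labels
  lbl2[lbl2 == 3L] <- 0L
  lm2 <- labelmap_to_meshes(lbl2, cs$lung_mask, mode = "thinning")
  expect_true(lm2$na[3])
  expect_false(lm2$na[1])
  # sample10k with a class smaller than the budget uses all voxels
  lm3 <- labelmap_to_meshes(cs$labels, cs$lung_mask, mode = "sample10k",
                            n_sample = 1e6)
  expect_false(any(lm3$na))
})

test_that("reconstruction from segmented point sets flags empty fissures", {
  cs <- generate_case(seed = 18, size = 64)
  kp <- foerstner_keypoints(cs$volume, cs$lung_mask, K_max = 1000,
                            sigma_grad = 0.5, sigma_tensor = 0.4, window = 3)
  lab <- label_keypoints(kp, cs, threshold = 2)
  sets <- split_by_label(kp, lab)
  sets$points[[2]] <- sets$points[[2]][0, , drop = FALSE]  # empty one fissure
  rec <- reconstruct_from_segmentation(sets$points, cs$lung_mask)
  expect_true(rec$na[2])
  # other fissures unaffected, open surfaces
  for (i in c(1, 3)) {
    if (!rec$na[i]) {
      expect_gt(count_boundary_edges(rec$meshes[[i]]), 0L)
    }
  }
  expect_false(all(rec$na))
})

test_that("PLY and OBJ mesh files round-trip", {
  m <- make_template(16)
  for (ext in c(".ply", ".obj")) {
    f <- tempfile(fileext = ext)
    write_mesh(m, f)
    m2 <- read_mesh(f)
    expect_equal(m2$vertices, unname(m$vertices), tolerance = 1e-6)
    expect_equal(m2$faces, m$faces)
  }
  rec <- list(meshes = list(m, NULL, m), na = c(FALSE, TRUE, FALSE))
  d <- tempfile()
  save_fissure_meshes(rec, d)
  back <- load_fissure_meshes(d)
  expect_true(back$na[2])
  expect_equal(back$meshes[[1]]$faces, m$faces)
})
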