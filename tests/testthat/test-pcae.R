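test_that("template plane has the closest-square layout", {
  tp <- make_template(2048)
  expect_equal(nrow(tp$vertices), 2025L)  # 45^2
  expect_equal(nrow(tp$faces), 3872L)     # 2 * 44^2
  expect_true(all(tp$vertices[, 3] == 0))
  expect_equal(range(tp$vertices[, 1]), c(-0.3, 0.3))
  expect_equal(range(tp$vertices[, 2]), c(-0.3, 0.3))
  # corner vertices present
  corners <- expand.grid(x = c(-0.3, 0.3), y = c(-0.3, 0.3))
  for (i in seq_len(4)) {
    expect_true(any(tp$vertices[, 1] == corners$x[i] &
                      tp$vertices[, 2] == corners$y[i]))
  }
  t9 <- make_template(9)
  expect_equal(nrow(t9$vertices), 9L)
  expect_equal(nrow(t9$faces), 8L)
})

test_that("farthest point sampling matches the greedy oracle", {
  # unit-square corners + centre: corners picked before the centre
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0.5, 0.5, 0))
  sel <- fps(pts, 4, start = 1)
  expect_setequal(sel, 1:4)
  expect_equal(sel[1], 1L)
  # N >= n: everything
  expect_equal(fps(pts, 10), 1:5)
  # brute-force equivalence on a random 30-point set
  set.seed(23)
  p30 <- matrix(rnorm(90), 30)
  expect_equal(fps(p30, 12), oracle_fps(p30, 12))
})

test_that("padding preserves originals and adds local offsets", {
  set.seed(4)
  p <- matrix(runif(21), 7, 3)
  expect_identical(pad_cloud(p, 7), p)
  out <- pad_cloud(p, 30, sigma_pad = 0.05, seed = 2)
  expect_equal(dim(out), c(30L, 3L))
  expect_equal(out[1:7, ], p)
  # each padded point lies near some original (within ~4 sigma)
  d <- sqrt(fissurept:::cpp_nn(out[8:30, , drop = FALSE], p)$d2)
  expect_true(all(d < 4 * 0.05))
  # single-point cloud
  one <- pad_cloud(p[1, , drop = FALSE], 16, sigma_pad = 0.05, seed = 3)
  d1 <- sqrt(rowSums(sweep(one, 2, p[1, ])^2))
  expect_gt(mean(d1 < 3 * 0.05 * sqrt(3)), 0.9)
  expect_error(pad_cloud(p, 3), "fps")
})

test_that("chamfer distance follows its convention and the n^2 oracle", {
  A <- matrix(runif(30), 10, 3)
  expect_equal(chamfer(A, A), 0)
  expect_equal(chamfer(matrix(c(0, 0, 0), 1), matrix(c(0.4, 0, 0), 1)),
               2 * 0.4^2)
  set.seed(31)
  B <- matrix(runif(150), 50, 3)
  C <- matrix(runif(150), 50, 3)
  expect_equal(chamfer(B, C), oracle_chamfer(B, C), tolerance = 1e-12)
  expect_equal(chamfer(B, C), chamfer(C, B))
  expect_error(chamfer(B[0, , drop = FALSE], C), "empty")
})

test_that("mesh regularizers have their closed forms and homogeneity", {
  tp <- make_template(9)  # 3x3 grid, spacing 0.3
  reg <- mesh_regularizers(tp)
  expect_equal(unname(reg["nc"]), 0)  # planar mesh
  # edge-length oracle by direct enumeration of unique edges
  eo <- fissurept:::mesh_edges(tp$faces)
  el_oracle <- mean(rowSums((tp$vertices[eo[, 1], ] -
                               tp$vertices[eo[, 2], ])^2))
  expect_equal(unname(reg["el"]), el_oracle)
  # scaling: EL and LS scale by s^2, NC unchanged
  bent <- tp
  set.seed(1)
  bent$vertices[, 3] <- runif(9, 0, 0.1)
  r1 <- mesh_regularizers(bent)
  bent2 <- bent
  bent2$vertices <- bent$vertices * 2
  r2 <- mesh_regularizers(bent2)
  expect_equal(unname(r2["el"] / r1["el"]), 4, tolerance = 1e-9)
  expect_equal(unname(r2["ls"] / r1["ls"]), 4, tolerance = 1e-9)
  expect_equal(unname(r2["nc"]), unname(r1["nc"]), tolerance = 1e-9)
  expect_true(all(r1 >= 0))
})

test_that("the encoder is permutation-invariant and the decoder residual", {
  cfg <- pcae_config(N = 64, h = 64)
  m <- build_pcae(cfg, seed = 6)
  set.seed(7)
  pts <- matrix(runif(64 * 3, -1, 1), 64)
  z <- pcae_encode(m, pts)
  expect_length(z, 64L)
  p <- sample(64)
  expect_equal(pcae_encode(m, pts[p, ]), z, tolerance = 1e-10)
  expect_error(pcae_encode(m, pts[1:10, ]), "exactly")
  # zero decoder weights: output equals the template exactly
  m0 <- m
  for (nm in grep("^f[12]\\.", names(m0$params), value = TRUE)) {
    m0$params[[nm]] <- m0$params[[nm]] * 0
  }
  dec <- pcae_decode(m0, z)
  expect_equal(dec$vertices, m0$template$vertices)
  expect_identical(dec$faces, m0$template$faces)
  # any latent code: connectivity preserved (correspondence across shapes)
  dec2 <- pcae_decode(m, rnorm(64))
  expect_identical(dec2$faces, m$template$faces)
  expect_equal(nrow(dec2$vertices), nrow(m$template$vertices))
})

test_that("the regularized mesh loss decomposes into its terms", {
  cfg <- pcae_config(N = 64, h = 64)
  m <- build_pcae(cfg, seed = 6)
  tp <- m$template
  target <- tp$vertices
  # all regularizer weights zero: chamfer term only
  cfg0 <- pcae_config(N = 64, h = 64, w_nc = 0, w_el = 0, w_ls = 0)
  expect_equal(pcae_loss(tp, target, cfg0), chamfer(tp$vertices, target))
  # template against its own vertices: CD = 0, planar NC = 0
  full <- pcae_loss(tp, target, cfg)
  reg <- mesh_regularizers(tp)
  expect_equal(full, unname(cfg$w_el * reg["el"] + cfg$w_ls * reg["ls"]))
  expect_gte(pcae_loss(tp, target + 0.3, cfg), 0)
  # the training-tape loss value agrees with the plain evaluation
  fp <- asNamespace("fissurept")
  attr(m$template, "edges") <- fp$mesh_edges(tp$faces)
  attr(m$template, "laplacian") <-
    fp$uniform_laplacian(nrow(tp$vertices), attr(m$template, "edges"))
  attr(m$template, "face_adj") <- fp$face_adjacency(tp$faces)
  tape <- fp$ad_tape()
  Vn <- fp$ad_node(tape, tp$vertices + 0.01)
  tl <- fp$pcae_loss_tape(tape, m, Vn, target, cfg)
  shifted <- new_mesh(tp$vertices + 0.01, tp$faces)
  expect_equal(as.numeric(tl$value), pcae_loss(shifted, target, cfg),
               tolerance = 1e-6)
})
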