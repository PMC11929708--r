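test_that("structure tensor vanishes on constant volumes and recovers a ramp", {
  v <- new_volume(array(0.5, rep(16, 3)))
  S <- structure_tensor(v)
  expect_lt(max(abs(S$xx)), 1e-12)
  expect_lt(max(abs(S$xy)), 1e-12)
  # pure ramp I = g * x: interior tensor ~ diag(g^2, 0, 0)
  g <- 0.03
  ramp <- array(rep(g * (0:23), 576), rep(24, 3))
  Sr <- structure_tensor(new_volume(ramp))
  inner <- 10:15  # outside the border-replication halo of both filters
  expect_equal(max(abs(Sr$xx[inner, inner, inner] - g^2)), 0,
               tolerance = 1e-10)
  expect_lt(max(abs(Sr$yy[inner, inner, inner])), 1e-12)
  expect_lt(max(abs(Sr$xy[inner, inner, inner])), 1e-12)
  expect_error(structure_tensor(new_volume(array(0, c(4, 4, 4)))),
               "filter support")
})

test_that("distinctiveness follows the closed-form 3x3 inverse trace", {
  mk <- function(a, b, c) {
    list(xx = array(a, c(2, 2, 2)), yy = array(b, c(2, 2, 2)),
         zz = array(c, c(2, 2, 2)),
         xy = array(0, c(2, 2, 2)), xz = array(0, c(2, 2, 2)),
         yz = array(0, c(2, 2, 2)))
  }
  expect_equal(foerstner_distinctiveness(mk(1, 1, 1), eps = 0)[1], 1 / 3)
  expect_equal(foerstner_distinctiveness(mk(2.5, 2.5, 2.5), eps = 0)[1],
               2.5 / 3)
  # rank-deficient tensor: D -> 0 as eps -> 0 (closed-form oracle)
  eps <- 1e-6
  d_reg <- foerstner_distinctiveness(mk(1, 1, 0), eps = eps)[1]
  oracle <- 1 / sum(1 / (c(1, 1, 0) + eps))
  expect_equal(d_reg, oracle, tolerance = 1e-12)
  expect_lt(d_reg, 2 * eps)
})

test_that("non-maximum suppression matches the exhaustive oracle", {
  set.seed(4)
  D <- array(runif(10^3), rep(10, 3))
  mask <- array(1L, rep(10, 3))
  got <- nms_select(D, mask, window = 5L)
  expect_equal(got, oracle_nms(D, mask, 5L))
  # single voxel-centred Gaussian bump -> exactly the peak voxel
  co <- seq_len(10) - 5
  bump <- exp(-(outer(outer(co^2, co^2, `+`), co^2, `+`)) / 8)
  sel <- nms_select(bump, mask, 5L)
  expect_equal(sel, rbind(c(4L, 4L, 4L)))
  # constant field: every masked voxel is a plateau candidate
  Dc <- array(1, rep(6, 3))
  mc <- array(0L, rep(6, 3)); mc[2:4, 2:4, 2:4] <- 1L
  expect_equal(nrow(nms_select(Dc, mc, 5L)), 27L)
  # two bumps separated by more than the window -> 2 maxima
  D2 <- array(0, rep(12, 3))
  D2[3, 3, 3] <- 1; D2[10, 10, 10] <- 1
  m2 <- array(1L, rep(12, 3))
  got2 <- nms_select(D2, m2, 5L)
  oracle2 <- oracle_nms(D2, m2, 5L)
  # the two peaks (0-based (2,2,2) and (9,9,9)) must both be selected
  row_in <- function(r, m) any(colSums(abs(t(m) - r)) == 0)
  expect_true(row_in(c(2, 2, 2), got2))
  expect_true(row_in(c(9, 9, 9), got2))
  expect_equal(got2, oracle2)
  expect_error(nms_select(D, array(0L, rep(10, 3))), "empty")
})

test_that("Foerstner keypoints honor the budget and stay inside the mask", {
  cs <- generate_case(seed = 9, size = 48)
  kp <- foerstner_keypoints(cs$volume, cs$lung_mask, K_max = 50L,
                            sigma_grad = 0.6, sigma_tensor = 0.5,
                            window = 3L)
  expect_lte(nrow(kp$coords), 50L)
  expect_gte(nrow(kp$coords), 1L)
  lin <- kp$voxel_indices[, 1] + 1 + 48 * kp$voxel_indices[, 2] +
    48^2 * kp$voxel_indices[, 3]
  expect_true(all(cs$lung_mask[lin] == 1))
  expect_true(all(kp$coords >= -1 & kp$coords <= 1))
  expect_equal(nrow(kp$features), nrow(kp$coords))
  expect_equal(ncol(kp$features), 125L)
  # top-K selection keeps the K largest distinctiveness values (sort oracle)
  kp_all <- foerstner_keypoints(cs$volume, cs$lung_mask, K_max = 100000L,
                                sigma_grad = 0.6, sigma_tensor = 0.5,
                                window = 3L)
  expect_equal(sort(kp$distinctiveness, decreasing = TRUE),
               sort(kp_all$distinctiveness, decreasing = TRUE)[1:50])
})

test_that("keypoints concentrate near the sheets when the budget binds", {
  cs <- generate_case(seed = 5, size = 64)
  kp <- foerstner_keypoints(cs$volume, cs$lung_mask, K_max = 150L,
                            sigma_grad = 0.5, sigma_tensor = 0.4,
                            window = 3L)
  d <- sapply(cs$gt_meshes, function(m) {
    fissurept:::cpp_point_tri_min_dist(kp$coords, m$vertices, m$faces)
  })
  near_rate <- mean(apply(d, 1, min) <= 2 * 2 / 63)
  # volume fraction of the within-2-voxel shell, estimated by counting
  vx <- which(cs$lung_mask > 0, arr.ind = TRUE) - 1L
  set.seed(1)
  vx <- vx[sample(nrow(vx), 3000), ]
  dv <- sapply(cs$gt_meshes, function(m) {
    fissurept:::cpp_point_tri_min_dist(voxel_to_norm(vx, rep(64L, 3)),
                                       m$vertices, m$faces)
  })
  vol_frac <- mean(apply(dv, 1, min) <= 2 * 2 / 63)
  expect_gt(near_rate, 2 * vol_frac)
})

test_that("false-negative-rate weights count misses per class", {
  truth <- c(0, 0, 1, 1, 1, 2, 2, 2, 2, 3)
  # all predictions background: every foreground voxel missed
  w <- fnr_weights(rep(0, 10), truth)
  expect_equal(w, c(0, 1, 1, 1))
  # perfect prediction
  expect_equal(fnr_weights(truth, truth), rep(0, 4))
  # half of class 2 missed
  pred <- truth
  pred[c(6, 7)] <- 0
  expect_equal(fnr_weights(pred, truth)[3], 0.5)
  # absent class gets weight 0; weights within [0,1]; order invariant
  expect_equal(fnr_weights(rep(0, 4), c(0, 0, 1, 1))[4], 0)
  p <- sample(10)
  expect_equal(fnr_weights(pred[p], truth[p]), fnr_weights(pred, truth))
})

test_that("recall-weighted cross-entropy rewards recovering missed classes", {
  truth <- c(0L, 0L, 1L, 1L)
  perfect <- diag(4)[truth + 1, ] * 20
  expect_lt(fnr_weighted_ce(perfect, truth), 1e-6)
  # weights are recomputed per batch: different error patterns give
  # different per-class weights
  l1 <- rbind(c(5, 0, 0, 0), c(5, 0, 0, 0), c(5, 0, 0, 0), c(0, 5, 0, 0))
  l2 <- rbind(c(5, 0, 0, 0), c(0, 5, 0, 0), c(0, 5, 0, 0), c(0, 5, 0, 0))
  w1 <- fnr_weights(max.col(l1) - 1L, truth)
  w2 <- fnr_weights(max.col(l2) - 1L, truth)
  expect_false(isTRUE(all.equal(w1, w2)))
  # gradient magnitude: with FNR_fg (1/2) > FNR_bg (1/3) a missed
  # foreground voxel pulls harder than an equally confident missed
  # background voxel
  base <- rbind(c(2, 0, 0, 0),      # bg correct
                c(2, 0, 0, 0),      # bg correct
                c(0, 2, 0, 0),      # bg wrong (missed background)
                c(2, 0, 0, 0),      # fg missed
                c(0, 2, 0, 0))      # fg correct
  truth2 <- c(0L, 0L, 0L, 1L, 1L)
  h <- 1e-5
  grad_at <- function(row, col) {
    lp <- base; lp[row, col] <- lp[row, col] + h
    lm <- base; lm[row, col] <- lm[row, col] - h
    (fnr_weighted_ce(lp, truth2) - fnr_weighted_ce(lm, truth2)) / (2 * h)
  }
  expect_gt(abs(grad_at(4, 2)), abs(grad_at(3, 1)))
})
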