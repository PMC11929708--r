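test_that("surface sampling is area-weighted, barycentric and seeded", {
  tri <- new_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                  rbind(c(1, 2, 3)))
  s <- sample_surface(tri, 500, seed = 2)
  expect_true(all(s[, 1] >= -1e-12 & s[, 2] >= -1e-12))
  expect_true(all(s[, 1] + s[, 2] <= 1 + 1e-12))
  expect_true(all(s[, 3] == 0))
  expect_identical(sample_surface(tri, 50, seed = 9),
                   sample_surface(tri, 50, seed = 9))
  # two faces with 3:1 area ratio draw ~3:1 samples
  two <- new_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0),
                        c(10, 0, 0), c(11, 0, 0), c(10, 2, 0)),
                  rbind(c(1, 2, 3), c(4, 5, 6)))
  s2 <- sample_surface(two, 4000, seed = 3)
  frac_big <- mean(s2[, 1] < 5)
  expect_gt(frac_big, 0.70)
  expect_lt(frac_big, 0.80)
  expect_error(sample_surface(new_mesh(matrix(0, 0, 3),
                                       matrix(integer(0), 0, 3)), 5),
               "empty")
})

test_that("exact point-to-triangle distance matches dense sampling", {
  set.seed(12)
  a <- c(0, 0, 0); b <- c(1, 0.2, 0); c3 <- c(0.3, 1, 0.5)
  V <- rbind(a, b, c3)
  F <- rbind(c(1L, 2L, 3L))
  for (i in 1:8) {
    p <- rnorm(3)
    got <- fissurept:::cpp_point_tri_min_dist(rbind(p), V, F)
    expect_equal(got, oracle_point_tri_dist(p, a, b, c3, m = 300),
                 tolerance = 2e-3)
  }
})

test_that("the parallel-square fixture gives ASSD = SDSD-free = HD = d", {
  d <- 0.37
  r <- surface_distances(square_mesh(0), square_mesh(d), n = 3000, seed = 1)
  expect_equal(r$assd, d, tolerance = 1e-9)
  expect_lt(r$sdsd, 1e-9)
  expect_equal(r$hd, d, tolerance = 1e-9)
  # doubling the sampling count leaves the constant distance unchanged
  r2 <- surface_distances(square_mesh(0), square_mesh(d), n = 6000, seed = 1)
  expect_lt(abs(r2$assd - r$assd), 1e-9)
})

test_that("surface distances are symmetric, ordered and homogeneous", {
  set.seed(14)
  mA <- make_template(16)
  mB <- make_template(16)
  mB$vertices <- mB$vertices + matrix(rnorm(3 * nrow(mB$vertices), 0, 0.02),
                                      ncol = 3)
  rAB <- surface_distances(mA, mB, n = 2000, seed = 5)
  rBA <- surface_distances(mB, mA, n = 2000, seed = 5)
  expect_equal(rAB$assd, rBA$assd)
  expect_equal(rAB$hd, rBA$hd)
  expect_lte(rAB$assd, rAB$hd)
  expect_gte(rAB$sdsd, 0)
  # identical meshes: zero everywhere
  r0 <- surface_distances(mA, mA, n = 500, seed = 2)
  expect_equal(c(r0$assd, r0$sdsd, r0$hd), c(0, 0, 0))
  # scaling both meshes scales every metric: exactly for the distance
  # kernel on matched points, statistically through the resampling
  pts <- sample_surface(mA, 500, seed = 7)
  d1 <- fissurept:::cpp_point_tri_min_dist(pts, mB$vertices, mB$faces)
  d3 <- fissurept:::cpp_point_tri_min_dist(3 * pts, 3 * mB$vertices,
                                           mB$faces)
  expect_equal(d3, 3 * d1, tolerance = 1e-12)
  sA <- mA; sA$vertices <- sA$vertices * 3
  sB <- mB; sB$vertices <- sB$vertices * 3
  rs <- surface_distances(sA, sB, n = 2000, seed = 5)
  expect_equal(rs$assd, 3 * rAB$assd, tolerance = 0.05)
  # empty mesh: n.a.
  expect_true(surface_distances(NULL, mA)$na)
})

test_that("case evaluation excludes n.a. fissures from aggregates", {
  gt <- list(square_mesh(0), square_mesh(0), square_mesh(0))
  pred <- list(meshes = list(square_mesh(0.2), square_mesh(0.6), NULL),
               na = c(FALSE, FALSE, TRUE))
  ev <- evaluate_case(pred, gt, n = 2000, seed = 3)
  expect_equal(ev$n_na, 1L)
  expect_true(ev$reports[[3]]$na)
  expect_equal(ev$summary$assd, (0.2 + 0.6) / 2, tolerance = 1e-6)
  # all predicted: no n.a.
  pred2 <- list(meshes = gt, na = rep(FALSE, 3))
  expect_equal(evaluate_case(pred2, gt, n = 200)$n_na, 0L)
  # CSV export carries one row per fissure
  f <- tempfile(fileext = ".csv")
  rows <- write_metrics_csv(list(case1 = ev), f)
  expect_equal(nrow(rows), 3L)
  expect_true(file.exists(f))
})
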