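# Independent brute-force oracles used to cross-check the implementation.

# O(n^2) k-nearest-neighbour oracle (ties toward lower index).
oracle_knn <- function(coords, k) {
  n <- nrow(coords)
  k <- min(k, n - 1)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt(rowSums(sweep(coords, 2, coords[i, ])^2))
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  }, integer(k)))
}

# Greedy farthest-point-sampling oracle.
oracle_fps <- function(points, N, start = 1L) {
  n <- nrow(points)
  if (N >= n) return(seq_len(n))
  sel <- start
  while (length(sel) < N) {
    dmin <- apply(points, 1, function(p) {
      min(sqrt(colSums((t(points[sel, , drop = FALSE]) - p)^2)))
    })
    dmin[sel] <- -Inf
    sel <- c(sel, which.max(dmin))
  }
  sel
}

# O(n^2) chamfer oracle (squared distances, mean per direction, summed).
oracle_chamfer <- function(A, B) {
  d2 <- function(X, Y) {
    apply(X, 1, function(p) min(colSums((t(Y) - p)^2)))
  }
  mean(d2(A, B)) + mean(d2(B, A))
}

# Exhaustive non-maximum-suppression oracle on a small grid.
oracle_nms <- function(D, mask, window) {
  r <- (window - 1) %/% 2
  d <- dim(D)
  out <- NULL
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (mask[x, y, z] == 0) next
    xs <- max(1, x - r):min(d[1], x + r)
    ys <- max(1, y - r):min(d[2], y + r)
    zs <- max(1, z - r):min(d[3], z + r)
    if (D[x, y, z] >= max(D[xs, ys, zs])) out <- rbind(out, c(x, y, z) - 1L)
  }
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

# Union-find largest-component-of-faces oracle.
oracle_largest_component <- function(faces) {
  nf <- nrow(faces)
  uf <- new.env(parent = emptyenv())
  uf$parent <- seq_len(nf)
  find <- function(i) {
    while (uf$parent[i] != i) i <- uf$parent[i]
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) uf$parent[rb] <- ra
  }
  edge_faces <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    for (e in list(faces[f, c(1, 2)], faces[f, c(2, 3)], faces[f, c(3, 1)])) {
      k <- paste(min(e), max(e))
      prev <- edge_faces[[k]]
      if (!is.null(prev)) union(prev, f)
      edge_faces[[k]] <- f
    }
  }
  roots <- vapply(seq_len(nf), find, integer(1))
  max(table(roots))
}

# Point-to-triangle distance oracle by dense barycentric sampling.
oracle_point_tri_dist <- function(p, a, b, c, m = 200) {
  s <- seq(0, 1, length.out = m)
  best <- Inf
  for (u in s) {
    vmax <- 1 - u
    vs <- seq(0, vmax, length.out = max(2, ceiling(m * vmax)))
    q <- outer(rep(1, length(vs)), a) +
      u * outer(rep(1, length(vs)), b - a) +
      vs * matrix(rep(c - a, each = length(vs)), ncol = 3)
    best <- min(best, sqrt(min(rowSums(sweep(q, 2, p)^2))))
  }
  best
}

# Small helpers shared across tests.
square_mesh <- function(z = 0, shift = c(0, 0)) {
  new_mesh(rbind(c(0 + shift[1], 0 + shift[2], z),
                 c(1 + shift[1], 0 + shift[2], z),
                 c(1 + shift[1], 1 + shift[2], z),
                 c(0 + shift[1], 1 + shift[2], z)),
           rbind(c(1, 2, 3), c(1, 3, 4)))
}

sphere_points <- function(n, r = 0.5, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n * 3), n)
  r * v / sqrt(rowSums(v^2))
}
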