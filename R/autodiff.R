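# Minimal tape-based reverse-mode automatic differentiation on dense
# matrices. Each forward op appends a node (value + backward closure) to a
# tape; ad_backward() walks the tape in reverse. This is the engine under
# every trainable model in the package; only the matrix primitives the point
# networks need are implemented.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  tape$n <- tape$n + 1L
  n$id <- tape$n
  tape$nodes[[tape$n]] <- n
  n
}

is_ad <- function(x) is.environment(x) && !is.null(x$value)

ad_val <- function(x) if (is_ad(x)) x$value else x

# Accumulate gradient g into node x (no-op for constants).
ad_acc <- function(x, g) {
  if (!is_ad(x)) return(invisible(NULL))
  if (is.null(x$grad)) x$grad <- g else x$grad <- x$grad + g
  invisible(NULL)
}

#' Run reverse-mode backpropagation from a scalar loss node
#'
#' @param tape the tape the graph was recorded on.
#' @param loss terminal node holding a 1x1 value.
#' @keywords internal
ad_backward <- function(tape, loss) {
  stopifnot(is_ad(loss), length(loss$value) == 1L)
  loss$grad <- matrix(1, 1, 1)
  for (i in seq(tape$n, 1L)) {
    n <- tape$nodes[[i]]
    if (!is.null(n$backfn) && !is.null(n$grad)) n$backfn(n$grad)
  }
  invisible(NULL)
}

ad_matmul <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_node(tape, av %*% bv, list(a, b), function(g) {
    ad_acc(a, g %*% t(bv))
    ad_acc(b, crossprod(av, g))
  })
}

# Elementwise addition; b may be a 1 x C row (bias broadcast) or a scalar.
ad_add <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  bcast_row <- is.matrix(bv) && nrow(bv) == 1L && nrow(av) > 1L
  val <- if (bcast_row) sweep(av, 2, as.numeric(bv), `+`) else av + bv
  ad_node(tape, val, list(a, b), function(g) {
    ad_acc(a, g)
    if (bcast_row) ad_acc(b, matrix(colSums(g), 1L)) else ad_acc(b, g)
  })
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, ad_val(a) - ad_val(b), list(a, b), function(g) {
    ad_acc(a, g)
    ad_acc(b, -g)
  })
}

ad_mul <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_node(tape, av * bv, list(a, b), function(g) {
    ad_acc(a, g * bv)
    ad_acc(b, g * av)
  })
}

ad_div <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_node(tape, av / bv, list(a, b), function(g) {
    ad_acc(a, g / bv)
    ad_acc(b, -g * av / (bv * bv))
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, ad_val(a) * s, list(a), function(g) ad_acc(a, g * s))
}

ad_relu <- function(tape, a) {
  av <- ad_val(a)
  m <- av > 0
  ad_node(tape, av * m, list(a), function(g) ad_acc(a, g * m))
}

ad_square <- function(tape, a) {
  av <- ad_val(a)
  ad_node(tape, av * av, list(a), function(g) ad_acc(a, 2 * g * av))
}

ad_sqrt <- function(tape, a, eps = 0) {
  av <- ad_val(a)
  s <- sqrt(av + eps)
  ad_node(tape, s, list(a), function(g) ad_acc(a, g / (2 * s)))
}

ad_gather <- function(tape, a, idx) {
  av <- ad_val(a)
  ad_node(tape, av[idx, , drop = FALSE], list(a), function(g) {
    acc <- matrix(0, nrow(av), ncol(av))
    s <- rowsum(g, group = idx, reorder = FALSE)
    acc[as.integer(rownames(s)), ] <- s
    ad_acc(a, acc)
  })
}

ad_cbind <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ca <- ncol(av)
  ad_node(tape, cbind(av, bv), list(a, b), function(g) {
    ad_acc(a, g[, seq_len(ca), drop = FALSE])
    ad_acc(b, g[, -seq_len(ca), drop = FALSE])
  })
}

ad_slice_rows <- function(tape, a, rows) {
  av <- ad_val(a)
  ad_node(tape, av[rows, , drop = FALSE], list(a), function(g) {
    acc <- matrix(0, nrow(av), ncol(av))
    acc[rows, ] <- g
    ad_acc(a, acc)
  })
}

ad_slice_cols <- function(tape, a, cols) {
  av <- ad_val(a)
  ad_node(tape, av[, cols, drop = FALSE], list(a), function(g) {
    acc <- matrix(0, nrow(av), ncol(av))
    acc[, cols] <- g
    ad_acc(a, acc)
  })
}

ad_rowsum <- function(tape, a) {
  av <- ad_val(a)
  ad_node(tape, matrix(rowSums(av), ncol = 1L), list(a), function(g) {
    ad_acc(a, matrix(g, nrow(av), ncol(av)))
  })
}

ad_sum <- function(tape, a) {
  av <- ad_val(a)
  ad_node(tape, matrix(sum(av), 1, 1), list(a), function(g) {
    ad_acc(a, matrix(as.numeric(g), nrow(av), ncol(av)))
  })
}

ad_mean <- function(tape, a) {
  av <- ad_val(a)
  n <- length(av)
  ad_node(tape, matrix(mean(av), 1, 1), list(a), function(g) {
    ad_acc(a, matrix(as.numeric(g) / n, nrow(av), ncol(av)))
  })
}

# Max over consecutive row-blocks of size g: (B*g) x C -> B x C.
ad_group_max <- function(tape, a, g) {
  av <- ad_val(a)
  n <- nrow(av); C <- ncol(av)
  stopifnot(n %% g == 0L)
  B <- n %/% g
  gm <- cpp_group_max(av, as.integer(g))
  ad_node(tape, gm$val, list(a), function(gr) {
    acc <- matrix(0, n, C)
    rows <- (rep(seq_len(B), times = C) - 1L) * g + as.vector(gm$arg)
    acc[cbind(rows, rep(seq_len(C), each = B))] <- as.numeric(gr)
    ad_acc(a, acc)
  })
}

# Sum over consecutive row-blocks of size g.
ad_group_sum <- function(tape, a, g) {
  av <- ad_val(a)
  n <- nrow(av); C <- ncol(av)
  stopifnot(n %% g == 0L)
  B <- n %/% g
  val <- matrix(.colSums(matrix(av, nrow = g), g, B * C), B, C)
  ad_node(tape, val, list(a), function(gr) {
    ad_acc(a, gr[rep(seq_len(B), each = g), , drop = FALSE])
  })
}

# Column-wise softmax over consecutive row-blocks of size g (used by vector
# attention: per-neighborhood, per-channel weights).
ad_group_softmax <- function(tape, a, g) {
  av <- ad_val(a)
  n <- nrow(av); C <- ncol(av)
  stopifnot(n %% g == 0L)
  B <- n %/% g
  m <- matrix(av, nrow = g)
  mx <- m[1L, ]
  if (g > 1L) for (j in 2:g) mx <- pmax(mx, m[j, ])
  e <- exp(sweep(m, 2, mx, `-`))
  s <- .colSums(e, g, B * C)
  y <- sweep(e, 2, s, `/`)
  val <- matrix(y, n, C)
  ad_node(tape, val, list(a), function(gr) {
    gm <- matrix(gr, nrow = g)
    dot <- .colSums(gm * y, g, B * C)
    dx <- y * sweep(gm, 2, dot, `-`)
    ad_acc(a, matrix(dx, n, C))
  })
}

# Global max over rows: n x C -> 1 x C.
ad_colmax <- function(tape, a) {
  av <- ad_val(a)
  cm <- cpp_col_max(av)
  j <- cm$arg
  val <- matrix(cm$val, 1L)
  ad_node(tape, val, list(a), function(g) {
    acc <- matrix(0, nrow(av), ncol(av))
    acc[cbind(j, seq_len(ncol(av)))] <- as.numeric(g)
    ad_acc(a, acc)
  })
}

ad_tile_rows <- function(tape, a, n) {
  av <- ad_val(a)
  stopifnot(nrow(av) == 1L)
  ad_node(tape, av[rep(1L, n), , drop = FALSE], list(a), function(g) {
    ad_acc(a, matrix(colSums(g), 1L))
  })
}

# Row-wise log-softmax.
ad_log_softmax <- function(tape, a) {
  av <- ad_val(a)
  mx <- av[cbind(seq_len(nrow(av)), max.col(av, ties.method = "first"))]
  sh <- av - mx
  lse <- log(rowSums(exp(sh)))
  val <- sh - lse
  p <- exp(val)
  ad_node(tape, val, list(a), function(g) {
    ad_acc(a, g - p * rowSums(g))
  })
}

ad_exp <- function(tape, a) {
  v <- exp(ad_val(a))
  ad_node(tape, v, list(a), function(g) ad_acc(a, g * v))
}

# Row-wise softmax.
ad_softmax <- function(tape, a) {
  ls <- ad_log_softmax(tape, a)
  av <- ad_val(ls)
  p <- exp(av)
  ad_node(tape, p, list(ls), function(g) ad_acc(ls, g * p))
}
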