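# Shared neural-network plumbing: parameter initialization, linear / MLP
# layers on the autodiff tape, the Adam optimizer, and the cosine learning
# rate schedule used by all trainable models.

nn_init_linear <- function(params, name, c_in, c_out) {
  params[[paste0(name, ".W")]] <-
    matrix(rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out)
  params[[paste0(name, ".b")]] <- matrix(0, 1, c_out)
  params
}

nn_param_nodes <- function(tape, params) {
  lapply(params, function(p) ad_node(tape, p))
}

nn_linear <- function(tape, pn, name, x) {
  ad_add(tape, ad_matmul(tape, x, pn[[paste0(name, ".W")]]),
         pn[[paste0(name, ".b")]])
}

# MLP: linear + ReLU on every layer except (optionally) the last.
nn_mlp <- function(tape, pn, prefix, x, n_layers, act_last = FALSE) {
  for (i in seq_len(n_layers)) {
    x <- nn_linear(tape, pn, paste0(prefix, i), x)
    if (i < n_layers || act_last) x <- ad_relu(tape, x)
  }
  x
}

nn_init_mlp <- function(params, prefix, dims) {
  for (i in seq_len(length(dims) - 1L)) {
    params <- nn_init_linear(params, paste0(prefix, i), dims[i], dims[i + 1])
  }
  params
}

nn_grads <- function(pnodes, params) {
  g <- vector("list", length(params))
  names(g) <- names(params)
  for (nm in names(params)) {
    gg <- pnodes[[nm]]$grad
    g[[nm]] <- if (is.null(gg)) params[[nm]] * 0 else gg
  }
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Cosine annealing learning rate
#'
#' Decays from `eta` at epoch 0 to `floor * eta` at epoch `n_epochs - 1`
#' along a half cosine.
#'
#' @param epoch 0-based epoch index.
#' @param n_epochs total number of epochs.
#' @param eta initial learning rate.
#' @param floor final learning rate as a fraction of `eta` (default 0.05).
#' @return the learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, n_epochs, eta = 1e-3, floor = 0.05) {
  stopifnot(floor > 0, floor <= 1)
  if (n_epochs <= 1L) return(eta)
  eta_min <- floor * eta
  eta_min + (eta - eta_min) / 2 * (1 + cos(pi * epoch / (n_epochs - 1)))
}

#' Count trainable parameters of a model
#'
#' @param model any model object of this package (point segmentation
#'   networks, the point-cloud autoencoder, the pre-segmentation CNN).
#' @return total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}
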