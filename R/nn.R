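# Minimal dense-network substrate: parameter initialization, SiLU, softmax,
# an Adam optimizer, and a generic multilayer perceptron with hand-derived
# gradients. The diffusion denoiser (denoiser.R) and the classifier
# (classifier.R) are built on these primitives; everything runs on base-R
# matrix algebra (BLAS).

silu <- function(z) z * stats::plogis(z)

silu_grad <- function(z) {
  s <- stats::plogis(z)
  s * (1 + z * (1 - s))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# He-style initialization, deterministic under the caller's RNG state.
init_mat <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  matrix(rnorm(n_in * n_out, 0, scale), n_in, n_out)
}

# Adam state for a named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Sinusoidal timestep embedding: t (integer vector) -> n x dim matrix.
sinusoidal_embedding <- function(t, dim) {
  half <- dim %/% 2
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / max(half - 1, 1))
  ang <- outer(as.numeric(t), freqs)
  cbind(sin(ang), cos(ang))
}

# ---- generic MLP (classifier / autoencoder substrate) -----------------------

mlp_init <- function(dims) {
  params <- list()
  for (i in seq_len(length(dims) - 1)) {
    params[[paste0("W", i)]] <- init_mat(dims[i], dims[i + 1])
    params[[paste0("b", i)]] <- numeric(dims[i + 1])
  }
  structure(list(params = params, dims = dims), class = "vf_mlp")
}

# Forward pass; hidden layers use SiLU, the output layer is linear.
mlp_forward <- function(net, X, keep_cache = FALSE) {
  L <- length(net$dims) - 1
  cache <- list(h = list(X), z = list())
  h <- X
  for (i in seq_len(L)) {
    z <- sweep(h %*% net$params[[paste0("W", i)]], 2,
               net$params[[paste0("b", i)]], "+")
    h <- if (i < L) silu(z) else z
    if (keep_cache) {
      cache$z[[i]] <- z
      cache$h[[i + 1]] <- h
    }
  }
  if (keep_cache) list(out = h, cache = cache) else h
}

# Backward pass given d(loss)/d(output); returns gradients for all params.
mlp_backward <- function(net, cache, d_out) {
  L <- length(net$dims) - 1
  grads <- list()
  d <- d_out
  for (i in rev(seq_len(L))) {
    if (i < L) d <- d * silu_grad(cache$z[[i]])
    grads[[paste0("W", i)]] <- crossprod(cache$h[[i]], d)
    grads[[paste0("b", i)]] <- colSums(d)
    if (i > 1) d <- tcrossprod(d, net$params[[paste0("W", i)]])
  }
  grads
}
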