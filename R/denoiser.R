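# Noise-prediction denoiser: a dense encoder-decoder with sinusoidal
# timestep conditioning injected into every block, residual blocks, and an
# encoder->decoder skip concatenation. Layout (widths w1 > w2):
#
#   h0 = silu(X W0 + b0 + E T0)            encoder, width w1
#   r1 = h0 + silu(h0 W1 + b1 + E T1)      residual block
#   d1 = silu(r1 W2 + b2)                  down-projection, width w2
#   r2 = d1 + silu(d1 W3 + b3 + E T3)      bottleneck residual block
#   u1 = silu([r2, r1] W4 + b4)            up-projection with skip, width w1
#   r3 = u1 + silu(u1 W5 + b5 + E T5)      residual block
#   out = r3 W6 + b6 + (E Ts) * X + E Tb   noise estimate, same shape as X
#
# E is the sinusoidal embedding of the integer timestep. The (E Ts) * X term
# is a time-gated identity shortcut at full input resolution: the optimal
# noise prediction approaches x_t / sqrt(1 - alpha_bar_t) as t grows, a map a
# low-width bottleneck cannot represent, so the isotropic component is
# carried by this gate (the convolutional U-Net it stands in for represents
# near-identity maps natively) while the encoder-decoder corrects the
# low-dimensional image-manifold component. E Tb is a time-modulated bias.
# Gradients are hand-derived; training uses Adam on the mean-squared
# noise-prediction loss.

denoiser_init <- function(d, widths = c(64, 32), temb_dim = 16) {
  w1 <- widths[1]; w2 <- widths[2]
  params <- list(
    W0 = init_mat(d, w1),  b0 = numeric(w1), T0 = init_mat(temb_dim, w1, 0.1),
    W1 = init_mat(w1, w1), b1 = numeric(w1), T1 = init_mat(temb_dim, w1, 0.1),
    W2 = init_mat(w1, w2), b2 = numeric(w2),
    W3 = init_mat(w2, w2), b3 = numeric(w2), T3 = init_mat(temb_dim, w2, 0.1),
    W4 = init_mat(w1 + w2, w1), b4 = numeric(w1),
    W5 = init_mat(w1, w1), b5 = numeric(w1), T5 = init_mat(temb_dim, w1, 0.1),
    W6 = init_mat(w1, d, scale = 1e-3), b6 = numeric(d),
    Ts = matrix(0, temb_dim, 1), Tb = matrix(0, temb_dim, d))
  structure(list(params = params, d = d, widths = widths,
                 temb_dim = temb_dim,
                 descriptor = sprintf("dense-unet(%d-%d-%d, temb=%d)",
                                      d, w1, w2, temb_dim)),
            class = "vf_denoiser")
}

denoiser_forward <- function(model, X, t, keep_cache = FALSE) {
  p <- model$params
  E <- sinusoidal_embedding(t, model$temb_dim)
  if (nrow(E) == 1 && nrow(X) > 1) E <- E[rep(1, nrow(X)), , drop = FALSE]
  add_b <- function(z, b) sweep(z, 2, b, "+")
  z0 <- add_b(X %*% p$W0, p$b0) + E %*% p$T0;  h0 <- silu(z0)
  z1 <- add_b(h0 %*% p$W1, p$b1) + E %*% p$T1; r1 <- h0 + silu(z1)
  z2 <- add_b(r1 %*% p$W2, p$b2);              d1 <- silu(z2)
  z3 <- add_b(d1 %*% p$W3, p$b3) + E %*% p$T3; r2 <- d1 + silu(z3)
  skip <- cbind(r2, r1)
  z4 <- add_b(skip %*% p$W4, p$b4);            u1 <- silu(z4)
  z5 <- add_b(u1 %*% p$W5, p$b5) + E %*% p$T5; r3 <- u1 + silu(z5)
  gate <- (E %*% p$Ts)[, 1]
  out <- add_b(r3 %*% p$W6, p$b6) + gate * X + E %*% p$Tb
  if (!keep_cache) return(out)
  list(out = out,
       cache = list(X = X, E = E, z0 = z0, h0 = h0, z1 = z1, r1 = r1,
                    z2 = z2, d1 = d1, z3 = z3, r2 = r2, skip = skip,
                    z4 = z4, u1 = u1, z5 = z5, r3 = r3))
}

denoiser_backward <- function(model, cache, d_out) {
  p <- model$params; cc <- cache
  w1 <- model$widths[1]; w2 <- model$widths[2]
  g <- list()
  g$W6 <- crossprod(cc$r3, d_out); g$b6 <- colSums(d_out)
  g$Ts <- crossprod(cc$E, matrix(rowSums(d_out * cc$X), ncol = 1))
  g$Tb <- crossprod(cc$E, d_out)
  dr3 <- tcrossprod(d_out, p$W6)
  ds5 <- dr3 * silu_grad(cc$z5)
  g$W5 <- crossprod(cc$u1, ds5); g$b5 <- colSums(ds5)
  g$T5 <- crossprod(cc$E, ds5)
  du1 <- dr3 + tcrossprod(ds5, p$W5)
  ds4 <- du1 * silu_grad(cc$z4)
  g$W4 <- crossprod(cc$skip, ds4); g$b4 <- colSums(ds4)
  dskip <- tcrossprod(ds4, p$W4)
  dr2 <- dskip[, seq_len(w2), drop = FALSE]
  dr1 <- dskip[, w2 + seq_len(w1), drop = FALSE]
  ds3 <- dr2 * silu_grad(cc$z3)
  g$W3 <- crossprod(cc$d1, ds3); g$b3 <- colSums(ds3)
  g$T3 <- crossprod(cc$E, ds3)
  dd1 <- dr2 + tcrossprod(ds3, p$W3)
  ds2 <- dd1 * silu_grad(cc$z2)
  g$W2 <- crossprod(cc$r1, ds2); g$b2 <- colSums(ds2)
  dr1 <- dr1 + tcrossprod(ds2, p$W2)
  ds1 <- dr1 * silu_grad(cc$z1)
  g$W1 <- crossprod(cc$h0, ds1); g$b1 <- colSums(ds1)
  g$T1 <- crossprod(cc$E, ds1)
  dh0 <- dr1 + tcrossprod(ds1, p$W1)
  ds0 <- dh0 * silu_grad(cc$z0)
  g$W0 <- crossprod(cc$X, ds0); g$b0 <- colSums(ds0)
  g$T0 <- crossprod(cc$E, ds0)
  g
}

#' Predicted noise for a batch of corrupted samples
#'
#' Evaluates the denoiser \eqn{\epsilon_\theta(x_t, t)}: the model's estimate
#' of the standard-normal noise that produced `xt` from the clean sample.
#' Output has the shape of the input for every valid timestep.
#'
#' A model with a `predict` function field (the denoiser contract: `(xt, t)
#' -> matrix of the same shape`) is dispatched to that function, so analytic
#' or oracle denoisers can stand in for a trained network.
#'
#' @param model A denoiser returned by [train_ddpm()] (class `vf_denoiser`),
#'   or any list with a `predict(xt, t)` function honoring the contract.
#' @param xt Numeric matrix `n x d` of corrupted samples (model scale
#'   `[-1, 1]`), or a vector of length `d`.
#' @param t Integer timestep(s) in `[1, T]`; scalar or length `n`.
#' @return `n x d` matrix of predicted noise.
#' @export
predict_noise <- function(model, xt, t) {
  if (is.null(dim(xt))) xt <- matrix(xt, nrow = 1)
  if (!is.null(model$predict)) return(model$predict(xt, t))
  stopifnot(ncol(xt) == model$d)
  denoiser_forward(model, xt, t)
}
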