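#' Forward diffusion: corrupt a clean sample at timestep t
#'
#' Closed-form forward process
#' \deqn{x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon,}
#' which takes the data distribution to (approximately) a standard normal by
#' `t = T`.
#'
#' @param x0 Clean sample(s), any numeric array/matrix scaled to `[-1, 1]`.
#' @param t Integer timestep in `[0, T]`.
#' @param noise Standard-normal array of the same shape as `x0`.
#' @param schedule A [build_schedule()] object.
#' @return Corrupted sample of the same shape.
#' @export
forward_diffuse <- function(x0, t, noise, schedule) {
  if (!identical(dim(x0) %||% length(x0), dim(noise) %||% length(noise)))
    stop("x0 and noise must have identical shapes")
  if (t < 0 || t > schedule$T) stop("t must lie in [0, T]")
  ab <- ab_at(schedule, t)
  sqrt(ab) * x0 + sqrt(1 - ab) * noise
}

#' Invert the forward process given the realized noise
#'
#' Algebraic inverse of the closed-form corruption:
#' \eqn{x_0 = (x_t - \sqrt{1-\bar\alpha_t}\,\epsilon)/\sqrt{\bar\alpha_t}}.
#' Used to verify round-trip identities and single reverse steps.
#'
#' @param xt Corrupted sample(s).
#' @param noise The noise array used in the forward step.
#' @param t Integer timestep; requires \eqn{\bar\alpha_t > 0}.
#' @param schedule A [build_schedule()] object.
#' @return The reconstructed clean sample.
#' @export
invert_forward <- function(xt, noise, t, schedule) {
  ab <- ab_at(schedule, t)
  if (ab <= 0) stop("degenerate timestep: alpha_bar[t] = 0")
  (xt - sqrt(1 - ab) * noise) / sqrt(ab)
}

#' Noise-prediction training loss
#'
#' The reconstruction objective
#' \eqn{L = \|\epsilon - \epsilon_\theta(x_t, t)\|^2} averaged over elements
#' and batch: zero when the model predicts the realized noise exactly, and
#' approximately 1 for a zero predictor on unit-normal noise.
#'
#' @param model A `vf_denoiser`.
#' @param x0 Clean batch, `n x d` matrix in `[-1, 1]`.
#' @param t Integer timestep(s) in `[1, T]`, scalar or length `n`.
#' @param noise `n x d` standard-normal matrix.
#' @param schedule A [build_schedule()] object.
#' @return Nonnegative scalar loss.
#' @export
diffusion_loss <- function(model, x0, t, noise, schedule) {
  if (is.null(dim(x0))) { x0 <- matrix(x0, 1); noise <- matrix(noise, 1) }
  if (!all(dim(x0) == dim(noise))) stop("x0 and noise must have identical shapes")
  if (any(t < 1 | t > schedule$T)) stop("t must lie in [1, T]")
  ab <- ab_at(schedule, t)
  xt <- sqrt(ab) * x0 + sqrt(1 - ab) * noise
  eps_hat <- predict_noise(model, xt, t)
  mean((noise - eps_hat)^2)
}

#' One ancestral sampling step of the reverse process
#'
#' Draws \eqn{x_{t-1} \sim N(\mu_\theta(x_t, t), \sigma_t^2 I)} with the
#' noise-prediction parameterization
#' \deqn{\mu_\theta = \frac{1}{\sqrt{\alpha_t}}\left(x_t -
#'       \frac{\beta_t}{\sqrt{1-\bar\alpha_t}}\,\epsilon_\theta(x_t,t)\right),}
#' \eqn{\sigma_t = \sqrt{\beta_t}}, and a deterministic final step
#' (\eqn{\sigma_1 = 0}). Draws from the current RNG stream unless `noise` is
#' supplied.
#'
#' With `clip_denoised = TRUE` the implied clean sample
#' \eqn{\hat x_0 = (x_t - \sqrt{1-\bar\alpha_t}\,\epsilon_\theta)/
#' \sqrt{\bar\alpha_t}} is clamped to the data range `[-1, 1]` and the mean
#' is taken as the forward-posterior mean of the clamped \eqn{\hat x_0};
#' whenever the clamp is inactive this is algebraically identical to the
#' formula above, and it prevents error amplification from driving pixels
#' out of range over many steps. [sample_ddpm()] samples with clipping on.
#'
#' @param model A `vf_denoiser`.
#' @param xt `n x d` matrix at timestep `t`.
#' @param t Integer timestep in `[1, T]`.
#' @param schedule A [build_schedule()] object.
#' @param noise Optional `n x d` standard-normal matrix (for reproducible or
#'   noise-free steps); default draws from the RNG.
#' @param clip_denoised Clamp the implied clean sample to `[-1, 1]`.
#' @return `n x d` matrix at timestep `t - 1`.
#' @export
reverse_step <- function(model, xt, t, schedule, noise = NULL,
                         clip_denoised = FALSE) {
  if (t < 1 || t > schedule$T) stop("t must lie in [1, T]: nothing to denoise at t = 0")
  if (is.null(dim(xt))) xt <- matrix(xt, 1)
  eps_hat <- predict_noise(model, xt, t)
  ab <- ab_at(schedule, t)
  if (clip_denoised) {
    x0h <- clamp((xt - sqrt(1 - ab) * eps_hat) / sqrt(ab), -1, 1)
    ab_prev <- ab_at(schedule, t - 1)
    mu <- (sqrt(ab_prev) * schedule$beta[t] * x0h +
           sqrt(schedule$alpha[t]) * (1 - ab_prev) * xt) / (1 - ab)
  } else {
    mu <- (xt - schedule$beta[t] / sqrt(1 - ab) * eps_hat) /
          sqrt(schedule$alpha[t])
  }
  if (schedule$sigma[t] == 0) return(mu)
  if (is.null(noise)) noise <- matrix(rnorm(length(xt)), nrow(xt))
  mu + schedule$sigma[t] * noise
}

#' Configuration for DDPM training
#'
#' The desk profile (defaults) is sized for CPU runs: small dense denoiser,
#' `T = 200` timesteps. The `"paper"` profile records the emulated study's
#' published settings — input 256 (or 128),
#' batch 32 (or 16), learning rate 1e-4, thousands of epochs,
#' `T = 10000` — and is exposed for completeness, not exercised by tests.
#'
#' @param updates Total number of optimizer updates (minibatch steps).
#' @param lr Learning rate for Adam.
#' @param batch_size Minibatch size.
#' @param input_size Image side (pixels); ignored for non-image data.
#' @param T,s Noise-schedule parameters.
#' @param widths Denoiser encoder/bottleneck widths.
#' @param temb_dim Sinusoidal timestep-embedding dimension.
#' @param seed Integer seed; fixed and recorded.
#' @param log_every Record mean loss every this many updates.
#' @return List of class `ddpm_config`.
#' @export
ddpm_config <- function(updates = 1200, lr = 2e-3, batch_size = 32,
                        input_size = 16, T = 200, s = 0.008,
                        widths = c(64, 32), temb_dim = 16, seed = 1,
                        log_every = 50) {
  stopifnot(updates >= 1, lr > 0, batch_size >= 1, T >= 1, s > 0)
  structure(list(updates = updates, lr = lr, batch_size = batch_size,
                 input_size = input_size, T = T, s = s, widths = widths,
                 temb_dim = temb_dim, seed = as.integer(seed),
                 log_every = log_every),
            class = "ddpm_config")
}

#' The published hyperparameter profile of the emulated study
#'
#' @return A `ddpm_config` with the published settings (input 256, batch 32,
#'   lr 1e-4; `T = 10000` timesteps per the grid-search optimum). Far beyond
#'   CPU budgets; recorded for completeness.
#' @export
ddpm_paper_profile <- function() {
  ddpm_config(updates = 10000, lr = 1e-4, batch_size = 32, input_size = 256,
              T = 10000, widths = c(128, 256), temb_dim = 64)
}

#' Train an unconditional DDPM on one class
#'
#' Standard noise-prediction training: each update draws a minibatch,
#' uniform timesteps from `{1..T}`, fresh Gaussian noise, corrupts the batch
#' with the closed-form forward process, and takes an Adam step on the
#' mean-squared error between realized and predicted noise. Images are
#' rescaled from 8-bit to `[-1, 1]`; a plain numeric matrix (rows = samples)
#' is accepted as-is for non-image data. Fully deterministic given the
#' config seed.
#'
#' @param dataset A non-empty [vf_dataset()] (typically one class), or an
#'   `n x d` numeric matrix already on model scale.
#' @param config A [ddpm_config()].
#' @return A `vf_denoiser` with fields `schedule`, `config`, `loss_log`
#'   (data frame `update`, `loss`), and `data_info`.
#' @export
train_ddpm <- function(dataset, config = ddpm_config()) {
  if (inherits(dataset, "vf_dataset")) {
    if (length(dataset) == 0) stop("dataset is empty")
    size <- dim(dataset$images[[1]]$pixels)[1]
    if (size != config$input_size)
      stop("dataset image size ", size, " != config input size ",
           config$input_size)
    X <- dataset_matrix(dataset)
    info <- list(kind = "images", size = size,
                 label = unique(dataset$manifest$label))
  } else {
    X <- as.matrix(dataset)
    if (nrow(X) == 0) stop("dataset is empty")
    info <- list(kind = "matrix", size = NA)
  }
  schedule <- build_schedule(config$T, config$s)
  with_seed(config$seed, {
    model <- denoiser_init(ncol(X), config$widths, config$temb_dim)
    opt <- adam_init(model$params)
    log_u <- integer(); log_l <- numeric(); acc <- numeric()
    for (u in seq_len(config$updates)) {
      idx <- sample.int(nrow(X), min(config$batch_size, nrow(X)),
                        replace = nrow(X) < config$batch_size)
      x0 <- X[idx, , drop = FALSE]
      t <- sample.int(schedule$T, length(idx), replace = TRUE)
      eps <- matrix(rnorm(length(x0)), nrow(x0))
      ab <- ab_at(schedule, t)
      xt <- sqrt(ab) * x0 + sqrt(1 - ab) * eps
      fw <- denoiser_forward(model, xt, t, keep_cache = TRUE)
      resid <- fw$out - eps
      acc <- c(acc, mean(resid^2))
      grads <- denoiser_backward(model, fw$cache, 2 * resid / length(resid))
      st <- adam_step(model$params, grads, opt, config$lr)
      model$params <- st$params; opt <- st$state
      if (u %% config$log_every == 0 || u == config$updates) {
        log_u <- c(log_u, u); log_l <- c(log_l, mean(acc)); acc <- numeric()
      }
    }
    model$schedule <- schedule
    model$config <- config
    model$loss_log <- data.frame(update = log_u, loss = log_l)
    model$data_info <- info
    model
  })
}

#' Draw samples from a trained DDPM by ancestral sampling
#'
#' Starts from standard normal noise and applies all `T` reverse steps.
#' `sample_ddpm()` returns the raw `n x d` matrix clamped to `[-1, 1]`;
#' [sample_images()] additionally maps to 8-bit phantom-convention images
#' with `provenance = "synthetic"`.
#'
#' @param model A trained `vf_denoiser` (with embedded schedule).
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return For `sample_ddpm()`, an `n x d` matrix in `[-1, 1]`.
#' @export
sample_ddpm <- function(model, n, seed = 1) {
  stopifnot(n >= 1)
  schedule <- model$schedule
  with_seed(derive_seed(seed, "sample"), {
    x <- matrix(rnorm(n * model$d), n)
    for (t in seq(schedule$T, 1))
      x <- reverse_step(model, x, t, schedule, clip_denoised = TRUE)
    clamp(x, -1, 1)
  })
}

#' @rdname sample_ddpm
#' @param label Class label for the emitted images (defaults to the label of
#'   the training data when available).
#' @return For `sample_images()`, a [vf_dataset()] of `n` synthetic images.
#' @export
sample_images <- function(model, n, seed = 1, label = NULL) {
  label <- label %||% model$data_info$label[1]
  if (is.null(label) || is.na(label)) stop("label is required for image output")
  size <- model$config$input_size
  if (model$d != size * size * 3) stop("model was not trained on images")
  m <- sample_ddpm(model, n, seed)
  vf_dataset(matrix_to_images(m, size, label, provenance = "synthetic",
                              id_prefix = sprintf("synth-s%d", seed),
                              seed = seed))
}
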