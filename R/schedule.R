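#' Cumulative signal-retention coefficient of the squared-cosine schedule
#'
#' Evaluates the cumulative noise schedule
#' \deqn{\bar\alpha_t = f(t)/f(0), \qquad
#'       f(t) = \cos^2\!\left(\frac{t/T + s}{1 + s}\cdot\frac{\pi}{2}\right),}
#' the squared-cosine parameterization that grows noise smoothly from
#' \eqn{\bar\alpha_0 = 1} to \eqn{\bar\alpha_T \approx 0}; the small offset
#' `s` keeps the first steps from being noise-free.
#'
#' @param t Integer timestep(s) in `[0, T]`.
#' @param T Total number of diffusion timesteps.
#' @param s Positive offset (default 0.008, the established convention).
#' @return \eqn{\bar\alpha_t} in `[0, 1]`, vectorized over `t`.
#' @export
cosine_alpha_bar <- function(t, T, s = 0.008) {
  stopifnot(T >= 1, s > 0)
  if (any(t < 0 | t > T)) stop("t must lie in [0, T]")
  f <- function(tt) cos(((tt / T + s) / (1 + s)) * pi / 2)^2
  f(t) / f(0)
}

#' Build the full diffusion noise schedule
#'
#' Computes \eqn{\bar\alpha_t} on the squared-cosine schedule for
#' `t = 0, ..., T`, derives the per-step quantities
#' \eqn{\beta_t = 1 - \bar\alpha_t/\bar\alpha_{t-1}} (clipped at 0.999 to
#' avoid a singular final step), \eqn{\alpha_t = 1 - \beta_t}, and the
#' ancestral-sampling standard deviation \eqn{\sigma_t = \sqrt{\beta_t}} with
#' \eqn{\sigma_1 = 0} (the final denoising step is deterministic). After
#' clipping, the stored \eqn{\bar\alpha_t} is recomputed as
#' \eqn{\prod_{u \le t} \alpha_u} so the product identity holds exactly.
#'
#' @param T Number of timesteps (>= 1).
#' @param s Positive schedule offset.
#' @return Object of class `noise_schedule` with fields `T`, `s`,
#'   `alpha_bar` (length `T + 1`, index 1 is `t = 0`), `alpha`, `beta`,
#'   `sigma` (each length `T`, index t is timestep t).
#' @export
build_schedule <- function(T = 200, s = 0.008) {
  if (T < 1) stop("T must be >= 1")
  ab_raw <- cosine_alpha_bar(0:T, T, s)
  beta <- pmin(1 - ab_raw[-1] / ab_raw[-(T + 1)], 0.999)
  alpha <- 1 - beta
  alpha_bar <- c(1, cumprod(alpha))
  sigma <- sqrt(beta)
  sigma[1] <- 0
  structure(list(T = T, s = s, alpha_bar = alpha_bar, alpha = alpha,
                 beta = beta, sigma = sigma),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf(
    "<noise_schedule: T=%d, s=%g, alpha_bar[T]=%.3g, beta in [%.3g, %.3g]>\n",
    x$T, x$s, x$alpha_bar[x$T + 1], min(x$beta), max(x$beta)))
  invisible(x)
}

# alpha_bar at integer timestep t (0-based), from a schedule.
ab_at <- function(schedule, t) schedule$alpha_bar[t + 1]
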