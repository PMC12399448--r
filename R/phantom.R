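#' Render one phantom laryngoscopy image
#'
#' Procedurally draws a square region-of-interest view of abducted vocal
#' folds: a dark peripheral vignette, a pink mucosa field, two elongated pale
#' fold bands converging anteriorly around a dark glottal gap, and a lesion
#' drawn according to the requested class archetype:
#'
#' * `nodule` — two mirror-symmetric bumps at the junction of the anterior
#'   third and posterior two thirds of the folds;
#' * `cyst` — one rounded encapsulated unilateral mid-fold mass;
#' * `polyp` — one reddish irregular unilateral mid-fold blob;
#' * `reinkes_edema` — bilateral widening (polypoid swelling) of the folds;
#' * `sulcus_vocalis` — a dark groove along the medial edge of one fold;
#' * `granuloma` — a lumpy unilateral mass near the posterior vocal process;
#' * `keratosis` — a flat whitish patch on one fold;
#' * `without_pathology` — no lesion (empty mask).
#'
#' Nuisance variation emulates acquisition conditions: uniform in-plane
#' rotation (±15°), illumination gain (±20%), and Gaussian sensor noise
#' (sd 4 intensity units). The ground-truth lesion mask is computed from the
#' same geometry, before noise. Output is deterministic given
#' `(label, seed, style, size)`.
#'
#' @param label One of [vf_labels()].
#' @param seed Nonnegative integer seed for this image.
#' @param size Image side in pixels (square output).
#' @param style Optional named list overriding any drawn style parameter
#'   (`theta_deg`, `gain`, `noise_sd`, `sep_a`, `sep_p`, `wf`, `side`,
#'   `lesion_v`).
#' @return A [vf_image()] with lesion `mask` and generation metadata.
#' @export
render_phantom <- function(label, seed, size = 64, style = list()) {
  if (!label %in% vf_labels()) stop("unknown label: ", label)
  stopifnot(seed >= 0, size >= 16)
  with_seed(derive_seed(seed, "phantom", label), {
    p <- list(
      theta_deg = runif(1, -15, 15),
      gain      = runif(1, 0.8, 1.2),
      noise_sd  = 4,
      sep_a     = 0.20 + runif(1, -0.02, 0.02),  # anterior centerline offset
      sep_p     = 0.45 + runif(1, -0.04, 0.04),  # posterior centerline offset
      wf        = 0.11 + runif(1, -0.012, 0.012),  # fold half-width
      side      = sample(c(-1, 1), 1),             # lesion side (unilateral)
      lesion_v  = -0.20 + runif(1, -0.10, 0.10),   # mid-fold position
      mucosa    = c(204, 132, 124) + runif(3, -10, 10),
      fold_col  = c(232, 206, 200) + runif(3, -8, 8),
      glottis   = c(58, 28, 30) + runif(3, -6, 6),
      phase     = runif(3, 0, 2 * pi))             # mucosa texture phases
    p[names(style)] <- style

    ax <- seq(-1, 1, length.out = size)
    u <- matrix(ax, size, size, byrow = TRUE)   # column -> horizontal
    v <- matrix(ax, size, size)                 # row -> vertical (top = -1)
    th <- p$theta_deg * pi / 180
    ur <- cos(th) * u + sin(th) * v             # glottal-frame coordinates
    vr <- -sin(th) * u + cos(th) * v

    geom <- list(theta_deg = p$theta_deg, sep_a = p$sep_a, sep_p = p$sep_p,
                 wf = p$wf, v_lo = -0.85, v_hi = 0.90, gain = p$gain,
                 mucosa = p$mucosa, fold_col = p$fold_col)
    cl <- fold_centerline(vr, geom)
    vin <- soft_band(vr, geom$v_lo, geom$v_hi, 0.06)

    # mucosa field with low-frequency texture
    tex <- 1 + 0.05 * (sin(2.3 * u + p$phase[1]) * cos(1.7 * v + p$phase[2]) +
                       0.6 * sin(3.1 * (u + v) + p$phase[3]))
    img <- array(0, dim = c(size, size, 3))
    for (k in 1:3) img[, , k] <- p$mucosa[k] * tex

    # glottal gap then fold bands (composited over the gap edges)
    w_gl <- clamp(((cl - 0.5 * p$wf) - abs(ur)) / (0.1 * p$wf + 0.02), 0, 1) * vin
    w_f  <- clamp((p$wf - abs(abs(ur) - cl)) / (0.25 * p$wf), 0, 1) * vin
    img <- blend(img, p$glottis, w_gl)
    img <- blend(img, p$fold_col, w_f)

    lm <- render_lesion(label, ur, vr, cl, p)
    img <- lm$img %||% img
    if (!is.null(lm$color)) img <- blend(img, lm$color, lm$w)
    mask <- lm$mask

    # vignette, illumination, sensor noise
    r <- sqrt(u^2 + v^2)
    shade <- 1 - 0.55 * clamp((r - 0.65) / 0.55, 0, 1)^1.5
    for (k in 1:3) img[, , k] <- img[, , k] * shade * p$gain
    img <- img + array(rnorm(length(img), 0, p$noise_sd), dim = dim(img))
    img <- round(clamp(img, 0, 255))

    vf_image(img, label = label, provenance = "original", mask = mask,
             id = sprintf("%s-%08d", label, as.integer(seed)),
             meta = c(list(seed = as.integer(seed)), geom,
                      list(side = p$side, lesion_v = p$lesion_v)))
  })
}

# Fold centerline offset |u| = cl(v): grows anterior -> posterior.
fold_centerline <- function(vr, geom) {
  frac <- clamp((vr - geom$v_lo) / (geom$v_hi - geom$v_lo), 0, 1)
  geom$sep_a + (geom$sep_p - geom$sep_a) * frac
}

# Soft indicator of lo <= x <= hi with edge width w.
soft_band <- function(x, lo, hi, w) {
  clamp((x - lo) / w, 0, 1) * clamp((hi - x) / w, 0, 1)
}

soft_disc <- function(ur, vr, u0, v0, r, aspect = 1, mod = 0) {
  du <- (ur - u0) / aspect
  dv <- vr - v0
  rr <- r * (1 + mod * sin(3 * atan2(dv, du)))
  clamp((rr - sqrt(du^2 + dv^2)) / (0.25 * r), 0, 1)
}

blend <- function(img, color, w) {
  for (k in 1:3) img[, , k] <- img[, , k] * (1 - w) + color[k] * w
  img
}

# Draw the class lesion; returns list(w, color, mask).
render_lesion <- function(label, ur, vr, cl, p) {
  s <- p$side; v0 <- p$lesion_v
  cl_at <- function(vv) p$sep_a + (p$sep_p - p$sep_a) * clamp((vv + 0.85) / 1.75, 0, 1)
  zero <- matrix(0, nrow(ur), ncol(ur))
  out <- switch(label,
    without_pathology = list(w = zero, color = NULL),
    nodule = {
      c0 <- cl_at(v0)
      w <- soft_disc(ur, vr, c0, v0, 0.055) + soft_disc(ur, vr, -c0, v0, 0.055)
      list(w = clamp(w, 0, 1), color = p$fold_col + c(6, -14, -10))
    },
    cyst = {
      c0 <- cl_at(v0)
      list(w = soft_disc(ur, vr, s * c0, v0, 0.09),
           color = c(228, 212, 178))
    },
    polyp = {
      c0 <- cl_at(v0)
      list(w = soft_disc(ur, vr, s * (c0 - 0.03), v0, 0.10, mod = 0.3),
           color = c(198, 74, 74))
    },
    reinkes_edema = {
      band <- clamp((1.8 * p$wf - abs(abs(ur) - cl)) / (0.25 * p$wf), 0, 1) -
              clamp((p$wf - abs(abs(ur) - cl)) / (0.25 * p$wf), 0, 1)
      w <- clamp(band, 0, 1) * soft_band(vr, -0.60, 0.50, 0.08)
      list(w = w, color = p$fold_col + c(-6, -16, -8))
    },
    sulcus_vocalis = {
      groove <- abs(abs(ur) - (cl - 0.35 * p$wf))
      onside <- (ur * s) > 0
      w <- clamp((0.018 - groove) / 0.010, 0, 1) * onside *
           soft_band(vr, -0.60, 0.60, 0.06)
      list(w = w, color = c(150, 86, 90))
    },
    granuloma = {
      v0g <- 0.62
      c0 <- cl_at(v0g)
      list(w = soft_disc(ur, vr, s * 0.8 * c0, v0g, 0.095, mod = 0.25),
           color = c(214, 122, 112))
    },
    keratosis = {
      c0 <- cl_at(v0)
      list(w = soft_disc(ur, vr, s * c0, v0, 0.16, aspect = 0.45, mod = 0.15),
           color = c(246, 244, 236))
    })
  out$mask <- out$w > 0.5
  out
}

#' Generate a labeled phantom dataset
#'
#' Renders exactly the requested number of images per class; output is
#' byte-identical for identical arguments (every image's seed is derived from
#' `(seed, label, index)`).
#'
#' @param distribution A [class_distribution()] (or named count vector), e.g.
#'   [reference_distribution()].
#' @param seed Integer seed for the whole dataset.
#' @param image_size Image side in pixels.
#' @return A [vf_dataset()] with `sum(distribution)` images.
#' @export
generate_dataset <- function(distribution, seed = 1, image_size = 64) {
  distribution <- class_distribution(distribution)
  images <- list()
  for (label in vf_labels()) {
    n <- distribution[[label]]
    if (n == 0) next
    for (i in seq_len(n)) {
      im <- render_phantom(label, seed = derive_seed(seed, label, i),
                           size = image_size)
      im$id <- sprintf("%s-%04d", label, i)
      images[[im$id]] <- im
    }
  }
  vf_dataset(images)
}

#' Degrade an image for curation testing
#'
#' Produces the failure modes the curation stage screens for: `blur` applies
#' Gaussian smoothing of width `severity` pixels; `remove_folds` replaces the
#' fold bands and glottal gap with mucosa texture (no folds visible);
#' `triplicate_fold` inserts a spurious third pale band through the glottal
#' midline. The label and id lineage are preserved in metadata.
#' `remove_folds` and `triplicate_fold` require renderer metadata and are
#' intended for phantom images.
#'
#' @param image A [vf_image()] from the phantom renderer.
#' @param mode `"blur"`, `"remove_folds"` or `"triplicate_fold"`.
#' @param severity Positive real; blur width in pixels, or band-width scale.
#' @return A modified copy of `image`.
#' @export
degrade <- function(image, mode = c("blur", "remove_folds", "triplicate_fold"),
                    severity = 1) {
  mode <- match.arg(mode)
  stopifnot(severity > 0)
  px <- image$pixels
  size <- dim(px)[1]
  if (mode == "blur") {
    px <- gaussian_blur(px, sigma = severity)
  } else {
    g <- image$meta
    if (is.null(g$wf)) stop("'", mode, "' needs phantom renderer metadata")
    ax <- seq(-1, 1, length.out = size)
    u <- matrix(ax, size, size, byrow = TRUE)
    v <- matrix(ax, size, size)
    th <- g$theta_deg * pi / 180
    ur <- cos(th) * u + sin(th) * v
    vr <- -sin(th) * u + cos(th) * v
    cl <- fold_centerline(vr, g)
    vin <- soft_band(vr, g$v_lo, g$v_hi, 0.06)
    # replacement/insertion colors carry the same vignette and illumination
    # gain as the rendered scene, so degraded regions blend photometrically
    shade <- (1 - 0.55 * clamp((sqrt(u^2 + v^2) - 0.65) / 0.55, 0, 1)^1.5) *
             (g$gain %||% 1)
    if (mode == "remove_folds") {
      # everything medial of the fold outer edges (including edematous
      # widening) becomes mucosa texture
      w <- clamp((cl + g$wf * max(2.0, 1 + 0.3 * severity) - abs(ur)) /
                 (0.15 * g$wf), 0, 1) * vin
      fill <- with_seed(derive_seed(image$meta$seed %||% 0, "remove"), {
        array(rep(g$mucosa, each = size * size), dim = dim(px)) * c(shade) +
          array(rnorm(length(px), 0, 4), dim = dim(px))
      })
      for (k in 1:3) px[, , k] <- px[, , k] * (1 - w) + fill[, , k] * w
    } else {
      w <- clamp((0.5 * g$wf * severity - abs(ur)) / (0.2 * g$wf), 0, 1) *
           soft_band(vr, -0.30, 0.85, 0.06)
      for (k in 1:3) px[, , k] <- px[, , k] * (1 - w) +
        (g$fold_col[k] * shade) * w
    }
    px <- round(clamp(px, 0, 255))
  }
  out <- image
  out$pixels <- clamp(px, 0, 255)
  out$id <- paste0(image$id, "-", mode)
  out$meta$degraded <- list(mode = mode, severity = severity,
                            parent = image$id)
  out
}

# Separable Gaussian blur with reflected edges; sigma in pixels.
gaussian_blur <- function(px, sigma) {
  if (sigma <= 0.05) return(px)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), seq(-r, r), "+")
    idx <- abs(idx - 1) %% (2 * n - 2) + 1          # reflect
    idx[idx > n] <- 2 * n - idx[idx > n]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  for (ch in 1:3) {
    m <- px[, , ch]
    px[, , ch] <- t(smooth1(t(smooth1(m))))
  }
  px
}
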