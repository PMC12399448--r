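#' Fit an image feature extractor
#'
#' The canonical feature network for Fréchet-distance evaluation is a large
#' pretrained classifier, which requires external weights; the package's
#' desk extractors are self-contained instead: `"pca"` (default) projects
#' flattened pixels onto the leading principal components of a reference
#' dataset (deterministic), and `"autoencoder"` trains a small dense
#' bottleneck autoencoder on the reference and uses its code layer.
#' Absolute distance values therefore live on the extractor's own scale and
#' are comparable only across sets evaluated with the same fitted extractor.
#'
#' @param reference [vf_dataset()] the extractor is fitted on (typically the
#'   original images).
#' @param type `"pca"` or `"autoencoder"`.
#' @param dim Feature dimension.
#' @param seed Seed for the autoencoder (ignored for PCA).
#' @param updates,lr Autoencoder training parameters.
#' @return Object of class `vf_extractor`.
#' @export
fit_extractor <- function(reference, type = c("pca", "autoencoder"),
                          dim = 32, seed = 1, updates = 400, lr = 1e-3) {
  type <- match.arg(type)
  stopifnot(length(reference) >= 2)
  X <- dataset_matrix(reference)
  dim <- min(dim, nrow(X) - 1, ncol(X))
  if (type == "pca") {
    pc <- stats::prcomp(X, center = TRUE, rank. = dim)
    ex <- list(type = "pca", center = pc$center, rotation = pc$rotation)
  } else {
    with_seed(derive_seed(seed, "ae"), {
      net <- mlp_init(c(ncol(X), 128, dim, 128, ncol(X)))
      opt <- adam_init(net$params)
      for (u in seq_len(updates)) {
        idx <- sample.int(nrow(X), min(32, nrow(X)))
        xb <- X[idx, , drop = FALSE]
        fw <- mlp_forward(net, xb, keep_cache = TRUE)
        grads <- mlp_backward(net, fw$cache,
                              2 * (fw$out - xb) / length(xb))
        st <- adam_step(net$params, grads, opt, lr)
        net$params <- st$params; opt <- st$state
      }
      ex <- list(type = "autoencoder", net = net, code_layer = 2)
    })
  }
  ex$d <- dim
  ex$input_len <- ncol(X)
  structure(ex, class = "vf_extractor")
}

#' Extract image features for distribution comparison
#'
#' @param dataset Non-empty [vf_dataset()] with image length matching the
#'   extractor.
#' @param extractor A [fit_extractor()] object.
#' @return `n x d` feature matrix (deterministic given the fitted extractor).
#' @export
extract_features <- function(dataset, extractor) {
  stopifnot(length(dataset) >= 1)
  X <- dataset_matrix(dataset)
  if (ncol(X) != extractor$input_len)
    stop("image size does not match the extractor input length")
  if (extractor$type == "pca") {
    sweep(X, 2, extractor$center) %*% extractor$rotation
  } else {
    net <- extractor$net
    h <- X
    for (i in seq_len(extractor$code_layer)) {
      z <- sweep(h %*% net$params[[paste0("W", i)]], 2,
                 net$params[[paste0("b", i)]], "+")
      h <- if (i < extractor$code_layer) silu(z) else z
    }
    h
  }
}

#' Fréchet distance between two feature distributions
#'
#' Gaussian-approximation distance
#' \deqn{\mathrm{FID} = \|\mu_r - \mu_s\|^2 +
#'       \mathrm{Tr}\left(\Sigma_r + \Sigma_s -
#'       2(\Sigma_r\Sigma_s)^{1/2}\right),}
#' where \eqn{\mu, \Sigma} are feature means and covariances of the two
#' sets. The matrix square root is taken by eigendecomposition of the
#' symmetrized product \eqn{\Sigma_r^{1/2}\Sigma_s\Sigma_r^{1/2}} with
#' negative eigenvalues clipped at zero; covariances are regularized by
#' `+1e-6 I`; a (numerically) negative result is floored at 0. Symmetric in
#' its arguments and zero for identical inputs.
#'
#' @param real_features,synth_features Feature matrices (>= 2 rows each,
#'   equal column count), e.g. from [extract_features()].
#' @return Object of class `fid_result`: `value`, `mu_r`, `mu_s`,
#'   `sigma_r`, `sigma_s`.
#' @export
fid <- function(real_features, synth_features) {
  real_features <- as.matrix(real_features)
  synth_features <- as.matrix(synth_features)
  if (ncol(real_features) != ncol(synth_features))
    stop("feature dimensions differ")
  if (nrow(real_features) < 2 || nrow(synth_features) < 2)
    stop("need >= 2 rows per feature set")
  mu_r <- colMeans(real_features); mu_s <- colMeans(synth_features)
  reg <- diag(1e-6, ncol(real_features))
  S_r <- stats::cov(real_features) + reg
  S_s <- stats::cov(synth_features) + reg
  sqrt_r <- sym_sqrt(S_r)
  inner <- sym_sqrt(sqrt_r %*% S_s %*% sqrt_r)
  value <- sum((mu_r - mu_s)^2) + sum(diag(S_r)) + sum(diag(S_s)) -
           2 * sum(diag(inner))
  structure(list(value = max(value, 0), mu_r = mu_r, mu_s = mu_s,
                 sigma_r = S_r, sigma_s = S_s),
            class = "fid_result")
}

# Symmetric PSD matrix square root by eigendecomposition, negative
# eigenvalues clipped at zero.
sym_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' @export
print.fid_result <- function(x, ...) {
  cat(sprintf("<fid_result: %.4f (d=%d)>\n", x$value, length(x$mu_r)))
  invisible(x)
}
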