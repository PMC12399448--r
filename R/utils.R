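#' Class vocabulary for vocal fold structural pathologies
#'
#' The eight image labels used throughout the package: healthy folds plus the
#' seven lesion phenotypes (nodule, cyst, polyp, Reinke's edema, sulcus
#' vocalis, granuloma, keratosis).
#'
#' @return Character vector of the 8 canonical labels.
#' @export
vf_labels <- function() {
  c("without_pathology", "nodule", "cyst", "polyp", "sulcus_vocalis",
    "reinkes_edema", "keratosis", "granuloma")
}

#' @rdname vf_labels
#' @return For `pathology_labels()`, the 7 lesion labels (healthy excluded).
#' @export
pathology_labels <- function() setdiff(vf_labels(), "without_pathology")

#' Reference class distribution of the emulated study collection
#'
#' Per-class image counts used as the package's reference imbalanced
#' distribution: 404 original images with a 39.25:1 ratio between the most
#' frequent class (healthy, 157) and the rarest (granuloma, 4), and the 4180
#' per-class synthetic counts that rebalance it.
#'
#' @param type `"original"` for the clinical-collection counts, `"synthetic"`
#'   for the synthetic-augmentation counts.
#' @return Named integer vector over [vf_labels()].
#' @export
reference_distribution <- function(type = c("original", "synthetic")) {
  type <- match.arg(type)
  counts <- switch(type,
    original  = c(without_pathology = 157L, nodule = 71L, cyst = 38L,
                  polyp = 35L, sulcus_vocalis = 33L, reinkes_edema = 29L,
                  keratosis = 37L, granuloma = 4L),
    synthetic = c(without_pathology = 384L, nodule = 374L, cyst = 538L,
                  polyp = 585L, sulcus_vocalis = 315L, reinkes_edema = 473L,
                  keratosis = 970L, granuloma = 541L))
  class_distribution(counts)
}

#' Validate a per-class count vector
#'
#' @param counts Named nonnegative integer vector; names must be a subset of
#'   [vf_labels()]. Missing classes are filled with 0.
#' @return Named integer vector over all 8 labels, class `class_distribution`.
#' @export
class_distribution <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector")
  unknown <- setdiff(names(counts), vf_labels())
  if (length(unknown))
    stop("unknown class label(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  out <- stats::setNames(integer(length(vf_labels())), vf_labels())
  out[names(counts)] <- as.integer(counts)
  structure(out, class = c("class_distribution", "integer"))
}

#' Derive a reproducible child seed from a global seed and a context key
#'
#' Stage and repeat seeds are derived by a stable integer hash of the global
#' seed and arbitrary key parts, so that every stochastic stage is
#' independently reseedable and the whole pipeline is reproducible from one
#' integer.
#'
#' @param seed Integer global seed.
#' @param ... Key parts (coerced to character), e.g. stage name, class label,
#'   repeat index.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  m <- 2147483647  # 2^31 - 1, keeps everything in 32-bit integer range
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
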