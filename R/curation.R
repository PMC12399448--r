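# Automated stand-in for expert review of synthetic images: the two stated
# rejection criteria — implausible fold structure (no folds, or a spurious
# third fold / unidentifiable glottis) and remarkable blur — implemented as
# measurable filters.

#' Sharpness score (variance of a Laplacian response)
#'
#' Variance of a discrete 4-neighbour Laplacian of the luminance channel;
#' higher is sharper. Zero for a constant image, invariant to a global
#' intensity offset, and strictly decreasing under increasing Gaussian blur.
#'
#' @param image A [vf_image()].
#' @return Nonnegative scalar.
#' @export
sharpness_score <- function(image) {
  y <- luminance(image$pixels)
  n <- nrow(y)
  if (n < 3) return(0)
  core <- y[2:(n - 1), 2:(n - 1)]
  lap <- y[1:(n - 2), 2:(n - 1)] + y[3:n, 2:(n - 1)] +
         y[2:(n - 1), 1:(n - 2)] + y[2:(n - 1), 3:n] - 4 * core
  stats::var(as.numeric(lap))
}

luminance <- function(px) 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]

#' Fold-structure plausibility score
#'
#' Counts elongated bright band components in the central region of the
#' image: the luminance crop (central `region` fraction) is thresholded at
#' the `percentile`-th intensity percentile, connected components are
#' labeled, and components are kept if they are large enough, elongated
#' (eccentricity >= `eccentricity`), and genuinely brighter than the
#' surrounding mucosa (mean component luminance >= `contrast` times the crop
#' median — the fold bands are pale against the pink mucosa, so bright
#' texture patches in a fold-free image do not qualify). A plausible
#' laryngoscopy view shows exactly two such bands (the vocal folds); zero
#' means no folds visible, three or more means a deformed render.
#'
#' @param image A [vf_image()].
#' @param region Central crop fraction (default 0.6).
#' @param percentile Luminance threshold percentile (default 70).
#' @param eccentricity Minimum component eccentricity (default 0.8).
#' @param min_area Minimum component area as a fraction of the crop
#'   (default 0.02).
#' @param contrast Minimum mean-luminance ratio over the crop median
#'   (default 1.15).
#' @return List with `fold_band_count` (integer) and `plausible`
#'   (`TRUE` iff exactly 2 bands).
#' @export
structure_score <- function(image, region = 0.6, percentile = 70,
                            eccentricity = 0.8, min_area = 0.02,
                            contrast = 1.15) {
  y <- luminance(image$pixels)
  n <- nrow(y)
  lo <- max(1L, floor(n * (1 - region) / 2))
  hi <- min(n, ceiling(n * (1 + region) / 2))
  crop <- y[lo:hi, lo:hi]
  thr <- stats::quantile(crop, percentile / 100, names = FALSE)
  med <- stats::median(crop)
  lab <- EBImage::bwlabel(crop >= thr)
  nb <- max(lab)
  count <- 0L
  if (nb > 0) {
    mom <- EBImage::computeFeatures.moment(lab)
    mom <- matrix(mom, nrow = nb, dimnames = list(NULL, colnames(mom)))
    areas <- tabulate(lab[lab > 0], nbins = nb)
    bright <- vapply(seq_len(nb), function(k) mean(crop[lab == k]), 0)
    keep <- areas >= min_area * length(crop) &
            mom[, "m.eccentricity"] >= eccentricity &
            bright >= contrast * med
    count <- sum(keep)
  }
  list(fold_band_count = as.integer(count), plausible = count == 2L)
}

#' Curate a dataset of synthetic images
#'
#' Retains images that are both sharp (sharpness score at or above the
#' threshold) and structurally plausible (exactly two fold bands); every
#' rejected image carries a reason (`blurry`, `wrong_fold_count`, or
#' `out_of_range` for degenerate pixel content). Deterministic; the report
#' partitions the input exactly.
#'
#' @param dataset A [vf_dataset()].
#' @param sharpness_threshold Numeric threshold; if `NULL`, the 5th
#'   percentile of sharpness scores over `reference` (or over `dataset`
#'   itself when no reference is given), emulating calibration on the
#'   original collection.
#' @param reference Optional [vf_dataset()] of original images used to
#'   calibrate the default sharpness threshold.
#' @param ... Passed to [structure_score()].
#' @return List with `dataset` (retained images) and `report` (class
#'   `curation_report`: `retained`, `rejected` (data frame id/reason),
#'   `thresholds`).
#' @export
curate <- function(dataset, sharpness_threshold = NULL, reference = NULL,
                   ...) {
  if (length(dataset) == 0) {
    report <- structure(list(retained = character(),
                             rejected = data.frame(id = character(),
                                                   reason = character()),
                             thresholds = list(sharpness = sharpness_threshold)),
                        class = "curation_report")
    return(list(dataset = dataset, report = report))
  }
  if (is.null(sharpness_threshold)) {
    ref <- reference %||% dataset
    scores <- vapply(ref$images, sharpness_score, 0)
    # inverted-ECDF quantile: the threshold is an attained score, so a
    # reference image at the threshold is itself retained
    sharpness_threshold <- stats::quantile(scores, 0.05, names = FALSE,
                                           type = 1)
  }
  ids <- names(dataset$images)
  reason <- rep(NA_character_, length(ids))
  for (i in seq_along(ids)) {
    im <- dataset$images[[i]]
    if (anyNA(im$pixels) || min(im$pixels) < 0 || max(im$pixels) > 255) {
      reason[i] <- "out_of_range"
    } else if (sharpness_score(im) < sharpness_threshold) {
      reason[i] <- "blurry"
    } else if (!structure_score(im, ...)$plausible) {
      reason[i] <- "wrong_fold_count"
    }
  }
  keep <- is.na(reason)
  report <- structure(
    list(retained = ids[keep],
         rejected = data.frame(id = ids[!keep], reason = reason[!keep],
                               stringsAsFactors = FALSE),
         thresholds = list(sharpness = sharpness_threshold,
                           structure = list(...))),
    class = "curation_report")
  list(dataset = subset_dataset(dataset, ids[keep]), report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("<curation_report: %d retained, %d rejected>\n",
              length(x$retained), nrow(x$rejected)))
  if (nrow(x$rejected)) print(table(x$rejected$reason))
  invisible(x)
}
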