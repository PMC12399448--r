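#' Labeled laryngoscopy image
#'
#' Lightweight container for one image: an `H x W x 3` array of 8-bit
#' intensities (stored as numeric 0..255), its class label, provenance
#' (`original` or `synthetic`), an optional binary lesion mask of the same
#' `H x W`, a unique id, and generation metadata (seed, geometry) when the
#' image came from the phantom renderer.
#'
#' @param pixels `H x W x 3` numeric array with values in `[0, 255]`; `H == W`.
#' @param label One of [vf_labels()] (binary-task datasets additionally allow
#'   `"with_pathology"`).
#' @param provenance `"original"` or `"synthetic"`.
#' @param mask Optional `H x W` logical matrix marking lesion pixels.
#' @param id Unique id string.
#' @param meta Optional list of generation metadata.
#' @return Object of class `vf_image`.
#' @export
vf_image <- function(pixels, label, provenance = "original", mask = NULL,
                     id = NULL, meta = list()) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (dim(pixels)[1] != dim(pixels)[2])
    stop("images must be square (region-of-interest crop)")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  valid <- c(vf_labels(), "with_pathology")
  if (!label %in% valid) stop("unknown label: ", label)
  provenance <- match.arg(provenance, c("original", "synthetic"))
  if (!is.null(mask)) {
    stopifnot(is.matrix(mask), all(dim(mask) == dim(pixels)[1:2]))
    mask <- mask > 0
  }
  structure(list(pixels = pixels, label = label, provenance = provenance,
                 mask = mask, id = id %||% "img", meta = meta),
            class = "vf_image")
}

#' @export
print.vf_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<vf_image %s: %dx%d, label=%s, provenance=%s, mask=%s>\n",
              x$id, d[1], d[2], x$label, x$provenance,
              if (is.null(x$mask)) "none" else sum(x$mask)))
  invisible(x)
}

#' Image dataset with manifest
#'
#' An ordered collection of [vf_image()] objects plus a manifest data frame
#' (`id`, `label`, `provenance`, `seed`) kept in 1:1 correspondence. All
#' images must share dimensions and ids must be unique.
#'
#' @param images List of `vf_image` objects.
#' @return Object of class `vf_dataset`.
#' @export
vf_dataset <- function(images) {
  stopifnot(is.list(images))
  if (length(images)) {
    dims <- vapply(images, function(im) dim(im$pixels)[1], 0)
    if (length(unique(dims)) > 1)
      stop("all images in a dataset must share dimensions")
    ids <- vapply(images, function(im) im$id, "")
    if (anyDuplicated(ids)) stop("duplicate image ids in dataset")
    names(images) <- ids
    manifest <- data.frame(
      id = ids,
      label = vapply(images, function(im) im$label, ""),
      provenance = vapply(images, function(im) im$provenance, ""),
      seed = vapply(images, function(im) as.integer(im$meta$seed %||% NA), 0L),
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    manifest <- data.frame(id = character(), label = character(),
                           provenance = character(), seed = integer(),
                           stringsAsFactors = FALSE)
  }
  structure(list(images = images, manifest = manifest), class = "vf_dataset")
}

#' @export
length.vf_dataset <- function(x) length(x$images)

#' @export
print.vf_dataset <- function(x, ...) {
  cat(sprintf("<vf_dataset: %d images", length(x)))
  if (length(x)) {
    d <- dim(x$images[[1]]$pixels)
    cat(sprintf(", %dx%d", d[1], d[2]))
  }
  cat(">\n")
  if (length(x)) print(dataset_counts(x))
  invisible(x)
}

#' Per-class counts of a dataset
#'
#' @param dataset A [vf_dataset()].
#' @param labels Optional label vector defining the count order; defaults to
#'   the labels present.
#' @return Named integer vector of per-class counts.
#' @export
dataset_counts <- function(dataset, labels = NULL) {
  lab <- dataset$manifest$label
  labels <- labels %||% (if (all(lab %in% vf_labels())) vf_labels()[vf_labels() %in% lab]
                         else unique(lab))
  vapply(labels, function(l) sum(lab == l), 0L)
}

#' Subset a dataset by id or position
#'
#' @param dataset A [vf_dataset()].
#' @param ids Character ids or integer positions to keep.
#' @return A [vf_dataset()] with the selected images, in the given order.
#' @export
subset_dataset <- function(dataset, ids) {
  if (is.character(ids)) {
    missing <- setdiff(ids, names(dataset$images))
    if (length(missing))
      stop("unknown id(s): ", paste(head(missing, 3), collapse = ", "))
  }
  vf_dataset(dataset$images[ids])
}

#' Concatenate datasets
#'
#' @param ... [vf_dataset()] objects with disjoint ids and equal dimensions.
#' @return The combined [vf_dataset()].
#' @export
combine_datasets <- function(...) {
  parts <- list(...)
  vf_dataset(do.call(c, lapply(parts, function(d) d$images)))
}

# Flatten a dataset into an n x (H*W*3) matrix, pixel order fixed, values
# rescaled from [0,255] to [-1,1] (the diffusion model's working range).
dataset_matrix <- function(dataset, rescale = TRUE) {
  stopifnot(length(dataset) > 0)
  m <- t(vapply(dataset$images, function(im) as.numeric(im$pixels),
                numeric(length(dataset$images[[1]]$pixels))))
  rownames(m) <- names(dataset$images)
  if (rescale) m / 127.5 - 1 else m
}

# Inverse of dataset_matrix: rows in [-1,1] -> list of 8-bit image arrays.
matrix_to_images <- function(m, size, label, provenance = "synthetic",
                             id_prefix = "synth", seed = NA) {
  lapply(seq_len(nrow(m)), function(i) {
    px <- array(round(clamp((m[i, ] + 1) * 127.5, 0, 255)), dim = c(size, size, 3))
    vf_image(px, label = label, provenance = provenance,
             id = sprintf("%s-%s-%05d", id_prefix, label, i),
             meta = list(seed = seed))
  })
}
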