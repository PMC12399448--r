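#' Write an image dataset to disk
#'
#' Layout: `<root>/<label>/<id>.png` (8-bit RGB), masks under
#' `<root>/masks/<id>.png` (single channel), and `<root>/manifest.csv` with
#' columns `id,label,provenance,path,seed`.
#'
#' @param dataset A [vf_dataset()].
#' @param root Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_image_dataset <- function(dataset, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$path <- file.path(man$label, paste0(man$id, ".png"))
  for (i in seq_len(nrow(man))) {
    im <- dataset$images[[man$id[i]]]
    dir.create(file.path(root, im$label), showWarnings = FALSE)
    png::writePNG(im$pixels / 255, file.path(root, man$path[i]))
    if (!is.null(im$mask)) {
      dir.create(file.path(root, "masks"), showWarnings = FALSE)
      png::writePNG(im$mask * 1, file.path(root, "masks",
                                           paste0(im$id, ".png")))
    }
  }
  manifest_path <- file.path(root, "manifest.csv")
  write.csv(man, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read an image dataset from a manifest
#'
#' Validates labels against the 8-class vocabulary (plus the binary task
#' labels), checks that every referenced file exists and that dimensions are
#' homogeneous; all problems are reported per row before failing. PNG and
#' JPEG files are accepted (the emulated study's source frames were JPG);
#' masks are re-attached when present under `masks/`.
#'
#' @param manifest Path to a `manifest.csv` written by
#'   [write_image_dataset()], or a dataset root containing one.
#' @return A [vf_dataset()].
#' @export
read_image_dataset <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  root <- dirname(manifest)
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("id", "label", "provenance", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ","))
  errors <- character()
  valid <- c(vf_labels(), "with_pathology")
  images <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(root, man$path[i])
    if (!man$label[i] %in% valid) {
      errors <- c(errors, sprintf("row %d (%s): unknown label '%s'",
                                  i, man$id[i], man$label[i]))
      next
    }
    if (!file.exists(f)) {
      errors <- c(errors, sprintf("row %d (%s): missing file %s",
                                  i, man$id[i], man$path[i]))
      next
    }
    px <- read_image_file(f)
    mask_f <- file.path(root, "masks", paste0(man$id[i], ".png"))
    mask <- if (file.exists(mask_f)) png::readPNG(mask_f) > 0.5 else NULL
    images[[i]] <- vf_image(px, man$label[i], man$provenance[i], mask = mask,
                            id = man$id[i],
                            meta = list(seed = man$seed[i] %||% NA))
  }
  if (length(errors))
    stop("invalid manifest rows:\n", paste(errors, collapse = "\n"))
  dims <- vapply(images, function(im) dim(im$pixels)[1], 0)
  if (length(unique(dims)) > 1)
    stop("image dimensions are not homogeneous: ",
         paste(unique(dims), collapse = ", "))
  vf_dataset(images)
}

read_image_file <- function(path) {
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) {
    as.array(EBImage::readImage(path))
  } else stop("unsupported image format: ", path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]
  round(px * 255)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML key-value file, merges it over the documented defaults
#' (see [default_config()]), rejects unknown keys, and validates values. An
#' empty file yields all defaults. `profile: paper` switches the DDPM stage
#' to the published settings ([ddpm_paper_profile()]).
#'
#' @param path Path to a YAML file.
#' @return Validated config list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path) %||% list()
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  validate_config(cfg)
}

#' @rdname load_config
#' @export
default_config <- function() {
  list(profile = "desk",
       seed = 1,
       output_root = "vfddpm-output",
       image_size = 24,
       phantom_counts = "reference",   # or a named label->count list
       synthetic_scale = 0.25,         # fraction of the reference synthetic counts
       ddpm_updates = 1200,
       ddpm_T = 200,
       scenarios = c("original_only_baseline", "synthetic_only", "mix50"),
       tasks = c("binary", "multiclass"),
       repeats = 3,
       curation = TRUE)
}

validate_config <- function(cfg) {
  if (!cfg$profile %in% c("desk", "paper"))
    stop("config key 'profile' must be 'desk' or 'paper'")
  for (key in c("seed", "image_size", "ddpm_updates", "ddpm_T", "repeats"))
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 1 ||
        cfg[[key]] != round(cfg[[key]]))
      stop("config key '", key, "' must be a positive integer")
  if (!is.numeric(cfg$synthetic_scale) || cfg$synthetic_scale <= 0 ||
      cfg$synthetic_scale > 1)
    stop("config key 'synthetic_scale' must be a fraction in (0, 1]")
  bad <- setdiff(cfg$scenarios, c("original_only_baseline", "synthetic_only",
                                  "mix10", "mix50"))
  if (length(bad)) stop("unknown scenario(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(cfg$tasks, c("binary", "multiclass"))
  if (length(bad)) stop("unknown task(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = c("pipeline_config", "list"))
}
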