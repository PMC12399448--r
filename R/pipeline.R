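#' Train per-class DDPMs and sample a synthetic dataset
#'
#' One unconditional diffusion model per class (classes with fewer
#' generation targets still get their own model, mirroring per-class
#' generation in the emulated study), then ancestral sampling of the
#' requested number of images per class.
#'
#' @param original [vf_dataset()] of training images.
#' @param counts Named per-class synthetic target counts.
#' @param seed Global seed; per-class seeds are derived.
#' @param updates,T,widths,lr DDPM desk-profile settings (see
#'   [ddpm_config()]).
#' @param verbose Print per-class progress.
#' @return List: `synthetic` ([vf_dataset()]), `models` (per-class
#'   denoisers), `loss_logs`.
#' @export
generate_synthetic_dataset <- function(original, counts, seed = 1,
                                       updates = 1200, T = 200,
                                       widths = c(64, 32), lr = 2e-3,
                                       verbose = FALSE) {
  counts <- counts[counts > 0]
  size <- dim(original$images[[1]]$pixels)[1]
  models <- list(); parts <- list()
  for (label in names(counts)) {
    ids <- original$manifest$id[original$manifest$label == label]
    if (!length(ids)) stop("no original images for class ", label)
    cfg <- ddpm_config(updates = updates, T = T, widths = widths, lr = lr,
                       input_size = size,
                       seed = derive_seed(seed, "ddpm", label))
    t0 <- Sys.time()
    models[[label]] <- train_ddpm(subset_dataset(original, ids), cfg)
    synth <- sample_images(models[[label]], counts[[label]],
                           seed = derive_seed(seed, "sample", label))
    parts[[label]] <- synth
    if (verbose)
      message(sprintf("  %s: trained %d updates, sampled %d images (%.1fs)",
                      label, updates, counts[[label]],
                      as.numeric(Sys.time() - t0, units = "secs")))
  }
  list(synthetic = do.call(combine_datasets, parts), models = models,
       loss_logs = lapply(models, function(m) m$loss_log))
}

#' Run the full augmentation study end to end
#'
#' Executes the whole workflow on phantom data: generate the original
#' collection (reference imbalanced distribution by default), train one
#' DDPM per class and sample synthetic images, curate them, build the
#' augmentation scenarios for both tasks, train and evaluate classifiers
#' with repeats, and aggregate mean ± SD metric tables. All stage seeds are
#' derived from the global seed; rerunning with the same config reproduces
#' every deterministic artifact. When `config$output_root` is non-`NULL`,
#' manifests, loss logs, the curation report, metric tables, and the
#' resolved config are written beneath it.
#'
#' @param config A [load_config()] / [default_config()] list (validated).
#' @param verbose Print stage progress.
#' @return List of class `pipeline_result`: `original`, `synthetic`,
#'   `curation`, `grid` (an `experiment_grid`), `fid`, `config`.
#' @export
run_pipeline <- function(config = default_config(), verbose = FALSE) {
  config <- validate_config(config)
  say <- function(...) if (verbose) message(...)
  counts <- if (identical(config$phantom_counts, "reference"))
    reference_distribution("original")
  else class_distribution(unlist(config$phantom_counts))

  say("stage 1/5: phantom originals (", sum(counts), " images, seed ",
      config$seed, ")")
  original <- generate_dataset(counts, seed = derive_seed(config$seed, "orig"),
                               image_size = config$image_size)

  say("stage 2/5: per-class DDPM training and sampling")
  synth_counts <- round(reference_distribution("synthetic") *
                        config$synthetic_scale)
  if (config$profile == "paper") {
    pp <- ddpm_paper_profile()
    gen <- generate_synthetic_dataset(original, synth_counts,
                                      seed = config$seed,
                                      updates = pp$updates, T = pp$T,
                                      widths = pp$widths, lr = pp$lr,
                                      verbose = verbose)
  } else {
    gen <- generate_synthetic_dataset(original, synth_counts,
                                      seed = config$seed,
                                      updates = config$ddpm_updates,
                                      T = config$ddpm_T, verbose = verbose)
  }

  curation <- NULL
  synthetic <- gen$synthetic
  if (isTRUE(config$curation)) {
    say("stage 3/5: curation of ", length(synthetic), " synthetic images")
    cur <- curate(synthetic, reference = original)
    synthetic <- cur$dataset
    curation <- cur$report
    say("  retained ", length(cur$report$retained), ", rejected ",
        nrow(cur$report$rejected))
  } else say("stage 3/5: curation disabled")

  say("stage 4/5: scenario grid (", paste(config$scenarios, collapse = ", "),
      ") x (", paste(config$tasks, collapse = ", "), "), ",
      config$repeats, " repeats")
  grid <- run_experiment_grid(original, synthetic,
                              scenarios = config$scenarios,
                              tasks = config$tasks,
                              repeats = config$repeats, seed = config$seed)

  say("stage 5/5: feature-distribution distance")
  extractor <- fit_extractor(original, "pca", dim = 32)
  fid_overall <- fid(extract_features(original, extractor),
                     extract_features(synthetic, extractor))

  result <- structure(list(original = original, synthetic = synthetic,
                           curation = curation, grid = grid,
                           fid = fid_overall, models = gen$models,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$output_root)) write_pipeline_outputs(result)
  result
}

write_pipeline_outputs <- function(result) {
  root <- result$config$output_root
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(result$config), file.path(root, "config.yaml"))
  write.csv(result$original$manifest,
            file.path(root, "original_manifest.csv"), row.names = FALSE)
  write.csv(result$synthetic$manifest,
            file.path(root, "synthetic_manifest.csv"), row.names = FALSE)
  if (!is.null(result$curation))
    jsonlite::write_json(
      list(retained = result$curation$retained,
           rejected = result$curation$rejected,
           thresholds = result$curation$thresholds),
      file.path(root, "curation_report.json"), auto_unbox = TRUE, digits = NA)
  write.csv(result$grid$runs, file.path(root, "grid_runs.csv"),
            row.names = FALSE)
  write.csv(result$grid$summary, file.path(root, "grid_summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(fid = result$fid$value, extractor = "pca-32"),
                       file.path(root, "fid.json"), auto_unbox = TRUE,
                       digits = NA)
  for (label in names(result$models))
    write.csv(result$models[[label]]$loss_log,
              file.path(root, paste0("ddpm_loss_", label, ".csv")),
              row.names = FALSE)
  invisible(root)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  originals:", length(x$original), " synthetic retained:",
      length(x$synthetic), "\n")
  cat("  overall feature-distribution distance:",
      round(x$fid$value, 3), "\n")
  print(x$grid$summary[, c("scenario", "task", "accuracy_mean",
                           "accuracy_sd")])
  invisible(x)
}
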