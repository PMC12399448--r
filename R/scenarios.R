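#' Collapse the 8-class labels to the binary task
#'
#' Maps every lesion class to `with_pathology`; `without_pathology` is kept.
#' Counts are conserved and the mapping is idempotent. A single-class result
#' (e.g. an all-healthy input) is allowed with a warning.
#'
#' @param dataset A [vf_dataset()].
#' @return A [vf_dataset()] with labels in
#'   `{without_pathology, with_pathology}`.
#' @export
make_binary_labels <- function(dataset) {
  images <- lapply(dataset$images, function(im) {
    if (!im$label %in% c(vf_labels(), "with_pathology"))
      stop("unknown label: ", im$label)
    if (im$label != "without_pathology") im$label <- "with_pathology"
    im
  })
  out <- vf_dataset(images)
  if (length(unique(out$manifest$label)) < 2 && length(out))
    warning("binary mapping produced a single-class dataset")
  out
}

#' Stratified two-way split
#'
#' Allocates `round-by-largest-remainder(fraction * n_c)` images of every
#' class to the first part; the split is disjoint, exhaustive, and
#' per-class proportions are within one image of `fraction`. A class with a
#' single image goes to the first part with a warning.
#'
#' @param dataset A [vf_dataset()].
#' @param fraction Fraction allocated to the first part, in (0, 1).
#' @param seed Integer seed controlling membership.
#' @return List of two [vf_dataset()] objects.
#' @export
stratified_split <- function(dataset, fraction, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  man <- dataset$manifest
  a_ids <- character(); b_ids <- character()
  with_seed(derive_seed(seed, "split"), {
    for (label in unique(man$label)) {
      ids <- man$id[man$label == label]
      n <- length(ids)
      if (n == 1) {
        warning("class '", label, "' has a single image; assigned to part A")
        a_ids <- c(a_ids, ids)
        next
      }
      k <- largest_remainder(fraction * n, n)
      pick <- sample(ids, k)
      a_ids <- c(a_ids, pick)
      b_ids <- c(b_ids, setdiff(ids, pick))
    }
  })
  list(subset_dataset(dataset, a_ids), subset_dataset(dataset, b_ids))
}

# Largest-remainder rounding of a single target x, bounded to [0, n].
largest_remainder <- function(x, n) {
  k <- floor(x)
  if (x - k >= 0.5) k <- k + 1
  min(max(k, 0), n)
}

#' Build one augmentation-scenario split
#'
#' The three scenarios of the emulated study plus its baseline:
#' * `synthetic_only` — train on all synthetic images, test on all originals;
#' * `mix10` / `mix50` — train on all synthetic images plus 10% / 50% of the
#'   originals (allocated per class by largest-remainder rounding), test on
#'   the remaining originals;
#' * `original_only_baseline` — stratified 80/20 train/validation over the
#'   originals only (no synthetic images).
#'
#' For the `binary` task labels are collapsed with [make_binary_labels()];
#' for `multiclass` only the seven lesion classes are used (healthy images
#' are excluded, as the multi-class task discriminates among pathologies).
#' Every emitted test image has provenance `original`, and train/test are
#' disjoint by id.
#'
#' @param original [vf_dataset()] of original-provenance images.
#' @param synthetic [vf_dataset()] of synthetic-provenance images (may be
#'   empty for the baseline).
#' @param scenario One of `synthetic_only`, `mix10`, `mix50`,
#'   `original_only_baseline`.
#' @param task `binary` or `multiclass`.
#' @param seed Integer seed controlling the original-image allocation.
#' @return Object of class `scenario_split` with fields `train`, `test`,
#'   `scenario`, `task`, `seed`.
#' @export
build_scenario <- function(original, synthetic = NULL,
                           scenario = c("synthetic_only", "mix10", "mix50",
                                        "original_only_baseline"),
                           task = c("binary", "multiclass"), seed = 1) {
  scenario <- match.arg(scenario)
  task <- match.arg(task)
  if (!all(original$manifest$provenance == "original"))
    stop("'original' must contain only provenance=original images")
  if (!is.null(synthetic) && length(synthetic) &&
      !all(synthetic$manifest$provenance == "synthetic"))
    stop("'synthetic' must contain only provenance=synthetic images")
  if (!is.null(synthetic) && length(synthetic) &&
      length(intersect(names(original$images), names(synthetic$images))))
    stop("original and synthetic datasets share ids")

  if (task == "multiclass") {
    keep_o <- original$manifest$id[original$manifest$label %in% pathology_labels()]
    original <- subset_dataset(original, keep_o)
    if (!is.null(synthetic) && length(synthetic)) {
      keep_s <- synthetic$manifest$id[synthetic$manifest$label %in% pathology_labels()]
      synthetic <- subset_dataset(synthetic, keep_s)
    }
  } else {
    original <- make_binary_labels(original)
    if (!is.null(synthetic) && length(synthetic))
      synthetic <- make_binary_labels(synthetic)
  }

  if (scenario == "original_only_baseline") {
    parts <- stratified_split(original, 0.8, seed = seed)
    train <- parts[[1]]; test <- parts[[2]]
  } else if (scenario == "synthetic_only") {
    if (is.null(synthetic) || length(synthetic) == 0)
      stop("scenario '", scenario, "' needs synthetic images")
    train <- synthetic; test <- original
  } else {
    if (is.null(synthetic) || length(synthetic) == 0)
      stop("scenario '", scenario, "' needs synthetic images")
    p <- if (scenario == "mix10") 0.10 else 0.50
    man <- original$manifest
    take <- character()
    with_seed(derive_seed(seed, "mix", scenario), {
      for (label in unique(man$label)) {
        ids <- man$id[man$label == label]
        k <- largest_remainder(p * length(ids), length(ids))
        if (k == 0)
          warning("class '", label, "' contributes no originals to the ",
                  scenario, " train set")
        if (k > 0) take <- c(take, sample(ids, k))
      }
    })
    train <- if (length(take))
      combine_datasets(synthetic, subset_dataset(original, take))
    else synthetic
    test <- subset_dataset(original, setdiff(man$id, take))
  }
  structure(list(train = train, test = test, scenario = scenario,
                 task = task, seed = as.integer(seed)),
            class = "scenario_split")
}

#' @export
print.scenario_split <- function(x, ...) {
  cat(sprintf("<scenario_split %s/%s: train %d (%d original), test %d>\n",
              x$scenario, x$task, length(x$train),
              sum(x$train$manifest$provenance == "original"), length(x$test)))
  invisible(x)
}

#' Run the repeated augmentation-experiment grid
#'
#' For every (scenario, task, repeat) combination, builds the split with a
#' derived seed, trains a classifier, evaluates it on the split's test set,
#' and aggregates per-metric mean and sample (n-1) standard deviation across
#' repeats. Binary metrics use `with_pathology` as the positive class;
#' multi-class metrics are macro-averaged one-vs-rest.
#'
#' @param original,synthetic [vf_dataset()] objects (see [build_scenario()]).
#' @param scenarios Character vector of scenario names.
#' @param tasks Character vector of task names.
#' @param repeats Number of repeats per cell (>= 2 for a meaningful SD).
#' @param seed Global seed; each run uses a derived seed.
#' @param config Base [classifier_config()]; its seed is re-derived per run.
#' @return List of class `experiment_grid`: `runs` (per-run metric rows),
#'   `summary` (mean ± SD rows), `reports` (per-run `vf_metrics` objects).
#' @export
run_experiment_grid <- function(original, synthetic,
                                scenarios = c("synthetic_only", "mix10",
                                              "mix50"),
                                tasks = c("binary", "multiclass"),
                                repeats = 3, seed = 1,
                                config = classifier_config()) {
  stopifnot(repeats >= 1)
  runs <- list(); reports <- list()
  for (task in tasks) for (scenario in scenarios) for (r in seq_len(repeats)) {
    rs <- derive_seed(seed, scenario, task, r)
    split <- build_scenario(original, synthetic, scenario, task, seed = rs)
    cfg <- config; cfg$seed <- derive_seed(rs, "clf")
    model <- train_classifier(split, cfg)
    rep_m <- evaluate_split(model, split)
    key <- sprintf("%s.%s.r%d", scenario, task, r)
    reports[[key]] <- rep_m
    runs[[key]] <- data.frame(scenario = scenario, task = task, repeat_ = r,
                              seed = rs, t(unlist(rep_m$overall)))
  }
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL
  metric_cols <- setdiff(names(runs), c("scenario", "task", "repeat_", "seed"))
  summ <- do.call(rbind, lapply(split(runs, list(runs$scenario, runs$task),
                                      drop = TRUE), function(g) {
    out <- data.frame(scenario = g$scenario[1], task = g$task[1], n = nrow(g))
    for (mc in metric_cols) {
      out[[paste0(mc, "_mean")]] <- mean(g[[mc]])
      out[[paste0(mc, "_sd")]] <- if (nrow(g) > 1) stats::sd(g[[mc]]) else 0
    }
    out
  }))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ, reports = reports,
                 seed = seed),
            class = "experiment_grid")
}

#' Evaluate a trained classifier on a scenario's test set
#'
#' @param model A `vf_classifier`.
#' @param split The `scenario_split` it was trained on.
#' @return A `vf_metrics` report (binary or macro averaging per the task).
#' @export
evaluate_split <- function(model, split) {
  predicted <- predict_labels(model, split$test)
  cm <- confusion_matrix(split$test$manifest$label, predicted,
                         classes = model$classes)
  averaging <- if (split$task == "binary") "binary" else "macro"
  classification_metrics(cm, averaging = averaging)
}
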