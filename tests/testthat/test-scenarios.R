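ref16 <- toy_dataset(reference_distribution("original"), size = 16, seed = 77)

test_that("binary mapping conserves counts and is idempotent", {
  bin <- make_binary_labels(ref16)
  counts <- table(bin$manifest$label)
  expect_equal(unname(counts[["without_pathology"]]), 157L)
  expect_equal(unname(counts[["with_pathology"]]), 247L)
  expect_length(bin, 404)
  expect_identical(make_binary_labels(bin)$manifest, bin$manifest)
  healthy_only <- toy_dataset(c(without_pathology = 3), size = 16, seed = 1)
  expect_warning(make_binary_labels(healthy_only), "single-class")
})

test_that("stratified splits are exact, disjoint and exhaustive", {
  ds <- toy_dataset(c(nodule = 5, cyst = 5), size = 16, seed = 5)
  parts <- stratified_split(ds, 0.8, seed = 1)
  expect_equal(unname(dataset_counts(parts[[1]])[c("nodule", "cyst")]), c(4L, 4L))
  expect_equal(unname(dataset_counts(parts[[2]])[c("nodule", "cyst")]), c(1L, 1L))
  p2 <- stratified_split(ds, 0.8, seed = 1)
  expect_identical(names(parts[[1]]$images), names(p2[[1]]$images))
  p3 <- stratified_split(ds, 0.8, seed = 2)
  expect_false(identical(sort(names(parts[[1]]$images)),
                         sort(names(p3[[1]]$images))))
  expect_length(p3[[1]], 8)

  singleton <- toy_dataset(c(granuloma = 1, nodule = 4), size = 16, seed = 6)
  expect_warning(out <- stratified_split(singleton, 0.5, seed = 1),
                 "single image")
  expect_true("granuloma" %in% out[[1]]$manifest$label)
})

test_that("split sizes always sum to the dataset size", {
  set.seed(88)
  for (i in 1:25) {
    counts <- c(nodule = sample(2:9, 1), cyst = sample(2:9, 1),
                polyp = sample(2:9, 1))
    ds <- toy_dataset(counts, size = 16, seed = i)
    fr <- runif(1, 0.15, 0.85)
    parts <- stratified_split(ds, fr, seed = i)
    expect_equal(length(parts[[1]]) + length(parts[[2]]), sum(counts))
    expect_length(intersect(names(parts[[1]]$images),
                            names(parts[[2]]$images)), 0)
    # per-class allocation within one image of the target fraction
    for (cl in names(counts)) {
      got <- sum(parts[[1]]$manifest$label == cl)
      expect_lte(abs(got - fr * counts[[cl]]), 1)
    }
  }
})

test_that("mix scenarios allocate originals with exact complements", {
  orig <- toy_dataset(c(nodule = 60, cyst = 40), size = 16, seed = 7)
  synth_src <- toy_dataset(c(nodule = 10, cyst = 10), size = 16, seed = 8)
  synth <- vf_dataset(lapply(synth_src$images, function(im) {
    im$provenance <- "synthetic"; im$id <- paste0("s-", im$id); im
  }))
  s10 <- build_scenario(orig, synth, "mix10", "multiclass", seed = 1)
  expect_equal(sum(s10$train$manifest$provenance == "original"), 10)
  expect_length(s10$test, 90)
  s50 <- build_scenario(orig, synth, "mix50", "multiclass", seed = 1)
  expect_equal(sum(s50$train$manifest$provenance == "original"), 50)
  expect_length(s50$test, 50)
  toy2 <- toy_dataset(c(nodule = 2, cyst = 2), size = 16, seed = 9)
  s <- build_scenario(toy2, synth, "mix50", "multiclass", seed = 1)
  expect_equal(unname(dataset_counts(s$test)[c("nodule", "cyst")]), c(1L, 1L))
})

test_that("no identifier or provenance leaks from train into test", {
  man <- ref16$manifest
  orig <- subset_dataset(ref16, unlist(lapply(split(man$id, man$label),
                                              head, 15)))
  synth <- vf_dataset(lapply(
    orig$images[unlist(lapply(split(orig$manifest$id, orig$manifest$label),
                              head, 5))],
    function(im) {
      im$provenance <- "synthetic"; im$id <- paste0("s-", im$id); im
    }))
  for (scen in c("synthetic_only", "mix10", "mix50",
                 "original_only_baseline")) {
    for (task in c("binary", "multiclass")) {
      sp <- suppressWarnings(
        build_scenario(orig, synth, scen, task, seed = 3))
      expect_length(intersect(names(sp$train$images), names(sp$test$images)), 0)
      expect_true(all(sp$test$manifest$provenance == "original"))
      if (scen %in% c("mix10", "mix50"))
        expect_equal(sum(sp$train$manifest$provenance == "original") +
                     length(sp$test),
                     if (task == "binary") length(orig) else
                       sum(orig$manifest$label %in% pathology_labels()))
    }
  }
})

test_that("the full-scale synthetic-only scenario matches the study sizes", {
  synth <- vf_dataset(lapply(
    toy_dataset(reference_distribution("synthetic") , size = 16,
                seed = 99)$images,
    function(im) { im$provenance <- "synthetic"; im$id <- paste0("s-", im$id); im }))
  sp <- build_scenario(ref16, synth, "synthetic_only", "binary", seed = 1)
  expect_length(sp$train, 4180)
  expect_length(sp$test, 404)
})

test_that("an impossible per-class allocation warns and contributes zero", {
  orig <- toy_dataset(c(granuloma = 4, nodule = 40), size = 16, seed = 10)
  synth <- vf_dataset(lapply(orig$images[1:10], function(im) {
    im$provenance <- "synthetic"; im$id <- paste0("s-", im$id); im
  }))
  expect_warning(sp <- build_scenario(orig, synth, "mix10", "multiclass",
                                      seed = 1),
                 "contributes no originals")
  expect_equal(sum(sp$train$manifest$label == "granuloma" &
                   sp$train$manifest$provenance == "original"), 0)
})

test_that("the experiment grid aggregates what its runs report", {
  orig <- toy_dataset(c(without_pathology = 14, nodule = 10, cyst = 10),
                      size = 16, seed = 12)
  synth <- vf_dataset(lapply(
    toy_dataset(c(without_pathology = 8, nodule = 8, cyst = 8), size = 16,
                seed = 13)$images,
    function(im) { im$provenance <- "synthetic"; im$id <- paste0("s-", im$id); im }))
  grid <- run_experiment_grid(orig, synth,
                              scenarios = c("original_only_baseline", "mix50"),
                              tasks = "binary", repeats = 2, seed = 5,
                              config = classifier_config(epochs = 2))
  expect_equal(nrow(grid$summary), 2)
  expect_equal(nrow(grid$runs), 4)
  # aggregation identity: summary mean/sd recomputable from the runs
  for (scen in c("original_only_baseline", "mix50")) {
    rows <- grid$runs[grid$runs$scenario == scen, ]
    srow <- grid$summary[grid$summary$scenario == scen, ]
    expect_equal(srow$accuracy_mean, mean(rows$accuracy))
    expect_equal(srow$accuracy_sd, sd(rows$accuracy))
  }
  # derived seeds differ across repeats
  expect_length(unique(grid$runs$seed), 4)
})
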