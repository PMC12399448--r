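#!/usr/bin/env Rscript
# Stage 1 — emulate the clinical collection.
#
# Generates the phantom laryngoscopy dataset with the reference imbalanced
# class distribution (404 images; largest class 157, smallest 4, ratio
# 39.25), writes it to results/phantoms/ with its manifest, and records
# per-class counts and sharpness statistics. Every downstream stage starts
# from this directory.

library(vfddpm)

seed <- 20250925
size <- 24
out <- "results"
dir.create(out, showWarnings = FALSE)

message("generating ", sum(reference_distribution("original")),
        " phantom originals at ", size, "x", size, " (seed ", seed, ")")
orig <- generate_dataset(reference_distribution("original"),
                         seed = derive_seed(seed, "orig"), image_size = size)
write_image_dataset(orig, file.path(out, "phantoms"))

counts <- dataset_counts(orig, vf_labels())
sharp <- vapply(orig$images, sharpness_score, 0)
stats <- data.frame(
  label = names(counts), count = as.integer(counts),
  sharpness_median = vapply(names(counts), function(l)
    median(sharp[orig$manifest$label == l]), 0))
write.csv(stats, file.path(out, "phantom_stats.csv"), row.names = FALSE)

message("per-class counts:")
print(counts)
message(sprintf("imbalance ratio %.2f; total %d; wrote %s",
                max(counts) / min(counts), length(orig),
                file.path(out, "phantoms")))
message("every image carries a ground-truth lesion mask; ",
        sum(vapply(orig$images, function(im) sum(im$mask) > 0, TRUE)),
        " images have non-empty masks (the 247 pathological cases)")
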