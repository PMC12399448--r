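#!/usr/bin/env Rscript
# Stage 3 — per-class diffusion models, synthetic images, curation.
#
# Reads the phantom originals from stage 1, trains one unconditional DDPM
# per class, samples synthetic images at a quarter of the reference
# synthetic counts, and curates them with the automated stand-in for expert
# review (sharpness + fold-structure plausibility). Writes the retained
# synthetic dataset, per-class loss logs, and the curation report.

library(vfddpm)

seed <- 20250925
out <- "results"
orig <- read_image_dataset(file.path(out, "phantoms"))
message("loaded ", length(orig), " originals")

synth_counts <- round(reference_distribution("synthetic") * 0.25)
message("training one DDPM per class; synthetic targets: ",
        paste(names(synth_counts), synth_counts, sep = "=", collapse = ", "))
gen <- generate_synthetic_dataset(orig, synth_counts,
                                  seed = derive_seed(seed, "gen"),
                                  verbose = TRUE)
for (label in names(gen$loss_logs))
  write.csv(gen$loss_logs[[label]],
            file.path(out, paste0("ddpm_loss_", label, ".csv")),
            row.names = FALSE)

cur <- curate(gen$synthetic, reference = orig)
message(sprintf("curation: retained %d / %d (%.1f%%)",
                length(cur$report$retained), length(gen$synthetic),
                100 * length(cur$report$retained) / length(gen$synthetic)))
if (nrow(cur$report$rejected)) print(table(cur$report$rejected$reason))

write_image_dataset(cur$dataset, file.path(out, "synthetic"))
jsonlite::write_json(list(retained = cur$report$retained,
                          rejected = cur$report$rejected,
                          thresholds = cur$report$thresholds),
                     file.path(out, "curation_report.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", file.path(out, "synthetic"), " and curation_report.json")
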