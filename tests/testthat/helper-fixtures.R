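# Shared fixtures, all generated in code at test time.

# Small labeled phantom dataset with the given per-class counts.
toy_dataset <- function(counts, size = 24, seed = 1) {
  generate_dataset(class_distribution(counts), seed = seed, image_size = size)
}

# Denoiser stand-ins honoring the predict contract (see predict_noise).
oracle_denoiser <- function(eps) list(predict = function(xt, t) eps)
zero_denoiser <- function() list(predict = function(xt, t) xt * 0)

# Add seeded Gaussian pixel noise to every image of a dataset (clamped).
corrupt_dataset <- function(dataset, sd, seed = 1) {
  images <- lapply(dataset$images, function(im) {
    set.seed(derive_seed(seed, im$id))
    im$pixels <- round(pmin(pmax(im$pixels +
      array(rnorm(length(im$pixels), 0, sd), dim = dim(im$pixels)), 0), 255))
    im
  })
  vf_dataset(images)
}
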