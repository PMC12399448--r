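test_that("phantom generation is deterministic and conserves counts", {
  counts <- c(nodule = 5, cyst = 3, without_pathology = 4)
  a <- generate_dataset(counts, seed = 3, image_size = 24)
  b <- generate_dataset(counts, seed = 3, image_size = 24)
  expect_identical(a, b)
  expect_equal(unname(dataset_counts(a)[c("without_pathology", "nodule", "cyst")]),
               c(4L, 5L, 3L))
  expect_length(generate_dataset(c(nodule = 0), seed = 1, image_size = 24), 0)
  only <- generate_dataset(c(nodule = 5), seed = 2, image_size = 24)
  expect_length(only, 5)
  expect_true(all(only$manifest$label == "nodule"))
  c_diff <- generate_dataset(counts, seed = 4, image_size = 24)
  expect_false(identical(a$images[[1]]$pixels, c_diff$images[[1]]$pixels))
})

test_that("the reference distribution reproduces the study's imbalance", {
  orig <- reference_distribution("original")
  expect_equal(sum(orig), 404L)
  expect_equal(max(orig), 157L)
  expect_equal(min(orig), 4L)
  expect_equal(max(orig) / min(orig), 39.25)
  expect_lte(max(orig) / min(orig), 40)
  expect_equal(sum(reference_distribution("synthetic")), 4180L)
})

test_that("lesion masks follow the class archetypes", {
  # no lesion -> empty mask
  healthy <- render_phantom("without_pathology", 7, size = 48)
  expect_equal(sum(healthy$mask), 0)

  # every lesion class marks at least one pixel, and the masked region's
  # appearance differs from a geometry-matched healthy render
  for (label in pathology_labels()) {
    im <- render_phantom(label, 3, size = 48)
    expect_gt(sum(im$mask), 0)
    style <- im$meta[c("theta_deg", "sep_a", "sep_p", "wf", "gain",
                       "mucosa", "fold_col", "side", "lesion_v")]
    ref <- render_phantom("without_pathology", 3, size = 48, style = style)
    sel <- array(im$mask, dim = dim(im$pixels))
    delta <- mean(abs(im$pixels[sel] - ref$pixels[sel]))
    expect_gt(delta, 5)
  }
})

test_that("nodules are mirror-symmetric about the glottal axis", {
  im <- render_phantom("nodule", 3, size = 64, style = list(theta_deg = 0))
  idx <- which(im$mask, arr.ind = TRUE)
  mid <- (64 + 1) / 2
  left <- idx[idx[, 2] < mid, , drop = FALSE]
  right <- idx[idx[, 2] > mid, , drop = FALSE]
  expect_gt(nrow(left), 0)
  expect_gt(nrow(right), 0)
  # reflect the right centroid and compare to the left centroid
  c_left <- colMeans(left)
  c_right <- colMeans(right)
  expect_lt(abs(c_left[1] - c_right[1]), 2)                 # same row
  expect_lt(abs((mid - c_left[2]) - (c_right[2] - mid)), 2) # mirrored column
})

test_that("keratosis renders as a whitish patch brighter than the mucosa", {
  im <- render_phantom("keratosis", 11, size = 48)
  inside <- mean(im$pixels[array(im$mask, dim = dim(im$pixels))])
  outside <- mean(im$pixels[array(!im$mask, dim = dim(im$pixels))])
  expect_gt(inside, outside)
})

test_that("unknown labels and degrade modes are rejected", {
  expect_error(render_phantom("tumor", 1), "unknown label")
  expect_error(generate_dataset(c(tumor = 3), 1), "unknown class label")
  im <- render_phantom("cyst", 1, size = 24)
  expect_error(degrade(im, "sharpen"), "arg")
  expect_error(degrade(im, "blur", severity = 0))
})

test_that("blur degradation approaches identity as severity vanishes", {
  im <- render_phantom("polyp", 5, size = 32)
  d_small <- max(abs(degrade(im, "blur", 0.2)$pixels - im$pixels))
  d_large <- max(abs(degrade(im, "blur", 2)$pixels - im$pixels))
  expect_lt(d_small, d_large)
  expect_lt(d_small, 10)
  expect_equal(max(abs(degrade(im, "blur", 0.01)$pixels - im$pixels)), 0)
})

test_that("degradation preserves label and lineage", {
  im <- render_phantom("granuloma", 2, size = 24)
  for (mode in c("blur", "remove_folds", "triplicate_fold")) {
    dg <- degrade(im, mode, 1)
    expect_equal(dg$label, im$label)
    expect_equal(dg$meta$degraded$parent, im$id)
    expect_equal(dim(dg$pixels), dim(im$pixels))
    expect_true(all(dg$pixels >= 0 & dg$pixels <= 255))
  }
})
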