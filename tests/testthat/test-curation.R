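test_that("sharpness is zero for flat images and offset-invariant", {
  flat <- vf_image(array(120, dim = c(16, 16, 3)), "without_pathology",
                   id = "flat")
  expect_equal(sharpness_score(flat), 0)
  set.seed(31)
  px <- array(runif(16 * 16 * 3, 40, 200), dim = c(16, 16, 3))
  im <- vf_image(px, "cyst", id = "rand")
  shifted <- vf_image(px + 30, "cyst", id = "rand2")
  expect_equal(sharpness_score(shifted), sharpness_score(im))
})

test_that("sharpness decreases monotonically with blur severity", {
  im <- render_phantom("keratosis", 6, size = 48)
  scores <- vapply(c(1, 2, 4, 8),
                   function(sv) sharpness_score(degrade(im, "blur", sv)), 0)
  expect_true(all(diff(scores) < 0))
  expect_lt(scores[1], sharpness_score(im))
})

test_that("the band detector sees two folds in pristine views", {
  for (label in c("without_pathology", "nodule", "keratosis",
                  "reinkes_edema", "sulcus_vocalis")) {
    sc <- structure_score(render_phantom(label, 8, size = 64))
    expect_equal(sc$fold_band_count, 2L)
    expect_true(sc$plausible)
  }
})

test_that("the band detector flags missing and triplicated folds", {
  for (label in c("without_pathology", "cyst", "granuloma")) {
    im <- render_phantom(label, 5, size = 64)
    rf <- structure_score(degrade(im, "remove_folds"))
    expect_equal(rf$fold_band_count, 0L)
    expect_false(rf$plausible)
    tf <- structure_score(degrade(im, "triplicate_fold"))
    expect_gte(tf$fold_band_count, 3L)
    expect_false(tf$plausible)
  }
})

test_that("curation retains exactly the clean images of a mixed batch", {
  pristine <- toy_dataset(c(nodule = 5, polyp = 5), size = 64, seed = 21)
  broken <- vf_dataset(lapply(pristine$images[1:5], function(im)
    degrade(im, "remove_folds")))
  mixed <- combine_datasets(pristine, broken)
  out <- curate(mixed, reference = pristine)
  expect_length(out$dataset, 10)
  expect_setequal(out$report$retained, names(pristine$images))
  # fold removal degrades both criteria; either rejection ground is valid
  expect_true(all(out$report$rejected$reason %in%
                  c("wrong_fold_count", "blurry")))
  # partition invariant
  expect_setequal(c(out$report$retained, out$report$rejected$id),
                  names(mixed$images))
  expect_length(intersect(out$report$retained, out$report$rejected$id), 0)
})

test_that("curation is deterministic and monotone in the threshold", {
  ds <- toy_dataset(c(cyst = 6), size = 64, seed = 22)
  a <- curate(ds)
  b <- curate(ds)
  expect_identical(a$report, b$report)
  scores <- sort(unname(vapply(ds$images, sharpness_score, 0)))
  retained <- vapply(c(0, scores[3], scores[5], Inf), function(thr)
    length(curate(ds, sharpness_threshold = thr)$dataset), 0L)
  expect_true(all(diff(retained) <= 0))
  expect_equal(unname(retained[length(retained)]), 0L)
})

test_that("empty input curates to an empty report, not an error", {
  out <- curate(vf_dataset(list()))
  expect_length(out$dataset, 0)
  expect_length(out$report$retained, 0)
  expect_equal(nrow(out$report$rejected), 0)
})

test_that("degenerate pixel content is flagged out of range", {
  im <- render_phantom("nodule", 2, size = 32)
  im$pixels[1, 1, 1] <- NA
  ds <- vf_dataset(list(im))
  out <- curate(ds, sharpness_threshold = 0)
  expect_equal(out$report$rejected$reason, "out_of_range")
})
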