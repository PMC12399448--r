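test_that("confusion matrices count actual-by-predicted pairs", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"),
                         classes = c("A", "B"))
  expect_equal(unclass(cm),
               matrix(c(1L, 0L, 1L, 1L), 2,
                      dimnames = list(actual = c("A", "B"),
                                      predicted = c("A", "B"))))
  perfect <- confusion_matrix(rep(c("A", "B"), c(3, 2)),
                              rep(c("A", "B"), c(3, 2)))
  expect_equal(diag(perfect), c(A = 3L, B = 2L))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0L)
  expect_error(confusion_matrix(c("A"), c("A", "B")), "equal length")
  expect_error(confusion_matrix(c("A"), c("C"), classes = c("A", "B")),
               "unknown label")
})

test_that("totals are conserved over random label pairs", {
  set.seed(61)
  classes <- c("A", "B", "C", "D")
  for (i in 1:40) {
    n <- sample(5:60, 1)
    a <- sample(classes, n, replace = TRUE)
    p <- sample(classes, n, replace = TRUE)
    cm <- confusion_matrix(a, p, classes)
    expect_equal(sum(cm), n)
    expect_equal(unname(rowSums(cm)),
                 unname(vapply(classes, function(cl) sum(a == cl), 0)))
  }
})

test_that("binary metrics match direct hand evaluation", {
  # TP=50 FP=10 FN=5 TN=35 with 'with_pathology' positive
  cm <- confusion_matrix(
    rep(c("with_pathology", "without_pathology"), c(55, 45)),
    c(rep("with_pathology", 50), rep("without_pathology", 5),
      rep("with_pathology", 10), rep("without_pathology", 35)),
    classes = c("with_pathology", "without_pathology"))
  m <- classification_metrics(cm, "binary")$overall
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 50 / 60)
  expect_equal(m$sensitivity, 50 / 55)
  expect_equal(m$specificity, 35 / 45)
  expect_equal(m$f1, 2 * (50 / 60) * (50 / 55) / (50 / 60 + 50 / 55))
  expect_equal(m$f1, 0.8696, tolerance = 1e-4)
})

test_that("degenerate predictors hit the metric boundaries", {
  classes <- c("with_pathology", "without_pathology")
  perfect <- confusion_matrix(rep(classes, c(6, 4)), rep(classes, c(6, 4)),
                              classes)
  mp <- classification_metrics(perfect, "binary")$overall
  expect_equal(unlist(mp), c(accuracy = 1, precision = 1, sensitivity = 1,
                             specificity = 1, f1 = 1))
  always_pos <- confusion_matrix(rep(classes, c(6, 4)),
                                 rep("with_pathology", 10), classes)
  ma <- classification_metrics(always_pos, "binary")
  expect_equal(ma$overall$sensitivity, 1)
  expect_equal(ma$overall$specificity, 0)
  expect_true(ma$zero_denominator)
  expect_error(classification_metrics(confusion_matrix(character(0),
                                                       character(0),
                                                       classes)),
               "empty")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(62)
  classes <- c("a", "b", "c")
  for (i in 1:30) {
    n <- sample(20:80, 1)
    a <- sample(classes, n, replace = TRUE)
    p <- sample(classes, n, replace = TRUE)
    cm <- confusion_matrix(a, p, classes)
    m <- classification_metrics(cm, "macro")
    # accuracy is the trace identity
    expect_equal(m$overall$accuracy, sum(diag(cm)) / sum(cm))
    # per-class F1 is the harmonic mean of precision and sensitivity
    pc <- m$per_class
    ok <- pc$precision + pc$sensitivity > 0
    expect_equal(pc$f1[ok],
                 (2 * pc$precision * pc$sensitivity /
                    (pc$precision + pc$sensitivity))[ok],
                 tolerance = 1e-12)
    # F1 lies between min and max of precision and sensitivity
    expect_true(all(pc$f1 <= pmax(pc$precision, pc$sensitivity) + 1e-12))
    expect_true(all(pc$f1 >= pmin(pc$precision, pc$sensitivity) - 1e-12))
    # macro metrics are invariant to class relabeling
    perm <- c("c", "a", "b")
    cm2 <- confusion_matrix(perm[match(a, classes)], perm[match(p, classes)],
                            classes)
    m2 <- classification_metrics(cm2, "macro")
    expect_equal(m2$overall, m$overall)
  }
})

test_that("weighted averaging weights by class support", {
  a <- rep(c("a", "b"), c(9, 1))
  p <- c(rep("a", 8), "b", "a")
  cm <- confusion_matrix(a, p, c("a", "b"))
  mw <- classification_metrics(cm, "weighted")
  mm <- classification_metrics(cm, "macro")
  pc <- mm$per_class
  expect_equal(mw$overall$sensitivity,
               sum(pc$support / sum(pc$support) * pc$sensitivity))
  expect_false(isTRUE(all.equal(mw$overall$sensitivity,
                                mm$overall$sensitivity)))
})

test_that("run aggregation reports sample mean and n-1 deviation", {
  mk <- function(acc) {
    cm <- confusion_matrix(c("a", "b"), c("a", "b"), c("a", "b"))
    r <- classification_metrics(cm, "macro")
    r$overall <- lapply(r$overall, function(x) acc)
    r
  }
  agg <- aggregate_runs(list(mk(0.6), mk(0.8)))
  expect_equal(agg$mean[agg$metric == "accuracy"], 0.7)
  expect_equal(agg$sd[agg$metric == "accuracy"], sd(c(0.6, 0.8)))
  expect_equal(agg$sd[agg$metric == "accuracy"], 0.1414, tolerance = 1e-3)
  one <- aggregate_runs(list(mk(0.5)))
  expect_equal(one$sd, rep(0, 5))
  expect_equal(one$n, rep(1L, 5))
  same <- aggregate_runs(list(mk(0.4), mk(0.4), mk(0.4)))
  expect_equal(same$mean[1], 0.4)
  expect_equal(same$sd[1], 0)
  broken <- mk(0.5)
  broken$overall$extra <- 1
  expect_error(aggregate_runs(list(mk(0.5), broken)), "heterogeneous")
})
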