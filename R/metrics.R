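#' Confusion matrix
#'
#' `K x K` integer counts with rows = actual class and columns = predicted
#' class.
#'
#' @param actual,predicted Equal-length label vectors.
#' @param classes Class vocabulary (defaults to the sorted union).
#' @return Matrix of class `vf_confusion`.
#' @export
confusion_matrix <- function(actual, predicted, classes = NULL) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  classes <- classes %||% sort(union(actual, predicted))
  bad <- setdiff(union(actual, predicted), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(actual, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(actual = classes, predicted = classes))
  structure(cm, class = c("vf_confusion", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy, precision (positive predictive value), sensitivity
#' (recall), specificity, and F1 (harmonic mean of precision and
#' sensitivity):
#' \deqn{\mathrm{Acc} = \frac{TP+TN}{TP+FP+FN+TN},\quad
#'       \mathrm{Prec} = \frac{TP}{TP+FP},\quad
#'       \mathrm{Sens} = \frac{TP}{TP+FN},}
#' \deqn{\mathrm{Spec} = \frac{TN}{TN+FP},\quad
#'       F_1 = 2\,\frac{\mathrm{Prec}\cdot\mathrm{Sens}}
#'                     {\mathrm{Prec}+\mathrm{Sens}}.}
#'
#' `binary` averaging computes the five quantities directly with `positive`
#' as the positive class; `macro` and `weighted` compute them one-vs-rest
#' per class and average (unweighted, or weighted by class support). A
#' zero denominator yields 0 for that quantity and sets the
#' `zero_denominator` flag.
#'
#' @param cm A [confusion_matrix()].
#' @param averaging `"binary"`, `"macro"`, or `"weighted"`.
#' @param positive Positive class for binary averaging.
#' @return Object of class `vf_metrics`: `overall` (named list of the five
#'   metrics), `per_class` (data frame), `averaging`, `cm`, flags.
#' @export
classification_metrics <- function(cm,
                                   averaging = c("macro", "weighted",
                                                 "binary"),
                                   positive = "with_pathology") {
  averaging <- match.arg(averaging)
  if (sum(cm) == 0) stop("confusion matrix is empty")
  classes <- rownames(cm)
  total <- sum(cm)
  accuracy <- sum(diag(cm)) / total
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  zero_flag <- FALSE
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    i <- match(cl, classes)
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- total - tp - fp - fn
    if ((tp + fp) == 0 || (tp + fn) == 0 || (tn + fp) == 0)
      zero_flag <<- TRUE
    prec <- safe_div(tp, tp + fp)
    sens <- safe_div(tp, tp + fn)
    spec <- safe_div(tn, tn + fp)
    f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    data.frame(class = cl, support = tp + fn, precision = prec,
               sensitivity = sens, specificity = spec, f1 = f1)
  }))
  if (averaging == "binary") {
    if (length(classes) != 2)
      stop("binary averaging needs a 2x2 confusion matrix")
    if (!positive %in% classes)
      stop("positive class '", positive, "' not among matrix classes")
    row <- per_class[per_class$class == positive, ]
    overall <- list(accuracy = accuracy, precision = row$precision,
                    sensitivity = row$sensitivity,
                    specificity = row$specificity, f1 = row$f1)
  } else {
    w <- if (averaging == "macro") rep(1 / nrow(per_class), nrow(per_class))
         else per_class$support / sum(per_class$support)
    overall <- list(accuracy = accuracy,
                    precision = sum(w * per_class$precision),
                    sensitivity = sum(w * per_class$sensitivity),
                    specificity = sum(w * per_class$specificity),
                    f1 = sum(w * per_class$f1))
  }
  structure(list(overall = overall, per_class = per_class,
                 averaging = averaging, positive = positive, cm = cm,
                 zero_denominator = zero_flag),
            class = "vf_metrics")
}

#' @export
print.vf_metrics <- function(x, ...) {
  cat(sprintf("<vf_metrics (%s averaging)>\n", x$averaging))
  print(round(unlist(x$overall), 4))
  invisible(x)
}

#' Aggregate repeated metric reports into mean ± SD rows
#'
#' @param reports List of `vf_metrics` objects with identical metric sets.
#' @return Data frame with one row per metric: `metric`, `mean`, `sd`
#'   (sample, n-1; 0 when `n = 1`), `n`.
#' @export
aggregate_runs <- function(reports) {
  stopifnot(length(reports) >= 1)
  mats <- lapply(reports, function(r) unlist(r$overall))
  nm <- names(mats[[1]])
  if (!all(vapply(mats, function(m) identical(names(m), nm), TRUE)))
    stop("reports have heterogeneous metric sets")
  M <- do.call(rbind, mats)
  data.frame(metric = nm,
             mean = colMeans(M),
             sd = if (nrow(M) > 1) apply(M, 2, stats::sd) else rep(0, ncol(M)),
             n = nrow(M), row.names = NULL)
}
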