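#' Configuration for classifier training
#'
#' Defaults follow the emulated study's protocol: batch size 16, learning
#' rate 1e-4 with Adam, integer-label cross-entropy, 20 epochs, stratified
#' 80/20 train/validation, and no further hyperparameter tuning. The desk
#' backbone is a two-hidden-layer perceptron on standardized flattened
#' pixels; descriptors for the published 16- and 50-layer convolutional
#' backbones are accepted for provenance but are not trainable here.
#'
#' @param batch_size Minibatch size (study protocol: 16).
#' @param lr Adam learning rate (study protocol: 1e-4).
#' @param epochs Training epochs (study protocol: 20).
#' @param val_fraction Stratified validation fraction used when a split
#'   provides no held-out set (study protocol: 0.2).
#' @param hidden Hidden-layer widths of the desk backbone.
#' @param backbone Descriptor string recorded in the output.
#' @param warm_start Optional trained `vf_classifier` whose parameters
#'   initialize this run (the study's "pre-trained" condition); `NULL` means
#'   random initialization (the "untrained" condition).
#' @param seed Integer seed.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(batch_size = 16, lr = 1e-4, epochs = 20,
                              val_fraction = 0.2, hidden = c(64, 32),
                              backbone = "desk-mlp", warm_start = NULL,
                              seed = 1) {
  stopifnot(batch_size >= 1, lr > 0, epochs >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(batch_size = batch_size, lr = lr, epochs = epochs,
                 val_fraction = val_fraction, hidden = hidden,
                 backbone = backbone, warm_start = warm_start,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Train an image classifier on a scenario split
#'
#' Trains the desk backbone with minibatch Adam on integer-label
#' cross-entropy. Pixels are flattened, scaled to `[0, 1]`, and standardized
#' per feature using training-set statistics (stored in the model). The
#' per-epoch history records training loss/accuracy and accuracy on the
#' split's held-out set. Deterministic given the config seed; a
#' `warm_start` model replaces random initialization.
#'
#' @param split A [build_scenario()] split (fields `train`, `test`), or a
#'   bare [vf_dataset()] (an internal stratified `val_fraction` split is then
#'   carved out for monitoring).
#' @param config A [classifier_config()].
#' @return A `vf_classifier` with `history` (per-epoch data frame), `classes`,
#'   `config`, and standardization state.
#' @export
train_classifier <- function(split, config = classifier_config()) {
  if (inherits(split, "vf_dataset")) {
    parts <- stratified_split(split, 1 - config$val_fraction,
                              seed = derive_seed(config$seed, "val"))
    split <- list(train = parts[[1]], test = parts[[2]],
                  scenario = "ad_hoc", task = "ad_hoc")
  }
  train <- split$train
  if (length(train) == 0) stop("train set is empty")
  classes <- sort(unique(train$manifest$label))
  if (length(classes) < 2) stop("train set has a single class; nothing to learn")

  X <- dataset_matrix(train, rescale = FALSE) / 255
  y <- match(train$manifest$label, classes)
  Xte <- NULL
  if (length(split$test)) {
    Xte <- dataset_matrix(split$test, rescale = FALSE) / 255
    yte <- match(split$test$manifest$label, classes)
    if (anyNA(yte)) stop("test set contains labels unseen in training")
  }
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg < 1e-6] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sg, "/")
  if (!is.null(Xte)) Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")

  with_seed(config$seed, {
    net <- mlp_init(c(ncol(X), config$hidden, length(classes)))
    if (!is.null(config$warm_start)) {
      ws <- config$warm_start
      if (!identical(ws$net$dims, net$dims))
        stop("warm-start backbone dimensions do not match")
      net$params <- ws$net$params
    }
    opt <- adam_init(net$params)
    n <- nrow(X)
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       accuracy = numeric(), val_accuracy = numeric())
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        fw <- mlp_forward(net, X[idx, , drop = FALSE], keep_cache = TRUE)
        P <- softmax_rows(fw$out)
        losses <- c(losses, -mean(log(pmax(P[cbind(seq_along(idx), y[idx])], 1e-12))))
        dO <- P
        dO[cbind(seq_along(idx), y[idx])] <- dO[cbind(seq_along(idx), y[idx])] - 1
        grads <- mlp_backward(net, fw$cache, dO / length(idx))
        st <- adam_step(net$params, grads, opt, config$lr)
        net$params <- st$params; opt <- st$state
      }
      pred <- max.col(mlp_forward(net, X))
      val_acc <- if (is.null(Xte)) NA_real_ else
        mean(max.col(mlp_forward(net, Xte)) == yte)
      hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                     accuracy = mean(pred == y),
                                     val_accuracy = val_acc))
    }
    structure(list(net = net, classes = classes, mu = mu, sigma = sg,
                   config = config, history = hist,
                   scenario = split$scenario, task = split$task),
              class = "vf_classifier")
  })
}

#' Predicted class probabilities
#'
#' @param object A `vf_classifier`.
#' @param dataset A [vf_dataset()].
#' @param ... Unused.
#' @return `n x K` matrix of probabilities (rows sum to 1), columns named by
#'   class.
#' @export
predict.vf_classifier <- function(object, dataset, ...) {
  X <- dataset_matrix(dataset, rescale = FALSE) / 255
  X <- sweep(sweep(X, 2, object$mu), 2, object$sigma, "/")
  P <- softmax_rows(mlp_forward(object$net, X))
  colnames(P) <- object$classes
  P
}

#' Predicted labels
#'
#' @param model A `vf_classifier`.
#' @param dataset A [vf_dataset()].
#' @return Character vector of predicted labels.
#' @export
predict_labels <- function(model, dataset) {
  model$classes[max.col(predict(model, dataset))]
}
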