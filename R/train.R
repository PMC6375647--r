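#' Training configuration
#'
#' Adam with learning rate 1e-5, decay 0, beta1 0.9, beta2 0.999, batch
#' size 32 (16/64/128 perform comparably) and 50 epochs are the defaults
#' used for full-scale training; small synthetic experiments typically use
#' a larger learning rate and far fewer epochs.
#'
#' @param learning_rate,decay,beta1,beta2 Adam hyperparameters.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param standardize Per-channel input normalization computed on the
#'   training set and stored with the model: `"none"` (or `FALSE`, the
#'   default) leaves raw energies, `"scale"` divides each channel by its
#'   standard deviation (preserving the natural zero of empty voxels),
#'   `"zscore"` (or `TRUE`) subtracts the mean as well.
#' @param seed Integer seed controlling shuffling, dropout and
#'   initialization; recorded in outputs.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-5, decay = 0, beta1 = 0.9,
                         beta2 = 0.999, batch_size = 32, epochs = 50,
                         standardize = FALSE, seed = 1) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, decay >= 0)
  if (is.logical(standardize)) standardize <- if (standardize) "zscore" else "none"
  standardize <- match.arg(standardize, c("none", "scale", "zscore"))
  structure(list(learning_rate = learning_rate, decay = decay, beta1 = beta1,
                 beta2 = beta2, batch_size = batch_size, epochs = epochs,
                 standardize = standardize, seed = as.integer(seed)),
            class = "train_config")
}

#' @noRd
onehot <- function(i, k) { v <- numeric(k); v[i] <- 1; v }

#' @noRd
tensor_values <- function(x) if (inherits(x, "voxel_tensor")) x$values else x

#' Train the 3D CNN
#'
#' Minimizes categorical cross-entropy with Adam.  Dropout masks, shuffling
#' and initialization all draw from the seeded RNG, so identical seeds give
#' identical runs.
#'
#' @param model A `pocket_cnn` from [build_network()], or `NULL` to build
#'   one from `labels` and the first tensor's shape.
#' @param tensors List of `voxel_tensor` objects (or bare 4-d arrays).
#' @param labels Factor (or character) of class labels, one per tensor.
#' @param tcfg A [train_config()].
#' @param verbose Print per-epoch loss/accuracy.
#' @return The trained `pocket_cnn`, with `$log` (data frame epoch, loss,
#'   accuracy), `$tcfg`, `$class_levels` and any standardization statistics.
#' @export
train_network <- function(model, tensors, labels, tcfg = train_config(),
                          verbose = FALSE) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stopf("training requires at least 2 classes")
  if (length(tensors) != length(labels)) stopf("one label per tensor required")
  dims <- lapply(tensors, function(x) dim(tensor_values(x)))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stopf("all tensors must share one shape")

  set.seed(tcfg$seed)
  if (is.null(model)) {
    d <- dims[[1]]
    model <- build_network(network_config(input_side = d[1],
                                          input_channels = d[4],
                                          classes = nlevels(labels)))
  }
  if (model$cfg$classes != nlevels(labels))
    stopf("model has %d output classes but labels have %d levels",
          model$cfg$classes, nlevels(labels))

  if (tcfg$standardize != "none") {
    nc <- model$cfg$input_channels
    mu <- numeric(nc); m2 <- numeric(nc); nvox <- 0
    for (x in tensors) {
      v <- tensor_values(x)
      nvox <- nvox + prod(dim(v)[1:3])
      for (c_ in seq_len(nc)) {
        mu[c_] <- mu[c_] + sum(v[, , , c_])
        m2[c_] <- m2[c_] + sum(v[, , , c_]^2)
      }
    }
    mu <- mu / nvox
    sdv <- sqrt(pmax(m2 / nvox - mu^2, 0))
    sdv[sdv < 1e-12] <- 1
    if (tcfg$standardize == "scale") mu <- numeric(nc)
    model$standardize <- list(mu = mu, sd = sdv, mode = tcfg$standardize)
  }

  y <- as.integer(labels)
  k <- model$cfg$classes
  n <- length(tensors)
  adam <- list(m = lapply(model$params, function(p) p * 0),
               v = lapply(model$params, function(p) p * 0), t = 0)
  log <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())

  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    lr <- tcfg$learning_rate / (1 + tcfg$decay * (epoch - 1))
    tot_loss <- 0; tot_correct <- 0
    for (bs in seq(1, n, by = tcfg$batch_size)) {
      idx <- ord[bs:min(bs + tcfg$batch_size - 1, n)]
      gsum <- NULL
      for (i in idx) {
        fw <- network_forward(model, tensor_values(tensors[[i]]),
                              train = TRUE, cache = TRUE)
        tot_loss <- tot_loss - log(max(fw$probs[y[i]], 1e-12))
        tot_correct <- tot_correct + (which.max(fw$probs) == y[i])
        gl <- fw$probs - onehot(y[i], k)
        g <- network_backward(model, fw$cache, gl)
        gsum <- if (is.null(gsum)) g
                else Map(function(a, b) a + b, gsum, g)
      }
      gsum <- lapply(gsum, function(g) g / length(idx))
      adam$t <- adam$t + 1
      for (nm in names(model$params)) {
        adam$m[[nm]] <- tcfg$beta1 * adam$m[[nm]] + (1 - tcfg$beta1) * gsum[[nm]]
        adam$v[[nm]] <- tcfg$beta2 * adam$v[[nm]] + (1 - tcfg$beta2) * gsum[[nm]]^2
        mhat <- adam$m[[nm]] / (1 - tcfg$beta1^adam$t)
        vhat <- adam$v[[nm]] / (1 - tcfg$beta2^adam$t)
        model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = tot_loss / n,
                                 accuracy = tot_correct / n))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f acc %.3f", epoch, tot_loss / n,
                      tot_correct / n))
  }

  model$trained <- TRUE
  model$class_levels <- levels(labels)
  model$tcfg <- tcfg
  model$log <- log
  model
}

#' Class probabilities for voxel tensors
#'
#' @param model A trained `pocket_cnn`.
#' @param tensors A single `voxel_tensor`/array or a list of them.
#' @return A matrix (samples x classes) of softmax probabilities with an
#'   attribute `labels` holding the argmax class per sample.
#' @export
predict_network <- function(model, tensors) {
  if (inherits(tensors, "voxel_tensor") || is.array(tensors))
    tensors <- list(tensors)
  din <- c(rep(model$cfg$input_side, 3), model$cfg$input_channels)
  probs <- t(vapply(tensors, function(x) {
    v <- tensor_values(x)
    if (!identical(as.integer(dim(v)), as.integer(din)))
      stopf("tensor shape (%s) does not match model input (%s)",
            paste(dim(v), collapse = "x"), paste(din, collapse = "x"))
    network_forward(model, v)$probs
  }, numeric(model$cfg$classes)))
  colnames(probs) <- model$class_levels %||% seq_len(model$cfg$classes)
  lab <- colnames(probs)[max.col(probs, ties.method = "first")]
  attr(probs, "labels") <- lab
  probs
}

#' @noRd
stratified_folds <- function(labels, k) {
  labels <- as.factor(labels)
  if (k > length(labels)) stopf("k = %d exceeds sample count %d", k, length(labels))
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' @noRd
cv_report <- function(predictions, fold, labels, seed) {
  labels <- as.factor(labels)
  per_class <- lapply(levels(labels), function(cl) {
    sc <- predictions[, cl]
    truth <- labels == cl
    auc <- roc_auc(sc, truth)$auc
    cm <- confusion(labels, attr(predictions, "labels"), positive = cl)
    c(auc = auc, classification_metrics(cm)["ACC"])
  })
  metrics <- do.call(rbind, per_class)
  rownames(metrics) <- levels(labels)
  structure(list(
    predictions = data.frame(id = seq_along(labels), fold = fold,
                             true = labels,
                             predicted = attr(predictions, "labels"),
                             predictions, check.names = FALSE),
    fold_assignment = fold,
    metrics = metrics,
    accuracy = mean(attr(predictions, "labels") == as.character(labels)),
    seed = seed), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d samples, %d folds, pooled accuracy %.3f\n",
              nrow(x$predictions), length(unique(x$fold_assignment)),
              x$accuracy))
  print(round(x$metrics, 3))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Splits the samples into k class-stratified folds; each fold is predicted
#' by a model trained on the other k-1, so every sample is predicted exactly
#' once by a model that never saw it.  Pooled predictions feed the
#' one-vs-rest metrics (AUC per class from the class's softmax probability).
#'
#' @param tensors List of voxel tensors.
#' @param labels Class labels, one per tensor.
#' @param k Number of folds (default 5).
#' @param cfg A [network_config()] (channel count must match the tensors).
#' @param tcfg A [train_config()]; its seed fixes folds, initialization and
#'   dropout.
#' @param verbose Print fold progress.
#' @return A `cv_report`: pooled predictions, fold assignment, per-class
#'   AUC/ACC matrix, pooled accuracy, and the seed.
#' @export
crossvalidate <- function(tensors, labels, k = 5, cfg = NULL,
                          tcfg = train_config(), verbose = FALSE) {
  labels <- as.factor(labels)
  set.seed(tcfg$seed)
  fold <- stratified_folds(labels, k)
  probs <- matrix(NA_real_, length(labels), nlevels(labels),
                  dimnames = list(NULL, levels(labels)))
  pred_lab <- character(length(labels))
  for (f in seq_len(k)) {
    if (verbose) message(sprintf("fold %d/%d", f, k))
    tr <- which(fold != f); te <- which(fold == f)
    model <- if (is.null(cfg)) NULL else build_network(cfg)
    model <- train_network(model, tensors[tr], droplevels(labels[tr]),
                           tcfg = tcfg)
    p <- predict_network(model, tensors[te])
    probs[te, colnames(p)] <- p
    pred_lab[te] <- attr(p, "labels")
  }
  attr(probs, "labels") <- pred_lab
  cv_report(probs, fold, labels, tcfg$seed)
}

#' Leave-one-group-out cross-validation
#'
#' One round per annotated group (e.g. one enzyme-class group): the group is
#' held out entirely during training and then predicted, so generalization
#' is measured across groups rather than within them.
#'
#' @inheritParams crossvalidate
#' @param groups Group labels, one per tensor (at least 2 distinct groups).
#' @return A `cv_report`; `fold_assignment` holds the group of each sample.
#' @export
logo_crossvalidate <- function(tensors, labels, groups, cfg = NULL,
                               tcfg = train_config(), verbose = FALSE) {
  labels <- as.factor(labels)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stopf("leave-one-group-out needs at least 2 groups")
  set.seed(tcfg$seed)
  probs <- matrix(NA_real_, length(labels), nlevels(labels),
                  dimnames = list(NULL, levels(labels)))
  pred_lab <- character(length(labels))
  for (g in levels(groups)) {
    if (verbose) message(sprintf("holding out group %s", g))
    tr <- which(groups != g); te <- which(groups == g)
    model <- if (is.null(cfg)) NULL else build_network(cfg)
    model <- train_network(model, tensors[tr], droplevels(labels[tr]),
                           tcfg = tcfg)
    p <- predict_network(model, tensors[te])
    probs[te, colnames(p)] <- p
    pred_lab[te] <- attr(p, "labels")
  }
  attr(probs, "labels") <- pred_lab
  cv_report(probs, as.integer(groups), labels, tcfg$seed)
}
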