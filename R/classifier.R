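# Single-hidden-layer pattern-recognition network with softmax output,
# cross-entropy objective, full-batch gradient descent with momentum,
# early stopping on validation loss (patience) or a gradient-norm floor,
# plus the evaluation suite: confusion matrix, one-vs-rest metrics,
# ROC AUC and the error histogram.

#' Configure the neural-network classifier
#'
#' @param hidden_units Width of the single hidden layer (default 15).
#' @param max_epochs Maximum training epochs (default 100).
#' @param patience Consecutive epochs without validation improvement before
#'   stopping (default 6).
#' @param min_delta Smallest validation-loss decrease counted as an
#'   improvement (default 1e-6).
#' @param gradient_floor Stop when the gradient norm falls below this
#'   (default 1e-5).
#' @param learning_rate Fixed step size of full-batch gradient descent
#'   (default 0.2).
#' @param momentum Momentum coefficient (default 0.9).
#' @param seed Seed for weight initialisation.
#' @return An `mlp_config`.
#' @export
mlp_config <- function(hidden_units = 15L, max_epochs = 100L, patience = 6L,
                       min_delta = 1e-6, gradient_floor = 1e-5,
                       learning_rate = 0.2, momentum = 0.9, seed = 1L) {
  stopifnot(hidden_units >= 1, max_epochs >= 1, patience >= 1,
            gradient_floor > 0, learning_rate > 0,
            momentum >= 0, momentum < 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 gradient_floor = gradient_floor,
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' One-hot encode labels
#' @param y Factor of labels.
#' @param classes Class order (defaults to `levels(y)`).
#' @return N x K 0/1 matrix.
#' @keywords internal
one_hot <- function(y, classes = levels(y)) {
  y <- factor(y, levels = classes)
  M <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  M[cbind(seq_along(y), as.integer(y))] <- 1
  M
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

mlp_forward <- function(W1, b1, W2, b2, X) {
  H <- tanh(sweep(X %*% W1, 2, b1, "+"))
  P <- softmax(sweep(H %*% W2, 2, b2, "+"))
  list(H = H, P = P)
}

cross_entropy <- function(P, T) {
  -mean(rowSums(T * log(pmax(P, 1e-12))))
}

#' Train the neural-network classifier
#'
#' Inputs are z-scored with training-set statistics (stored in the model).
#' The network has one tanh hidden layer and a softmax output trained by
#' full-batch gradient descent with momentum on the cross-entropy loss; the
#' squared-error trace (mean of \eqn{(x_i - z_i)^2} between one-hot targets
#' and outputs) is logged alongside. Training stops after `patience`
#' consecutive epochs without validation improvement, when the gradient norm
#' drops below `gradient_floor`, or at `max_epochs`; the weights of the best
#' validation epoch are restored. Fully seeded.
#'
#' @param X N x D feature matrix.
#' @param y Factor of N labels.
#' @param split A [split_dataset()] result on the rows of `X`.
#' @param cfg An [mlp_config()].
#' @return An `ann_model` containing weights, the scaler, the class order
#'   and a `trace` data frame (per-epoch cross-entropy and MSE per phase,
#'   gradient norm), plus `best_epoch` and `stop_reason`.
#' @export
train_ann <- function(X, y, split, cfg = mlp_config()) {
  X <- as.matrix(X)
  y <- if (is.factor(y)) y else factor(y)
  classes <- levels(y)
  stopifnot(nrow(X) == length(y))
  tr <- split$train; va <- split$validation; te <- split$test
  if (length(unique(y[tr])) < 2) {
    stop("training set is degenerate: fewer than two classes", call. = FALSE)
  }
  mu <- colMeans(X[tr, , drop = FALSE])
  sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  Ttr <- one_hot(y[tr], classes)
  D <- ncol(X); K <- length(classes); Hn <- cfg$hidden_units
  ntr <- length(tr)

  with_seed(cfg$seed, {
    W1 <- matrix(stats::rnorm(D * Hn, sd = 1 / sqrt(D)), D, Hn)
    W2 <- matrix(stats::rnorm(Hn * K, sd = 1 / sqrt(Hn)), Hn, K)
  })
  b1 <- numeric(Hn); b2 <- numeric(K)
  vW1 <- W1 * 0; vW2 <- W2 * 0; vb1 <- b1 * 0; vb2 <- b2 * 0

  phase_loss <- function(idx) {
    if (!length(idx)) return(c(ce = NA_real_, mse = NA_real_))
    fw <- mlp_forward(W1, b1, W2, b2, Z[idx, , drop = FALSE])
    Tt <- one_hot(y[idx], classes)
    c(ce = cross_entropy(fw$P, Tt), mse = mean((Tt - fw$P)^2))
  }

  trace <- data.frame()
  best <- list(val = Inf, epoch = 0L,
               W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  fails <- 0L
  stop_reason <- "max_epochs"
  Xtr <- Z[tr, , drop = FALSE]

  for (epoch in seq_len(cfg$max_epochs)) {
    fw <- mlp_forward(W1, b1, W2, b2, Xtr)
    dZ2 <- (fw$P - Ttr) / ntr                    # softmax + CE gradient
    gW2 <- crossprod(fw$H, dZ2); gb2 <- colSums(dZ2)
    dH <- tcrossprod(dZ2, W2) * (1 - fw$H^2)
    gW1 <- crossprod(Xtr, dH); gb1 <- colSums(dH)
    gnorm <- sqrt(sum(gW1^2) + sum(gb1^2) + sum(gW2^2) + sum(gb2^2))

    vW1 <- cfg$momentum * vW1 - cfg$learning_rate * gW1
    vb1 <- cfg$momentum * vb1 - cfg$learning_rate * gb1
    vW2 <- cfg$momentum * vW2 - cfg$learning_rate * gW2
    vb2 <- cfg$momentum * vb2 - cfg$learning_rate * gb2
    W1 <- W1 + vW1; b1 <- b1 + vb1; W2 <- W2 + vW2; b2 <- b2 + vb2

    ltr <- phase_loss(tr); lva <- phase_loss(va); lte <- phase_loss(te)
    trace <- rbind(trace, data.frame(
      epoch = epoch, ce_train = ltr["ce"], ce_validation = lva["ce"],
      ce_test = lte["ce"], mse_train = ltr["mse"],
      mse_validation = lva["mse"], mse_test = lte["mse"],
      gradient = gnorm, row.names = NULL))

    val <- if (length(va)) lva["ce"] else ltr["ce"]
    if (val < best$val - cfg$min_delta) {
      best <- list(val = val, epoch = epoch, W1 = W1, b1 = b1,
                   W2 = W2, b2 = b2)
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= cfg$patience) { stop_reason <- "patience"; break }
    }
    if (gnorm < cfg$gradient_floor) { stop_reason <- "gradient_floor"; break }
  }

  structure(list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
                 center = mu, scale = sg, classes = classes,
                 trace = trace, best_epoch = best$epoch,
                 stop_reason = stop_reason, config = cfg),
            class = "ann_model")
}

#' Class probabilities from a trained model
#' @param object An `ann_model`.
#' @param X Feature matrix with the training-time width.
#' @param ... Unused.
#' @return N x K probability matrix (rows sum to 1).
#' @export
predict.ann_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$center)) {
    stop(sprintf("X has %d columns, model expects %d", ncol(X),
                 length(object$center)), call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  P <- mlp_forward(object$W1, object$b1, object$W2, object$b2, Z)$P
  colnames(P) <- object$classes
  P
}

#' Confusion matrix of a model on test data
#'
#' Rows are true classes, columns argmax predictions.
#'
#' @param model An `ann_model`.
#' @param X_test,y_test Test rows and labels.
#' @return K x K integer matrix of class `confusion_matrix`.
#' @export
evaluate <- function(model, X_test, y_test) {
  P <- predict(model, X_test)
  pred <- factor(model$classes[max.col(P, ties.method = "first")],
                 levels = model$classes)
  confusion_matrix(y_test, pred, model$classes)
}

#' Build a confusion matrix from labels
#' @param truth,pred Factors (coerced) of equal length.
#' @param classes Class order.
#' @return K x K integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- levels(factor(c(as.character(truth),
                                                   as.character(pred))))
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- unclass(table(truth = truth, predicted = pred))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' One-vs-rest metrics from a confusion matrix
#'
#' For each class k, with TP the diagonal entry, FN/FP the remaining row and
#' column mass and TN the rest: accuracy (TP+TN)/(all), precision TP/(TP+FP),
#' specificity TN/(TN+FP) and sensitivity TP/(TP+FN), all in percent.
#' `class_accuracy` is the diagonal recall TP/(row total) -- the per-class
#' figure customarily read off a normalised confusion matrix. The
#' `macro` row ("average ratio") is the unweighted mean over classes;
#' undefined (0/0) entries are NA and excluded from the mean.
#'
#' @param cm A K x K confusion matrix, rows = truth.
#' @return List with `per_class` (data frame) and `macro` (named vector).
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  tot <- sum(cm)
  if (tot <= 0) stop("empty confusion matrix", call. = FALSE)
  K <- nrow(cm)
  res <- lapply(seq_len(K), function(k) {
    TP <- cm[k, k]
    FN <- sum(cm[k, ]) - TP
    FP <- sum(cm[, k]) - TP
    TN <- tot - TP - FN - FP
    pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
    c(accuracy = pct(TP + TN, tot),
      class_accuracy = pct(TP, TP + FN),
      precision = pct(TP, TP + FP),
      specificity = pct(TN, TN + FP),
      sensitivity = pct(TP, TP + FN))
  })
  per_class <- as.data.frame(do.call(rbind, res))
  rownames(per_class) <- rownames(cm)
  macro <- colMeans(per_class, na.rm = TRUE)
  list(per_class = per_class, macro = macro)
}

#' One-vs-rest ROC AUC
#'
#' Per-class AUC via the rank (Mann-Whitney) statistic on the class's score
#' column, reported in percent; the macro value is the unweighted mean over
#' classes present in `y`. A class absent from `y` gets NA and is excluded.
#'
#' @param scores N x K probability matrix (rows sum to 1).
#' @param y Factor of true labels, levels matching `colnames(scores)`.
#' @return List with `per_class` (named vector, percent) and `macro`.
#' @export
roc_auc <- function(scores, y) {
  scores <- as.matrix(scores)
  if (max(abs(rowSums(scores) - 1)) > 1e-6) {
    stop("score rows must sum to 1", call. = FALSE)
  }
  classes <- colnames(scores)
  y <- factor(y, levels = classes)
  auc <- vapply(seq_along(classes), function(k) {
    pos <- y == classes[k]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores[, k])
    100 * (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  names(auc) <- classes
  list(per_class = auc, macro = mean(auc, na.rm = TRUE))
}

#' Error histogram over output units
#'
#' Bins the errors (target minus output, over every output unit of every
#' sample) into `bins` equal-width bins spanning the observed range, counted
#' separately per phase (train/validation/test).
#'
#' @param targets,outputs Aligned N x K matrices.
#' @param phase Character/factor of length N tagging each row's phase.
#' @param bins Number of bins (default 20).
#' @return List with `breaks` (length bins + 1), `centers` and `counts`
#'   (phase x bins matrix).
#' @export
error_histogram <- function(targets, outputs, phase, bins = 20L) {
  targets <- as.matrix(targets); outputs <- as.matrix(outputs)
  if (!length(targets) || !identical(dim(targets), dim(outputs))) {
    stop("targets and outputs must be non-empty and aligned", call. = FALSE)
  }
  stopifnot(length(phase) == nrow(targets))
  err <- targets - outputs
  rng <- range(err)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * 1e-9
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  phase <- factor(phase)
  counts <- t(vapply(levels(phase), function(ph) {
    e <- as.vector(err[phase == ph, , drop = FALSE])
    tabulate(findInterval(e, breaks, rightmost.closed = TRUE), nbins = bins)
  }, integer(bins)))
  rownames(counts) <- levels(phase)
  list(breaks = breaks,
       centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = counts)
}

#' Full metrics report for a trained model
#'
#' Combines the confusion matrix, one-vs-rest metrics and ROC AUC on the
#' test partition into the layout of the per-class results tables
#' (classes + "average ratio" row).
#'
#' @param model An `ann_model`.
#' @param X,y Full feature matrix and labels.
#' @param split The `dataset_split` used in training.
#' @return List with `confusion`, `per_class` (data frame incl. `auc`),
#'   `macro` (named vector) and `trace`.
#' @export
metrics_report <- function(model, X, y, split) {
  te <- split$test
  cm <- evaluate(model, X[te, , drop = FALSE], y[te])
  m <- metrics_from_confusion(cm)
  a <- roc_auc(predict(model, X[te, , drop = FALSE]), y[te])
  per_class <- cbind(auc = a$per_class, m$per_class)
  macro <- c(auc = a$macro, m$macro)
  list(confusion = cm, per_class = per_class, macro = macro,
       trace = model$trace, best_epoch = model$best_epoch,
       stop_reason = model$stop_reason)
}
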