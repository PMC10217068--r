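# ANN training contracts, confusion-matrix metrics, AUC, error histogram

make_blob_data <- function(n_per_class = 50, K = 2, sep = 3, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(K), function(k) {
    ang <- 2 * pi * k / K
    cbind(rnorm(n_per_class, sep * cos(ang)),
          rnorm(n_per_class, sep * sin(ang)))
  }))
  y <- factor(rep(letters[seq_len(K)], each = n_per_class))
  list(X = X, y = y)
}

test_that("train_ann separates linearly separable clusters", {
  d <- make_blob_data(100, K = 2, sep = 3, seed = 91)
  sp <- split_dataset(d$y, seed = 1)
  m <- train_ann(d$X, d$y, sp, mlp_config(seed = 1))
  P <- predict(m, d$X[sp$train, ])
  acc <- mean(colnames(P)[max.col(P, ties.method = "first")] ==
                d$y[sp$train])
  expect_gte(acc, 0.99)
  expect_lte(nrow(m$trace), 100)
})

test_that("early stopping halts within patience of the best epoch", {
  # constant features: validation loss plateaus immediately
  set.seed(92)
  X <- matrix(1, 80, 5)
  y <- factor(rep(c("a", "b"), 40))
  sp <- split_dataset(y, seed = 2)
  m <- train_ann(X, y, sp, mlp_config(seed = 2))
  expect_true(m$stop_reason %in% c("patience", "gradient_floor"))
  expect_lte(nrow(m$trace), m$best_epoch + m$config$patience + 1)
  # best-epoch validation loss is <= all later validation losses
  vl <- m$trace$ce_validation
  expect_true(all(vl[m$best_epoch] <= vl[seq_along(vl) > m$best_epoch] +
                    1e-12))
})

test_that("training is deterministic and rejects degenerate input", {
  d <- make_blob_data(30, K = 3, seed = 93)
  sp <- split_dataset(d$y, seed = 3)
  m1 <- train_ann(d$X, d$y, sp, mlp_config(seed = 7))
  m2 <- train_ann(d$X, d$y, sp, mlp_config(seed = 7))
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$trace, m2$trace)

  y1 <- factor(rep("a", nrow(d$X)), levels = c("a", "b"))
  sp1 <- list(train = 1:60, validation = 61:75, test = 76:90)
  expect_error(train_ann(d$X, y1, sp1), "degenerate")
})

test_that("evaluate builds the confusion matrix by argmax", {
  d <- make_blob_data(20, K = 4, sep = 4, seed = 94)
  sp <- split_dataset(d$y, seed = 4)
  m <- train_ann(d$X, d$y, sp, mlp_config(seed = 4))
  cm <- evaluate(m, d$X[sp$test, ], d$y[sp$test])
  expect_equal(sum(cm), length(sp$test))
  expect_identical(dim(cm), c(4L, 4L))
  # row sums = per-class test counts
  expect_equal(unname(rowSums(cm)), unname(table(d$y[sp$test])),
               ignore_attr = TRUE)
  expect_error(evaluate(m, d$X[sp$test, 1, drop = FALSE], d$y[sp$test]),
               "columns")
})

test_that("confusion_matrix tallies match a manual count", {
  set.seed(95)
  truth <- sample(c("a", "b", "c"), 20, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 20, replace = TRUE)
  cm <- confusion_matrix(truth, pred, classes = c("a", "b", "c"))
  for (i in c("a", "b", "c")) for (j in c("a", "b", "c")) {
    expect_equal(cm[i, j], sum(truth == i & pred == j))
  }
})

test_that("metrics_from_confusion reproduces direct arithmetic", {
  cm <- matrix(c(9, 1, 2, 8), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- metrics_from_confusion(cm)
  expect_equal(m$per_class["pos", "accuracy"], 85)
  expect_equal(m$per_class["pos", "sensitivity"], 90)
  expect_equal(m$per_class["pos", "precision"], 100 * 9 / 11)
  expect_equal(m$per_class["pos", "specificity"], 80)

  # perfect diagonal: everything 100
  cmd <- diag(c(10, 10, 10, 10))
  md <- metrics_from_confusion(cmd)
  expect_true(all(as.matrix(md$per_class) == 100))
  expect_true(all(md$macro == 100))

  # single misclassification, checked against the one-vs-rest oracle
  cm1 <- diag(c(5, 5, 5)); cm1[1, 2] <- 1
  m1 <- metrics_from_confusion(cm1)
  for (k in 1:3) {
    o <- oracle_metrics(cm1, k)
    expect_equal(m1$per_class[k, "accuracy"], o[["accuracy"]])
    expect_equal(m1$per_class[k, "precision"], o[["precision"]])
    expect_equal(m1$per_class[k, "specificity"], o[["specificity"]])
    expect_equal(m1$per_class[k, "sensitivity"], o[["sensitivity"]])
  }
  # macro = unweighted mean; class_accuracy = diagonal recall
  expect_equal(m1$macro[["sensitivity"]], mean(m1$per_class$sensitivity))
  expect_equal(m1$per_class[1, "class_accuracy"], 100 * 5 / 6)

  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "empty")
})

test_that("metrics invariants: TP totals and row/column identities", {
  set.seed(96)
  for (rep in 1:20) {
    cm <- matrix(rpois(16, 5), 4, 4)
    if (sum(cm) == 0) next
    tot <- sum(cm)
    tps <- diag(cm)
    expect_equal(sum(tps), sum(diag(cm)))
    for (k in 1:4) {
      TP <- cm[k, k]
      FN <- sum(cm[k, ]) - TP
      FP <- sum(cm[, k]) - TP
      expect_equal(TP + FN, sum(cm[k, ]))
      expect_equal(TP + FP, sum(cm[, k]))
    }
  }
})

test_that("roc_auc: perfect, null and oracle-checked cases", {
  # perfectly ranked scores
  y <- factor(rep(c("a", "b"), each = 5))
  s <- cbind(a = c(.9, .8, .85, .95, .7, .3, .2, .1, .25, .15))
  s <- cbind(a = s[, 1], b = 1 - s[, 1])
  r <- roc_auc(s, y)
  expect_equal(unname(r$per_class["a"]), 100)
  expect_equal(unname(r$per_class["b"]), 100)
  expect_equal(r$macro, 100)

  # label-independent scores: AUC near 50 at large N
  set.seed(97)
  n <- 2000
  y2 <- factor(sample(c("a", "b"), n, replace = TRUE))
  p <- runif(n)
  r2 <- roc_auc(cbind(a = p, b = 1 - p), y2)
  expect_lt(abs(r2$macro - 50), 3)

  # 6-sample toy vs exhaustive pair counting
  y3 <- factor(c("a", "a", "b", "b", "a", "b"))
  sa <- c(0.9, 0.4, 0.35, 0.8, 0.55, 0.1)
  r3 <- roc_auc(cbind(a = sa, b = 1 - sa), y3)
  expect_equal(unname(r3$per_class["a"]), oracle_auc(sa, y3 == "a"))

  # absent class: NA, excluded from macro
  y4 <- factor(c("a", "a", "a"), levels = c("a", "b"))
  r4 <- roc_auc(cbind(a = c(.6, .7, .8), b = c(.4, .3, .2)), y4)
  expect_true(is.na(r4$per_class["a"]) && is.na(r4$per_class["b"]))

  expect_error(roc_auc(cbind(a = 1, b = 1), factor("a")), "sum to 1")
})

test_that("error_histogram bins errors per phase", {
  # outputs equal targets: all mass in the bin containing zero
  T <- diag(4); O <- diag(4)
  eh <- error_histogram(T, O, phase = rep("train", 4), bins = 20)
  expect_equal(sum(eh$counts), 16)
  expect_equal(max(eh$counts), 16)

  # errors only at -1 and 1: the two extreme bins
  T2 <- rbind(c(1, 0), c(0, 1))
  O2 <- rbind(c(0, 1), c(1, 0))
  eh2 <- error_histogram(T2, O2, phase = c("train", "test"), bins = 10)
  expect_equal(sum(eh2$counts[, c(1, 10)]), 4)

  # random case against the direct binning oracle
  set.seed(98)
  T3 <- matrix(runif(60), 20, 3)
  O3 <- matrix(runif(60), 20, 3)
  ph <- sample(c("train", "validation", "test"), 20, replace = TRUE)
  eh3 <- error_histogram(T3, O3, ph, bins = 20)
  err <- T3 - O3
  for (p in unique(ph)) {
    expect_equal(unname(eh3$counts[p, ]),
                 oracle_bin_counts(as.vector(err[ph == p, ]), eh3$breaks))
  }
  expect_error(error_histogram(matrix(0, 0, 2), matrix(0, 0, 2),
                               character(0)), "non-empty")
})
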