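# End-to-end orchestration of the six systems (three strategies):
#   s1_mobilenet / s1_densenet : one backbone -> PCA(450) -> ANN
#   s2_fuse_before             : concat(2048+2048) -> PCA(710) -> ANN
#   s2_fuse_after              : PCA(450) + PCA(450) -> concat 900 -> ANN
#   s3_mobilenet_hand / s3_densenet_hand : PCA(450) + handcrafted 255 -> 705
# All strategies share the split, training and evaluation code paths and
# differ only in feature assembly. The default backbones are two toy specs
# with different projection seeds standing in for the two pretrained CNNs.

#' All recognised strategy names
#' @return Character vector of the six strategy identifiers.
#' @export
strategy_names <- function() {
  c("s1_mobilenet", "s1_densenet", "s2_fuse_before", "s2_fuse_after",
    "s3_mobilenet_hand", "s3_densenet_hand")
}

#' Configure a pipeline run
#'
#' @param strategy One of [strategy_names()].
#' @param synthetic A [synthetic_config()] used when no `data_dir` is given.
#' @param data_dir Optional class-per-subdirectory image folder; overrides
#'   the synthetic source.
#' @param backbone_a,backbone_b The two backbone specs (defaults: toy specs
#'   with different projection seeds, standing in for MobileNet and
#'   DenseNet-121).
#' @param pca_single,pca_fused PCA widths for the single-model (450) and
#'   fused-before (710) pathways; capped at N - 1 with a message on small
#'   data.
#' @param mlp An [mlp_config()].
#' @param seed Master seed for split and training.
#' @param augment Augment the training partition 9-fold before feature
#'   extraction (default TRUE, mirroring the reference training procedure;
#'   validation and test are never augmented).
#' @param enhance_window Mean-filter window of the enhancement stage.
#' @param outdir Optional directory for artifacts (split manifest, metrics,
#'   confusion matrix, trace, log); nothing is written when NULL.
#' @return A `strategy_config`.
#' @export
strategy_config <- function(strategy = "s3_mobilenet_hand",
                            synthetic = synthetic_config(),
                            data_dir = NULL,
                            backbone_a = backbone_spec("toy", seed = 101L),
                            backbone_b = backbone_spec("toy", seed = 202L),
                            pca_single = 450L, pca_fused = 710L,
                            mlp = mlp_config(), seed = 1L,
                            augment = TRUE, enhance_window = 5L,
                            outdir = NULL) {
  strategy <- match.arg(strategy, strategy_names())
  structure(list(strategy = strategy, synthetic = synthetic,
                 data_dir = data_dir, backbone_a = backbone_a,
                 backbone_b = backbone_b, pca_single = as.integer(pca_single),
                 pca_fused = as.integer(pca_fused), mlp = mlp,
                 seed = as.integer(seed), augment = isTRUE(augment),
                 enhance_window = as.integer(enhance_window),
                 outdir = outdir),
            class = "strategy_config")
}

pipe_log <- function(log, fmt, ...) {
  line <- sprintf(fmt, ...)
  c(log, line)
}

# Fit PCA on training rows only and project all rows; width capped at
# n_train - 1 with a message.
reduce_train_pca <- function(X, train_idx, dim) {
  k <- cap_pca_dim(dim, length(train_idx), ncol(X))
  model <- fit_pca(X[train_idx, , drop = FALSE], k)
  apply_pca(model, X)
}

#' Run one strategy end-to-end
#'
#' Stages: load/generate dataset -> enhance -> split -> (optional 9-fold
#' training augmentation) -> feature extraction -> per-strategy PCA/fusion
#' -> ANN training -> test-set evaluation. Every stage is logged with its
#' output dimensions; a width that violates the strategy's fusion contract
#' aborts with the stage name. Deterministic for a fixed config and seed.
#'
#' @param cfg A [strategy_config()].
#' @return List with `metrics` (see [metrics_report()]), `split`, the fused
#'   `feature_width`, the `log` lines, and `model`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "strategy_config"))
  log <- character(0)

  set <- if (!is.null(cfg$data_dir)) read_image_folder(cfg$data_dir)
         else generate_synthetic_dataset(cfg$synthetic)
  log <- pipe_log(log, "dataset: %d images, %d classes",
                  length(set$images), length(set$classes))

  set$images <- lapply(set$images, enhance, window = cfg$enhance_window)
  log <- pipe_log(log, "enhance: window %d", cfg$enhance_window)

  split <- split_dataset(set$labels, seed = cfg$seed)
  log <- pipe_log(log, "split: %d train / %d validation / %d test",
                  length(split$train), length(split$validation),
                  length(split$test))

  if (cfg$augment) {
    aug <- augment_training_set(set, split, seed = cfg$seed)
    set <- aug$set; split <- aug$split
    log <- pipe_log(log, "augment: train grown to %d", length(split$train))
  }

  n_train <- length(split$train)
  needs_hand <- cfg$strategy %in% c("s3_mobilenet_hand", "s3_densenet_hand")
  needs_b <- cfg$strategy %in% c("s2_fuse_before", "s2_fuse_after",
                                 "s1_densenet", "s3_densenet_hand")
  needs_a <- !cfg$strategy %in% c("s1_densenet", "s3_densenet_hand")

  A <- if (needs_a) extract_deep_features(set$images, cfg$backbone_a)
  B <- if (needs_b) extract_deep_features(set$images, cfg$backbone_b)
  if (needs_a) log <- pipe_log(log, "deep features A: %d x %d",
                               nrow(A), ncol(A))
  if (needs_b) log <- pipe_log(log, "deep features B: %d x %d",
                               nrow(B), ncol(B))

  X <- switch(cfg$strategy,
    s1_mobilenet = reduce_train_pca(A, split$train, cfg$pca_single),
    s1_densenet = reduce_train_pca(B, split$train, cfg$pca_single),
    s2_fuse_before = {
      Z <- cbind(A, B)
      log <- pipe_log(log, "fuse before PCA: width %d", ncol(Z))
      reduce_train_pca(Z, split$train, cfg$pca_fused)
    },
    s2_fuse_after = {
      Ar <- reduce_train_pca(A, split$train, cfg$pca_single)
      Br <- reduce_train_pca(B, split$train, cfg$pca_single)
      fuse_after_pca(Ar, Br, width = ncol(Ar))
    },
    s3_mobilenet_hand = ,
    s3_densenet_hand = {
      C <- if (cfg$strategy == "s3_mobilenet_hand") A else B
      Cr <- reduce_train_pca(C, split$train, cfg$pca_single)
      H <- handcrafted_matrix(set$images)
      scaler <- fit_minmax(H[split$train, , drop = FALSE])
      H <- apply_minmax(scaler, H)
      log <- pipe_log(log, "handcrafted: %d x %d", nrow(H), ncol(H))
      fuse_cnn_handcrafted(Cr, H, cnn_width = ncol(Cr), hand_width = ncol(H))
    }
  )
  log <- pipe_log(log, "fused features: %d x %d", nrow(X), ncol(X))

  expected <- switch(cfg$strategy,
    s1_mobilenet = , s1_densenet = min(cfg$pca_single, n_train - 1L),
    s2_fuse_before = min(cfg$pca_fused, n_train - 1L),
    s2_fuse_after = 2L * min(cfg$pca_single, n_train - 1L),
    min(cfg$pca_single, n_train - 1L) + 255L)
  if (ncol(X) != expected) {
    stop(sprintf("stage fusion: strategy %s expected width %d, got %d",
                 cfg$strategy, expected, ncol(X)), call. = FALSE)
  }

  mlp <- cfg$mlp
  mlp$seed <- cfg$seed
  model <- train_ann(X, set$labels, split, mlp)
  log <- pipe_log(log, "train: stopped at epoch %d (%s), best epoch %d",
                  nrow(model$trace), model$stop_reason, model$best_epoch)

  metrics <- metrics_report(model, X, set$labels, split)
  log <- pipe_log(log, "test macro accuracy (diagonal recall): %.2f%%",
                  metrics$macro[["class_accuracy"]])

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write_split_manifest(split, set$labels,
                         file.path(cfg$outdir, "split.csv"))
    utils::write.csv(as.data.frame(unclass(metrics$confusion)),
                     file.path(cfg$outdir, "confusion.csv"))
    utils::write.csv(metrics$trace, file.path(cfg$outdir, "trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(strategy = cfg$strategy, seed = cfg$seed,
           per_class = metrics$per_class,
           macro = as.list(metrics$macro),
           best_epoch = metrics$best_epoch,
           stop_reason = metrics$stop_reason),
      file.path(cfg$outdir, "metrics.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(log, file.path(cfg$outdir, "run.log"))
  }

  list(metrics = metrics, split = split, feature_width = ncol(X),
       log = log, model = model)
}

#' Compare the fused pathway with its two single branches
#'
#' On one synthetic dataset and one split, trains three networks on exactly
#' the same rows: backbone-only (PCA-reduced), handcrafted-only, and their
#' fusion. Feature extraction is shared, so the comparison isolates the
#' feature-assembly stage.
#'
#' @param synthetic A [synthetic_config()]; its `seed` is overridden by
#'   `seed`.
#' @param seed Controls dataset generation, split and training.
#' @param backbone Backbone spec (default toy).
#' @param pca_single Backbone PCA width before fusion (default 450, capped
#'   at n_train - 1).
#' @param mlp An [mlp_config()]; its seed is overridden by `seed`.
#' @param augment Augment the training partition 9-fold (default TRUE).
#' @return Named vector of macro test accuracies (diagonal recall, percent)
#'   for `fused`, `cnn`, `handcrafted`.
#' @export
compare_fusion_branches <- function(synthetic = synthetic_config(),
                                    seed = 1L,
                                    backbone = backbone_spec("toy",
                                                             seed = 101L),
                                    pca_single = 450L,
                                    mlp = mlp_config(),
                                    augment = TRUE) {
  synthetic$seed <- as.integer(seed)
  set <- generate_synthetic_dataset(synthetic)
  set$images <- lapply(set$images, enhance)
  split <- split_dataset(set$labels, seed = seed)
  if (augment) {
    aug <- augment_training_set(set, split, seed = seed)
    set <- aug$set; split <- aug$split
  }
  A <- extract_deep_features(set$images, backbone)
  Ar <- reduce_train_pca(A, split$train, pca_single)
  H <- handcrafted_matrix(set$images)
  H <- apply_minmax(fit_minmax(H[split$train, , drop = FALSE]), H)
  Xf <- fuse_cnn_handcrafted(Ar, H, cnn_width = ncol(Ar),
                             hand_width = ncol(H))
  mlp$seed <- as.integer(seed)
  macro_acc <- function(X) {
    model <- train_ann(X, set$labels, split, mlp)
    metrics_report(model, X, set$labels, split)$macro[["class_accuracy"]]
  }
  c(fused = macro_acc(Xf), cnn = macro_acc(Ar), handcrafted = macro_acc(H))
}
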