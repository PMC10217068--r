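# Deep feature extraction through a pluggable backbone, plus PCA reduction.
# The bundled "toy" backbone is a deterministic, fixed-seed random projection
# of pooled image patches: it needs no downloaded weights, so the full
# pipeline runs offline and bit-reproducibly. Pretrained specs (mobilenet,
# densenet121) are declared but raise an explicit environment error here.

#' Describe a feature-extraction backbone
#'
#' @param name One of "toy", "mobilenet", "densenet121". Only "toy" is
#'   runnable in this package; the pretrained names are placeholders that
#'   raise an explicit error if no weights are available.
#' @param output_dim Feature width per image (reference configuration 2048,
#'   reached for pretrained specs by concatenating global-average and
#'   global-max pooling of the final feature map).
#' @param input_size (H, W) the backbone nominally expects; the toy backbone
#'   pools on a fixed grid so any input size is accepted.
#' @param grid Pooling grid for the toy backbone (grid x grid cells, each
#'   contributing its per-channel mean intensity).
#' @param seed Seed of the toy backbone's fixed random projection. Two specs
#'   with different seeds behave as two different backbones.
#' @return A `backbone_spec` object.
#' @export
backbone_spec <- function(name = c("toy", "mobilenet", "densenet121"),
                          output_dim = 2048L, input_size = c(224L, 224L),
                          grid = 8L, seed = 101L) {
  name <- match.arg(name)
  stopifnot(output_dim >= 1, grid >= 1)
  structure(list(name = name, output_dim = as.integer(output_dim),
                 input_size = as.integer(input_size), grid = as.integer(grid),
                 seed = as.integer(seed)),
            class = "backbone_spec")
}

# Evaluate an expression with an isolated, restored RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# Per-channel mean over a grid x grid partition of the image (mean-pooled
# patches), intensities scaled to [0, 1]. Returns a vector of length
# 3 * grid^2 (grey images are treated as three identical channels).
pool_grid <- function(img, grid) {
  if (!is_rgb(img)) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  ri <- ceiling(seq_len(h) / h * grid)
  ci <- ceiling(seq_len(w) / w * grid)
  cell <- (rep(ri, times = w) - 1L) * grid + rep(ci, each = h)
  cnt <- tabulate(cell, nbins = grid * grid)
  out <- numeric(0)
  for (ch in 1:3) {
    v <- as.vector(img[, , ch]) / 255
    out <- c(out, as.vector(rowsum(v, cell)) / cnt)
  }
  unname(out)
}

# Materialise the toy backbone's fixed projection (W, b) for a spec.
toy_projection <- function(spec) {
  p <- 3L * spec$grid^2
  with_seed(spec$seed, {
    W <- matrix(stats::rnorm(spec$output_dim * p, sd = 1 / sqrt(p)),
                spec$output_dim, p)
    b <- stats::rnorm(spec$output_dim, sd = 0.1)
    list(W = W, b = b)
  })
}

#' Extract deep features for a list of images
#'
#' For the toy backbone each image is reduced to mean-pooled patches
#' (per-cell channel means on a fixed grid), then passed through a fixed-seed
#' random projection with a tanh non-linearity:
#' \eqn{f = \tanh(W x + b)}. Deterministic for a fixed spec and inputs.
#'
#' @param images List of image arrays in [0, 255].
#' @param spec A [backbone_spec()].
#' @return N x output_dim numeric matrix.
#' @export
extract_deep_features <- function(images, spec = backbone_spec()) {
  stopifnot(inherits(spec, "backbone_spec"), length(images) >= 1)
  if (spec$name != "toy") {
    stop(sprintf(paste0("pretrained backbone '%s' has no weights available ",
                        "in this environment; use backbone_spec(\"toy\")"),
                 spec$name), call. = FALSE)
  }
  proj <- toy_projection(spec)
  X <- t(vapply(images, function(im) {
    tanh(as.vector(proj$W %*% pool_grid(im, spec$grid)) + proj$b)
  }, numeric(spec$output_dim)))
  colnames(X) <- sprintf("%s_%04d", spec$name, seq_len(spec$output_dim))
  X
}

#' Fit a principal component analysis model
#'
#' Standard centred (not scaled) PCA. Component signs are fixed so that each
#' component's largest-magnitude loading is positive, making results
#' reproducible across numerical libraries.
#'
#' @param X N x D numeric matrix with finite entries.
#' @param n_components Number of components, at most `min(N - 1, D)`.
#' @return A `pca_model` with `rotation` (D x k), `center` (length D),
#'   `explained_variance_ratio` (length k, non-increasing) and
#'   `n_components`.
#' @export
fit_pca <- function(X, n_components) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite", call. = FALSE)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1 || n_components > kmax) {
    stop(sprintf("n_components must be in [1, %d] for a %d x %d matrix",
                 kmax, nrow(X), ncol(X)), call. = FALSE)
  }
  # centred PCA via the smaller-side eigendecomposition: covariance (D x D)
  # when D <= N, Gram matrix (N x N) otherwise -- much cheaper than a full
  # SVD on wide feature matrices.
  n <- nrow(X); d <- ncol(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (d <= n) {
    e <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
    vars <- pmax(e$values, 0)
    rot <- e$vectors[, seq_len(n_components), drop = FALSE]
  } else {
    e <- eigen(tcrossprod(Xc), symmetric = TRUE)    # eigenvalues = s^2
    vars <- pmax(e$values, 0) / (n - 1)
    sv <- sqrt(pmax(e$values[seq_len(n_components)], 0))
    if (any(sv == 0)) {
      stop("degenerate input: requested components beyond the data rank",
           call. = FALSE)
    }
    rot <- crossprod(Xc, e$vectors[, seq_len(n_components), drop = FALSE])
    rot <- sweep(rot, 2, sv, "/")
  }
  tot <- sum(vars)
  if (tot == 0) stop("degenerate input: X has no variance", call. = FALSE)
  for (k in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, k])), k] < 0) rot[, k] <- -rot[, k]
  }
  rownames(rot) <- colnames(X)
  structure(list(rotation = rot, center = ctr,
                 sdev_all = sqrt(vars),
                 explained_variance_ratio = vars[seq_len(n_components)] / tot,
                 n_components = as.integer(n_components)),
            class = "pca_model")
}

#' Project data through a fitted PCA model
#'
#' @param model A [fit_pca()] result.
#' @param X Matrix with the same number of columns the model was fitted on.
#' @return N x n_components score matrix.
#' @export
apply_pca <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$center)) {
    stop(sprintf("X has %d columns, model expects %d", ncol(X),
                 length(model$center)), call. = FALSE)
  }
  S <- sweep(X, 2, model$center) %*% model$rotation
  colnames(S) <- sprintf("pc_%03d", seq_len(ncol(S)))
  S
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components over %d features; %.1f%% variance\n",
              x$n_components, length(x$center),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}
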