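# Feature-level fusion with exact dimensional contracts. Widths per mode:
# single backbone after PCA 450; fuse-before-PCA 2048+2048 = 4096 -> 710;
# fuse-after-PCA 450+450 = 900; backbone-plus-handcrafted 450+255 = 705.

#' Expected fused widths per fusion mode
#' @return Named integer vector.
#' @export
fusion_plan <- function() {
  c(single_pca = 450L, fuse_before_pca = 710L, fuse_after_pca = 900L,
    cnn_plus_handcrafted = 705L)
}

check_fusable <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) {
    stop(sprintf("row mismatch: %d vs %d", nrow(A), nrow(B)), call. = FALSE)
  }
  list(A = A, B = B)
}

# Cap a requested PCA dimension at what the data supports, reporting the cap.
cap_pca_dim <- function(requested, n, d) {
  kmax <- min(n - 1L, d)
  if (requested > kmax) {
    message(sprintf("PCA dimension capped at %d (requested %d, N = %d, D = %d)",
                    kmax, requested, n, d))
    kmax
  } else requested
}

#' Fuse two backbone feature matrices, then reduce with PCA
#'
#' Column-concatenates the two feature matrices (reference widths 2048 each,
#' giving 4096) and fits + applies PCA to `pca_dim` (reference 710). When the
#' sample size cannot support `pca_dim` components the dimension is capped at
#' N - 1 with a message, never silently.
#'
#' @param A,B N x D feature matrices with equal row counts.
#' @param pca_dim Target width after reduction (default 710).
#' @return N x pca_dim score matrix with the fitted model in attribute
#'   `pca_model`.
#' @export
fuse_before_pca <- function(A, B, pca_dim = 710L) {
  m <- check_fusable(A, B)
  Z <- cbind(m$A, m$B)
  k <- cap_pca_dim(pca_dim, nrow(Z), ncol(Z))
  model <- fit_pca(Z, k)
  out <- apply_pca(model, Z)
  attr(out, "pca_model") <- model
  out
}

#' Fuse two already-reduced backbone feature matrices
#'
#' Lossless column concatenation, A's block first (reference 450 + 450 =
#' 900).
#'
#' @param A_red,B_red N x 450 PCA-reduced matrices.
#' @param width Expected width of each input (default 450).
#' @return N x (2 * width) matrix with a `block_map` attribute.
#' @export
fuse_after_pca <- function(A_red, B_red, width = 450L) {
  m <- check_fusable(A_red, B_red)
  if (ncol(m$A) != width || ncol(m$B) != width) {
    stop(sprintf("both inputs must have width %d (got %d and %d)",
                 width, ncol(m$A), ncol(m$B)), call. = FALSE)
  }
  out <- cbind(m$A, m$B)
  attr(out, "block_map") <- c(A = ncol(m$A), B = ncol(m$B))
  out
}

#' Fuse reduced backbone features with the handcrafted block
#'
#' Lossless concatenation, backbone block first (reference 450 + 255 = 705).
#'
#' @param C_red N x 450 PCA-reduced backbone features.
#' @param H N x 255 handcrafted feature matrix.
#' @param cnn_width,hand_width Expected input widths (defaults 450 and 255).
#' @return N x (cnn_width + hand_width) matrix with a `block_map` attribute.
#' @export
fuse_cnn_handcrafted <- function(C_red, H, cnn_width = 450L,
                                 hand_width = 255L) {
  m <- check_fusable(C_red, H)
  if (ncol(m$A) != cnn_width) {
    stop(sprintf("backbone block must have width %d (got %d)",
                 cnn_width, ncol(m$A)), call. = FALSE)
  }
  if (ncol(m$B) != hand_width) {
    stop(sprintf("handcrafted block must have width %d (got %d)",
                 hand_width, ncol(m$B)), call. = FALSE)
  }
  out <- cbind(m$A, m$B)
  attr(out, "block_map") <- c(cnn = ncol(m$A), handcrafted = ncol(m$B))
  out
}

#' Fit a per-column min-max scaler on training rows
#'
#' Handcrafted blocks are min-max scaled to [0, 1] over the training set
#' before fusion so that no block dominates by numeric range. Constant
#' columns map to 0.
#'
#' @param X Training feature matrix.
#' @return A `minmax_scaler`.
#' @export
fit_minmax <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  structure(list(lo = lo, rng = ifelse(hi > lo, hi - lo, 1)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#' @param scaler A [fit_minmax()] result.
#' @param X Matrix with matching columns.
#' @return Scaled matrix (training rows land in [0, 1]).
#' @export
apply_minmax <- function(scaler, X) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  X <- as.matrix(X)
  sweep(sweep(X, 2, scaler$lo), 2, scaler$rng, "/")
}
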