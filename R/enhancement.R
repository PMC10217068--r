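# Two-filter enhancement: a 5x5 centre-excluded averaging filter to denoise,
# a 4-neighbour Laplacian for edge response, and their sharpening
# combination OX = smoothed - Laplacian(smoothed).

# Pad a matrix by replicating its border pixels `r` deep.
pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

# Sum of shifted copies of `m` over window offsets, replicated borders.
# `offsets` is a 2-column matrix of (drow, dcol); returns same-shape matrix.
shift_sum <- function(m, offsets, weights = NULL) {
  r <- max(abs(offsets))
  p <- pad_replicate(m, r)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  if (is.null(weights)) weights <- rep(1, nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    out <- out + weights[k] *
      p[(1 + r + dr):(h + r + dr), (1 + r + dc):(w + r + dc), drop = FALSE]
  }
  out
}

# Apply a per-channel matrix operation to grey or RGB images.
per_channel <- function(img, f) {
  if (!is_rgb(img)) return(f(img))
  out <- img
  for (ch in 1:3) out[, , ch] <- f(img[, , ch])
  out
}

#' Centre-excluded mean filter
#'
#' Replaces each pixel by the mean of the other `window^2 - 1` pixels of its
#' `window` x `window` neighbourhood (the centre pixel itself is excluded
#' from the average). Borders are handled by edge replication. The output is
#' rounded to the nearest integer and clipped to [0, 255]. RGB images are
#' filtered per channel.
#'
#' @param img Image array in [0, 255].
#' @param window Odd window size >= 3 (default 5, i.e. the mean of 24
#'   neighbours).
#' @return Filtered image, same shape as the input.
#' @export
mean_filter <- function(img, window = 5L) {
  check_image(img)
  if (length(window) != 1L || !is.finite(window) || window < 3 ||
      window %% 2 != 1) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  r <- (window - 1L) / 2
  off <- as.matrix(expand.grid(dr = -r:r, dc = -r:r))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
  n <- nrow(off)
  out <- per_channel(img, function(m) round(shift_sum(m, off) / n))
  clip01(out)
}

#' Discrete Laplacian edge response
#'
#' Convolves the luminance image with the 4-neighbour kernel
#' \code{[[0,1,0],[1,-4,1],[0,1,0]]}, replicating borders. RGB input is
#' converted to luminance first. The response is signed and is not clipped.
#'
#' @param img Image array.
#' @return Signed H x W matrix of Laplacian responses.
#' @export
laplacian <- function(img) {
  check_image(img)
  g <- as_gray(img)
  off <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1), c(0, 0))
  shift_sum(g, off, weights = c(1, 1, 1, 1, -4))
}

# Per-channel signed Laplacian (no luminance conversion); used by enhance()
# so each colour channel is sharpened by its own edge response.
laplacian_channel <- function(m) {
  off <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1), c(0, 0))
  shift_sum(m, off, weights = c(1, 1, 1, 1, -4))
}

#' Sharpen a fundus image
#'
#' The enhancement combination: smooth with the centre-excluded mean filter,
#' then subtract the Laplacian of the smoothed image,
#' \code{OX = v - laplacian(v)} with \code{v = mean_filter(img)}. Applied per
#' channel for RGB; the result is clipped to [0, 255]. Deterministic.
#'
#' @param img Image array in [0, 255].
#' @param window Mean-filter window (default 5).
#' @return Enhanced image, same shape as the input.
#' @export
enhance <- function(img, window = 5L) {
  v <- mean_filter(img, window)
  out <- per_channel(v, function(m) m - laplacian_channel(m))
  clip01(out)
}

#' Filter-quality metrics
#'
#' Compares a filtered image with the original: mean squared error (MSE,
#' lower is better), edge preservation index (EPI, the Pearson correlation
#' between the Laplacian edge maps of the two images; 1 means identical edge
#' structure) and structural content (SC, the energy ratio
#' \eqn{\sum original^2 / \sum filtered^2}).
#'
#' If both edge maps are constant the EPI is 1 when they are equal and NA
#' otherwise (correlation undefined).
#'
#' @param original,filtered Images of identical shape.
#' @return A list with elements `mse`, `epi`, `sc`.
#' @export
filter_quality <- function(original, filtered) {
  check_image(original, "original")
  check_image(filtered, "filtered")
  if (!identical(dim(original), dim(filtered))) {
    stop("`original` and `filtered` must have identical shape", call. = FALSE)
  }
  mse <- mean((original - filtered)^2)
  e1 <- laplacian(original)
  e2 <- laplacian(filtered)
  if (stats::sd(e1) == 0 || stats::sd(e2) == 0) {
    epi <- if (isTRUE(all.equal(e1, e2))) 1 else NA_real_
  } else {
    epi <- stats::cor(as.vector(e1), as.vector(e2))
  }
  denom <- sum(filtered^2)
  sc <- if (denom == 0) NA_real_ else sum(original^2) / denom
  list(mse = mse, epi = epi, sc = sc)
}
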