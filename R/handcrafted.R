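# Classical descriptor blocks: GLCM (24), fuzzy colour histogram (16),
# local binary patterns (203) and wavelet sub-band statistics (12),
# concatenated into the 255-dimensional handcrafted vector.

#' Quantise a grey image to a fixed number of levels
#'
#' Maps intensities in [0, 255] to integer levels 0 .. levels-1 by uniform
#' binning of the full range.
#'
#' @param img Grey image in [0, 255].
#' @param levels Number of grey levels.
#' @return Integer matrix of levels.
#' @keywords internal
quantize_gray <- function(img, levels = 8L) {
  q <- floor(clip01(img) * levels / 256)
  q[q > levels - 1] <- levels - 1
  q
}

# Offsets (drow, dcol) at distance d for the four GLCM angles, in the fixed
# order 0, 45, 90, 135 degrees.
glcm_offsets <- function(d = 1L) {
  list(`0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L), `135` = c(-d, -d))
}

glcm_stat_names <- c("contrast", "correlation", "energy", "homogeneity",
                     "entropy", "dissimilarity")

# Six texture statistics of a normalised symmetric co-occurrence matrix P.
glcm_stats <- function(P) {
  L <- nrow(P)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  var_i <- sum((i - mu_i)^2 * P); var_j <- sum((j - mu_j)^2 * P)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (var_i * var_j == 0) 1 else
    sum((i - mu_i) * (j - mu_j) * P) / sqrt(var_i * var_j)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + (i - j)^2))
  pz <- P[P > 0]
  entropy <- -sum(pz * log2(pz))
  dissimilarity <- sum(abs(i - j) * P)
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity, entropy = entropy,
    dissimilarity = dissimilarity)
}

#' Grey-level co-occurrence texture features
#'
#' Quantises the image to `levels` grey values and, for each of the four
#' directions (0, 45, 90, 135 degrees) at pixel distance `d`, builds the
#' symmetric normalised co-occurrence matrix and computes six statistics
#' (contrast, correlation, energy, homogeneity, entropy, dissimilarity),
#' giving a 24-vector in angle-major order.
#'
#' @param img Grey image in [0, 255] (RGB is converted to luminance).
#' @param levels Grey quantisation levels (default 8).
#' @param d Co-occurrence distance in pixels (default 1).
#' @return Named numeric vector of length 24.
#' @export
glcm_features <- function(img, levels = 8L, d = 1L) {
  check_image(img)
  g <- as_gray(img)
  if (nrow(g) <= d && ncol(g) <= d) {
    stop("image too small for co-occurrence distance d = ", d, call. = FALSE)
  }
  q <- quantize_gray(g, levels)
  h <- nrow(q); w <- ncol(q)
  out <- numeric(0)
  for (ang in names(glcm_offsets(d))) {
    o <- glcm_offsets(d)[[ang]]
    r1 <- max(1, 1 - o[1]):min(h, h - o[1])
    c1 <- max(1, 1 - o[2]):min(w, w - o[2])
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + o[1], c1 + o[2], drop = FALSE]
    # symmetric counts: each ordered pair counted in both directions
    idx <- c(a * levels + b, b * levels + a)
    counts <- tabulate(idx + 1L, nbins = levels * levels)
    P <- matrix(counts / sum(counts), levels, levels, byrow = TRUE)
    s <- glcm_stats(P)
    names(s) <- sprintf("glcm_%s_%s", ang, glcm_stat_names)
    out <- c(out, s)
  }
  out
}

#' Hue of RGB pixels
#'
#' Standard hexagonal HSV hue in degrees [0, 360); achromatic pixels
#' (max = min) get hue 0.
#'
#' @param img RGB image in [0, 255].
#' @return H x W matrix of hues in degrees.
#' @keywords internal
pixel_hue <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  delta <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  nz <- delta > 0
  ir <- nz & mx == r
  ig <- nz & !ir & mx == g
  ib <- nz & !ir & !ig
  h[ir] <- 60 * (((g[ir] - b[ir]) / delta[ir]) %% 6)
  h[ig] <- 60 * ((b[ig] - r[ig]) / delta[ig] + 2)
  h[ib] <- 60 * ((r[ib] - g[ib]) / delta[ib] + 4)
  h %% 360
}

#' Fuzzy colour histogram
#'
#' Maps each pixel to its hue and spreads a unit of mass over `bins`
#' triangular membership functions whose centres are evenly spaced on the
#' hue circle, with full overlap between adjacent bins: a pixel exactly on a
#' centre contributes 1 to that bin; a pixel midway between two centres
#' contributes 1/2 to each. The histogram is normalised to sum to 1.
#'
#' @param img RGB image in [0, 255].
#' @param bins Number of fuzzy bins (default 16).
#' @return Named numeric vector of length `bins` summing to 1.
#' @export
fch_features <- function(img, bins = 16L) {
  check_image(img)
  if (!is_rgb(img)) stop("fuzzy colour histogram needs an RGB image",
                         call. = FALSE)
  h <- as.vector(pixel_hue(img))
  width <- 360 / bins
  centers <- (seq_len(bins) - 1L) * width
  acc <- numeric(bins)
  for (k in seq_len(bins)) {
    dist <- abs(h - centers[k])
    dist <- pmin(dist, 360 - dist)        # circular distance
    m <- pmax(0, 1 - dist / width)        # triangular membership
    acc[k] <- sum(m)
  }
  names(acc) <- sprintf("fch_%02d", seq_len(bins))
  acc / sum(acc)
}

#' Local binary pattern histogram (24-neighbour, 5x5 block)
#'
#' For every interior pixel, compares each of the 24 other pixels of its
#' 5 x 5 block with the centre value \eqn{g_c}: the code is
#' \eqn{\sum_{p=0}^{23} s(g_p - g_c) 2^p} with \eqn{s(x) = 1} when
#' \eqn{x \ge 0}, neighbours taken in fixed raster (row-major) order. The
#' codes, which range over [0, 2^24 - 1], are histogrammed into `bins`
#' equal-width bins and normalised to sum to 1.
#'
#' @param img Grey image (RGB converted to luminance); needs at least a
#'   5 x 5 interior, i.e. both dimensions >= 5.
#' @param bins Histogram length (default 203).
#' @return Named numeric vector of length `bins` summing to 1.
#' @export
lbp_features <- function(img, bins = 203L) {
  check_image(img)
  g <- as_gray(img)
  h <- nrow(g); w <- ncol(g)
  if (h < 5 || w < 5) stop("image must be at least 5 x 5 for LBP",
                           call. = FALSE)
  rows <- 3:(h - 2); cols <- 3:(w - 2)
  gc <- g[rows, cols, drop = FALSE]
  code <- matrix(0, length(rows), length(cols))
  p <- 0L
  for (dr in -2:2) for (dc in -2:2) {
    if (dr == 0 && dc == 0) next
    gp <- g[rows + dr, cols + dc, drop = FALSE]
    code <- code + (gp >= gc) * 2^p
    p <- p + 1L
  }
  maxcode <- 2^24 - 1
  breaks <- seq(0, maxcode, length.out = bins + 1)
  bin <- findInterval(as.vector(code), breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = bins)
  names(counts) <- sprintf("lbp_%03d", seq_len(bins))
  counts / sum(counts)
}

# One-level 2-D Haar decomposition; pads odd dimensions by edge replication.
# Returns list(LL, LH, HL, HH) where the first letter is the row (vertical)
# filter and the second the column (horizontal) filter.
haar_dwt2 <- function(m) {
  if (nrow(m) %% 2 == 1) m <- rbind(m, m[nrow(m), , drop = FALSE])
  if (ncol(m) %% 2 == 1) m <- cbind(m, m[, ncol(m), drop = FALSE])
  ro <- seq(1, nrow(m), by = 2)
  lo_r <- (m[ro, , drop = FALSE] + m[ro + 1, , drop = FALSE]) / sqrt(2)
  hi_r <- (m[ro, , drop = FALSE] - m[ro + 1, , drop = FALSE]) / sqrt(2)
  co <- seq(1, ncol(m), by = 2)
  list(
    LL = (lo_r[, co, drop = FALSE] + lo_r[, co + 1, drop = FALSE]) / sqrt(2),
    LH = (lo_r[, co, drop = FALSE] - lo_r[, co + 1, drop = FALSE]) / sqrt(2),
    HL = (hi_r[, co, drop = FALSE] + hi_r[, co + 1, drop = FALSE]) / sqrt(2),
    HH = (hi_r[, co, drop = FALSE] - hi_r[, co + 1, drop = FALSE]) / sqrt(2)
  )
}

#' Wavelet sub-band statistics
#'
#' One-level 2-D Haar decomposition into the approximation (LL) and detail
#' (LH, HL, HH) sub-bands; each sub-band contributes its mean, standard
#' deviation and variance, in that order, giving 12 values.
#'
#' @param img Grey image (RGB converted to luminance), both dimensions >= 2.
#' @param wavelet Only "haar" is implemented.
#' @return Named numeric vector of length 12.
#' @export
dwt_features <- function(img, wavelet = "haar") {
  check_image(img)
  if (!identical(wavelet, "haar")) {
    stop("only the haar wavelet is implemented", call. = FALSE)
  }
  g <- as_gray(img)
  if (nrow(g) < 2 || ncol(g) < 2) {
    stop("image must be at least 2 x 2 for the wavelet transform",
         call. = FALSE)
  }
  bands <- haar_dwt2(g)
  out <- numeric(0)
  for (nm in c("LL", "LH", "HL", "HH")) {
    v <- as.vector(bands[[nm]])
    s <- stats::sd(v)
    if (is.na(s)) s <- 0   # single-coefficient sub-band
    vals <- c(mean(v), s, s^2)
    names(vals) <- sprintf("dwt_%s_%s", nm, c("mean", "sd", "var"))
    out <- c(out, vals)
  }
  out
}

#' Block layout of the handcrafted feature vector
#' @return Named integer vector of block widths in concatenation order.
#' @export
handcrafted_blocks <- function() {
  c(glcm = 24L, fch = 16L, lbp = 203L, dwt = 12L)
}

#' The 255-dimensional handcrafted descriptor
#'
#' Concatenates, in fixed order, the GLCM (24), fuzzy colour histogram (16),
#' local binary pattern (203) and wavelet (12) blocks. GLCM, LBP and the
#' wavelet statistics are computed on luminance; the colour histogram on the
#' RGB channels. Deterministic for a fixed input.
#'
#' @param img RGB image in [0, 255].
#' @return Named numeric vector of length 255 with a `block_map` attribute.
#' @export
handcrafted_vector <- function(img) {
  check_image(img)
  if (!is_rgb(img)) stop("handcrafted_vector needs an RGB image",
                         call. = FALSE)
  g <- as_gray(img)
  v <- c(glcm_features(g), fch_features(img), lbp_features(g),
         dwt_features(g))
  stopifnot(length(v) == 255L)
  attr(v, "block_map") <- handcrafted_blocks()
  v
}

#' Handcrafted feature matrix for a list of images
#'
#' @param images List of RGB images.
#' @return N x 255 matrix, one row per image, with a `block_map` attribute.
#' @export
handcrafted_matrix <- function(images) {
  rows <- lapply(images, handcrafted_vector)
  X <- do.call(rbind, lapply(rows, as.numeric))
  colnames(X) <- names(rows[[1]])
  attr(X, "block_map") <- handcrafted_blocks()
  X
}
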