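# Brute-force reference implementations, kept deliberately naive (nested
# loops, direct formula evaluation) and independent of the package's
# vectorised code paths.

# random test images ---------------------------------------------------------

rand_gray <- function(h, w, levels = 256) {
  matrix(sample(0:(levels - 1), h * w, replace = TRUE), h, w)
}

rand_rgb <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

# replicated-border pixel lookup
px <- function(m, i, j) {
  m[min(max(i, 1), nrow(m)), min(max(j, 1), ncol(m))]
}

# centre-excluded mean filter, nested loops
oracle_mean_filter <- function(m, window = 5) {
  r <- (window - 1) / 2
  out <- m * 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    s <- 0
    for (di in -r:r) for (dj in -r:r) {
      if (di == 0 && dj == 0) next
      s <- s + px(m, i + di, j + dj)
    }
    out[i, j] <- s / (window^2 - 1)
  }
  out
}

# 4-neighbour Laplacian, nested loops
oracle_laplacian <- function(m) {
  out <- m * 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    out[i, j] <- px(m, i - 1, j) + px(m, i + 1, j) +
      px(m, i, j - 1) + px(m, i, j + 1) - 4 * m[i, j]
  }
  out
}

# symmetric normalised co-occurrence matrix by explicit pair enumeration
oracle_glcm <- function(q, levels, offset) {
  P <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
    i2 <- i + offset[1]; j2 <- j + offset[2]
    if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
      a <- q[i, j] + 1; b <- q[i2, j2] + 1
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  P / sum(P)
}

oracle_glcm_stats <- function(P) {
  L <- nrow(P)
  con <- cor_num <- ene <- hom <- ent <- dis <- 0
  mu_i <- 0; mu_j <- 0
  for (a in 1:L) for (b in 1:L) {
    mu_i <- mu_i + (a - 1) * P[a, b]
    mu_j <- mu_j + (b - 1) * P[a, b]
  }
  var_i <- 0; var_j <- 0
  for (a in 1:L) for (b in 1:L) {
    var_i <- var_i + (a - 1 - mu_i)^2 * P[a, b]
    var_j <- var_j + (b - 1 - mu_j)^2 * P[a, b]
    con <- con + (a - b)^2 * P[a, b]
    ene <- ene + P[a, b]^2
    hom <- hom + P[a, b] / (1 + (a - b)^2)
    if (P[a, b] > 0) ent <- ent - P[a, b] * log2(P[a, b])
    dis <- dis + abs(a - b) * P[a, b]
    cor_num <- cor_num + (a - 1 - mu_i) * (b - 1 - mu_j) * P[a, b]
  }
  corr <- if (var_i * var_j == 0) 1 else cor_num / sqrt(var_i * var_j)
  c(con, corr, ene, hom, ent, dis)
}

# per-pixel 24-bit LBP codes by direct evaluation of the code sum
oracle_lbp_codes <- function(g) {
  h <- nrow(g); w <- ncol(g)
  codes <- c()
  for (i in 3:(h - 2)) for (j in 3:(w - 2)) {
    # fixed raster order: dr outer, dc inner (the package's documented order)
    p <- 0; code <- 0
    for (dr in -2:2) for (dc in -2:2) {
      if (dr == 0 && dc == 0) next
      if (g[i + dr, j + dc] >= g[i, j]) code <- code + 2^p
      p <- p + 1
    }
    codes <- c(codes, code)
  }
  codes
}

oracle_lbp_hist <- function(g, bins = 203) {
  codes <- oracle_lbp_codes(g)
  breaks <- seq(0, 2^24 - 1, length.out = bins + 1)
  counts <- numeric(bins)
  for (cd in codes) {
    k <- max(1, which(cd >= breaks[-length(breaks)] &
                        (cd < breaks[-1] | seq_len(bins) == bins)))
    k <- min(k[length(k)], bins)
    counts[k] <- counts[k] + 1
  }
  counts / sum(counts)
}

# one-level Haar transform by explicit 2x2 block arithmetic
oracle_haar <- function(m) {
  if (nrow(m) %% 2 == 1) m <- rbind(m, m[nrow(m), ])
  if (ncol(m) %% 2 == 1) m <- cbind(m, m[, ncol(m)])
  H <- nrow(m) / 2; W <- ncol(m) / 2
  LL <- LH <- HL <- HH <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    a <- m[2 * i - 1, 2 * j - 1]; b <- m[2 * i - 1, 2 * j]
    c_ <- m[2 * i, 2 * j - 1]; d <- m[2 * i, 2 * j]
    LL[i, j] <- (a + b + c_ + d) / 2
    LH[i, j] <- (a - b + c_ - d) / 2
    HL[i, j] <- (a + b - c_ - d) / 2
    HH[i, j] <- (a - b - c_ + d) / 2
  }
  list(LL = LL, LH = LH, HL = HL, HH = HH)
}

# one-vs-rest metrics by direct TP/TN/FP/FN tallies
oracle_metrics <- function(cm, k) {
  tot <- sum(cm)
  TP <- cm[k, k]
  FN <- sum(cm[k, ]) - TP
  FP <- sum(cm[, k]) - TP
  TN <- tot - TP - FN - FP
  c(accuracy = 100 * (TP + TN) / tot,
    precision = 100 * TP / (TP + FP),
    specificity = 100 * TN / (TN + FP),
    sensitivity = 100 * TP / (TP + FN))
}

# AUC by exhaustive concordance counting over all positive/negative pairs
oracle_auc <- function(score, pos) {
  s1 <- score[pos]; s0 <- score[!pos]
  conc <- 0
  for (a in s1) for (b in s0) {
    conc <- conc + (a > b) + 0.5 * (a == b)
  }
  100 * conc / (length(s1) * length(s0))
}

# direct histogram binning
oracle_bin_counts <- function(x, breaks) {
  bins <- length(breaks) - 1
  counts <- numeric(bins)
  for (v in x) {
    for (k in seq_len(bins)) {
      hi_ok <- if (k == bins) v <= breaks[k + 1] else v < breaks[k + 1]
      if (v >= breaks[k] && hi_ok) { counts[k] <- counts[k] + 1; break }
    }
  }
  counts
}
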