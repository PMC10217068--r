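# Dataset plumbing: the two-stage 80/20 split, nine-fold training-set
# augmentation, and a seeded synthetic fundus-image generator with
# class-conditioned structure (haze, blob lesions, enlarged optic disc).

#' Per-class split counts under the two-stage 80/20 rule
#'
#' Stage 1 holds out 20% of a class for testing; stage 2 holds out 20% of the
#' remainder for validation; the rest trains. Fractions are resolved to the
#' nearest integer, which reproduces the reference class tables exactly
#' (e.g. 1038 -> 664 train / 166 validation / 208 test).
#'
#' @param n Class size.
#' @return Named integer vector (train, validation, test).
#' @export
split_counts <- function(n) {
  test <- as.integer(round(0.2 * n))
  m <- as.integer(n) - test
  validation <- as.integer(round(0.2 * m))
  c(train = m - validation, validation = validation, test = test)
}

#' Split a labelled set into train/validation/test indices
#'
#' Applies [split_counts()] independently within every class; membership is
#' shuffled by `seed` but the per-class counts are deterministic functions of
#' the class sizes.
#'
#' @param labels Factor of class labels (or a `labeled_image_set`).
#' @param seed Integer seed controlling the shuffle.
#' @param min_per_class Minimum class size (default 5).
#' @return A `dataset_split`: `list(train, validation, test, counts)` of
#'   disjoint index vectors covering all indices.
#' @export
split_dataset <- function(labels, seed = 1L, min_per_class = 5L) {
  if (inherits(labels, "labeled_image_set")) labels <- labels$labels
  labels <- if (is.factor(labels)) labels else factor(labels)
  tab <- table(labels)
  if (any(tab < min_per_class)) {
    stop("every class needs at least ", min_per_class, " samples",
         call. = FALSE)
  }
  tr <- integer(0); va <- integer(0); te <- integer(0)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      k <- split_counts(length(idx))
      te <- c(te, idx[seq_len(k["test"])])
      va <- c(va, idx[k["test"] + seq_len(k["validation"])])
      tr <- c(tr, idx[(k["test"] + k["validation"]) + seq_len(k["train"])])
    }
  })
  counts <- vapply(levels(labels), function(cl) {
    c(train = sum(labels[tr] == cl), validation = sum(labels[va] == cl),
      test = sum(labels[te] == cl))
  }, integer(3))
  structure(list(train = sort(tr), validation = sort(va), test = sort(te),
                 counts = t(counts)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("dataset_split:\n")
  print(rbind(x$counts, total = colSums(x$counts)))
  invisible(x)
}

#' Write a split manifest
#' @param split A `dataset_split`.
#' @param labels The labels the split was built from.
#' @param path Output CSV path (columns index,label,partition).
#' @param paths Optional per-item source paths.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, labels, path, paths = NULL) {
  if (inherits(labels, "labeled_image_set")) {
    if (is.null(paths)) paths <- labels$paths
    labels <- labels$labels
  }
  part <- character(length(labels))
  part[split$train] <- "train"
  part[split$validation] <- "validation"
  part[split$test] <- "test"
  df <- data.frame(index = seq_along(labels), label = as.character(labels),
                   partition = part)
  if (!is.null(paths)) df$path <- paths
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# --- augmentation ----------------------------------------------------------

rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]

# Rotate a matrix by an arbitrary angle (degrees, counter-clockwise) about
# the image centre, nearest-neighbour lookup with replicated borders.
rotate_nn <- function(m, angle) {
  h <- nrow(m); w <- ncol(m)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- row(m) - cy; xx <- col(m) - cx
  # inverse mapping: source = R(-th) %*% dest
  sx <- cos(th) * xx + sin(th) * yy + cx
  sy <- -sin(th) * xx + cos(th) * yy + cy
  si <- pmin(pmax(round(sy), 1), h)
  sj <- pmin(pmax(round(sx), 1), w)
  matrix(m[cbind(as.vector(si), as.vector(sj))], h, w)
}

# Shift a matrix by (dr, dc) pixels with replicated borders.
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  si <- pmin(pmax(seq_len(h) - dr, 1), h)
  sj <- pmin(pmax(seq_len(w) - dc, 1), w)
  m[si, sj, drop = FALSE]
}

#' Nine-fold image augmentation
#'
#' Produces exactly nine variants of an image: horizontal flip, vertical
#' flip, rotations by 90, 180, 270 and +/-15 degrees, and 10% shifts along
#' each axis (replicated borders). The +/-15 degree rotations use
#' deterministic nearest-neighbour resampling, so the whole list is
#' reproducible; `seed` is accepted for interface stability but no
#' randomness is consumed.
#'
#' @param img Image array in [0, 255].
#' @param seed Unused placeholder for API stability.
#' @return Named list of 9 images.
#' @export
augment_image <- function(img, seed = 1L) {
  check_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  ops <- list(
    flip_h  = function(m) m[, rev(seq_len(ncol(m))), drop = FALSE],
    flip_v  = function(m) m[rev(seq_len(nrow(m))), , drop = FALSE],
    rot90   = function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE],
    rot180  = rot180,
    rot270  = function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
    rot_p15 = function(m) rotate_nn(m, 15),
    rot_m15 = function(m) rotate_nn(m, -15),
    shift_x = function(m) shift_mat(m, 0L, as.integer(round(0.1 * w))),
    shift_y = function(m) shift_mat(m, as.integer(round(0.1 * h)), 0L)
  )
  lapply(ops, function(f) per_channel(img, f))
}

#' Augment only the training rows of a labelled set
#'
#' Appends the nine variants of every training image to the set; validation
#' and test items are never touched (leakage guard).
#'
#' @param set A `labeled_image_set`.
#' @param split A `dataset_split` on `set`.
#' @param seed Forwarded to [augment_image()].
#' @return List with the enlarged `set` and an updated `split` whose train
#'   indices include the appended variants.
#' @export
augment_training_set <- function(set, split, seed = 1L) {
  new_imgs <- list(); new_labs <- character(0)
  for (i in split$train) {
    v <- augment_image(set$images[[i]], seed)
    new_imgs <- c(new_imgs, v)
    new_labs <- c(new_labs, rep(as.character(set$labels[i]), length(v)))
  }
  n0 <- length(set$images)
  images <- c(set$images, new_imgs)
  labels <- factor(c(as.character(set$labels), new_labs),
                   levels = set$classes)
  out_set <- labeled_image_set(images, labels)
  out_split <- split
  out_split$train <- c(split$train, n0 + seq_along(new_imgs))
  out_split$counts <- NULL  # counts no longer reflect raw class sizes
  list(set = out_set, split = out_split)
}

# --- synthetic fundus generator -------------------------------------------

#' Configuration of the synthetic fundus generator
#'
#' Class effects: cataract = global haze (convex blend towards a bright grey
#' veil), diabetic retinopathy = 5-15 small bright/dark-red blob lesions,
#' glaucoma = enlarged central bright disc (cup-to-disc style radius
#' multiplier), normal = baseline anatomy. Every image contains a circular
#' retina field, one bright optic disc and 2-4 dark vessel curves, plus
#' additive Gaussian pixel noise. Image j of each class shares its base
#' anatomy (per-image sub-seed), so zero effect sizes make the disease
#' classes bit-identical to the normal class.
#'
#' @param n_per_class Images per class (default 100).
#' @param image_size (H, W), default c(64, 64).
#' @param seed Master seed; identical seed and config give a bit-identical
#'   dataset.
#' @param haze_strength Cataract blend weight in [0, 1] (default 0.35).
#' @param lesion_count Inclusive (min, max) lesion count for retinopathy
#'   (default c(5, 15); c(0, 0) disables lesions).
#' @param lesion_intensity Lesion contrast in intensity units (default 60).
#' @param disc_enlargement Glaucoma optic-disc radius multiplier
#'   (default 1.8; 1 disables the effect).
#' @param noise_sd Gaussian pixel noise standard deviation (default 5).
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = 100L, image_size = c(64L, 64L),
                             seed = 1L, haze_strength = 0.35,
                             lesion_count = c(5L, 15L),
                             lesion_intensity = 60,
                             disc_enlargement = 1.8, noise_sd = 5) {
  if (n_per_class < 1 || any(image_size < 8)) {
    stop("n_per_class must be >= 1 and image_size at least 8 x 8",
         call. = FALSE)
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 haze_strength = haze_strength,
                 lesion_count = as.integer(lesion_count),
                 lesion_intensity = lesion_intensity,
                 disc_enlargement = disc_enlargement, noise_sd = noise_sd),
            class = "synthetic_config")
}

#' Ordered class labels used throughout the package
#' @return Character vector of the four classes.
#' @export
fundus_classes <- function() {
  c("cataract", "diabetic_retinopathy", "glaucoma", "normal")
}

# Draw one synthetic fundus image. All structural randomness (disc position,
# vessels, lesion layout, noise) is drawn in a fixed order from the current
# RNG; the class only scales deterministic effect layers, so two classes
# with zero effect sizes produce identical pixels from the same sub-seed.
gen_fundus_image <- function(class, cfg) {
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  half <- min(h, w) / 2
  yy <- (row(matrix(0, h, w)) - (h + 1) / 2) / half
  xx <- (col(matrix(0, h, w)) - (w + 1) / 2) / half
  rr <- sqrt(xx^2 + yy^2)

  # base anatomy: dark background, circular retina field with radial falloff
  base <- c(18, 10, 6)
  retina <- c(175, 85, 35)
  falloff <- pmax(0, 1 - 0.45 * rr^2)
  inside <- rr <= 0.94
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    img[, , ch] <- base[ch] + inside * (retina[ch] * falloff - base[ch])
  }

  # optic disc: bright blob, slightly off-centre; glaucoma enlarges it
  disc_dx <- stats::runif(1, -0.18, 0.18)
  disc_dy <- stats::runif(1, -0.18, 0.18)
  r_disc <- 0.13 * if (class == "glaucoma") cfg$disc_enlargement else 1
  dd <- sqrt((xx - disc_dx)^2 + (yy - disc_dy)^2)
  disc <- exp(-(dd / r_disc)^4)
  disc_col <- c(235, 205, 120)
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] + inside * disc * (disc_col[ch] - img[, , ch])
  }

  # 2-4 dark vessel curves radiating from the disc centre
  n_ves <- sample(2:4, 1)
  ves_col <- c(70, 20, 12)
  for (v in seq_len(n_ves)) {
    ang <- stats::runif(1, 0, 2 * pi)
    curv <- stats::runif(1, -1.2, 1.2)
    tt <- seq(0, 1.1, length.out = 80)
    px <- disc_dx + tt * cos(ang + curv * tt)
    py <- disc_dy + tt * sin(ang + curv * tt)
    ci <- round((py * half) + (h + 1) / 2)
    cj <- round((px * half) + (w + 1) / 2)
    ok <- ci >= 1 & ci <= h & cj >= 1 & cj <= w
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[cbind(ci[ok], cj[ok])] <- ves_col[ch]
      img[, , ch] <- pl
    }
  }

  # lesion layout is always drawn; only retinopathy renders it
  n_les <- sample(5:15, 1)
  les <- list(x = stats::runif(n_les, -0.6, 0.6),
              y = stats::runif(n_les, -0.6, 0.6),
              r = stats::runif(n_les, 0.03, 0.07),
              bright = stats::runif(n_les) < 0.5)
  n_apply <- if (class == "diabetic_retinopathy") {
    min(n_les, max(n_les, cfg$lesion_count[1]), cfg$lesion_count[2])
  } else 0L
  for (k in seq_len(n_apply)) {
    dd <- sqrt((xx - les$x[k])^2 + (yy - les$y[k])^2)
    blob <- exp(-(dd / les$r[k])^2) * inside
    delta <- cfg$lesion_intensity * if (les$bright[k]) c(1, 0.9, 0.3) else
      -c(0.8, 1, 1) * 0.9
    for (ch in 1:3) img[, , ch] <- img[, , ch] + blob * delta[ch]
  }

  # cataract: global haze towards a bright grey veil
  haze <- cfg$haze_strength * (class == "cataract")
  if (haze > 0) img <- (1 - haze) * img + haze * 205

  img <- img + array(stats::rnorm(h * w * 3, sd = cfg$noise_sd),
                     dim = c(h, w, 3))
  clip01(img)
}

#' Generate a synthetic class-per-folder style fundus dataset
#'
#' See [synthetic_config()] for the class effects. Image `j` of every class
#' is drawn from the sub-seed derived from `(seed, j)`, so the dataset is
#' bit-reproducible and classes are paired on base anatomy.
#'
#' @param cfg A [synthetic_config()].
#' @return A `labeled_image_set` in the fixed class order.
#' @export
generate_synthetic_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  images <- list(); labels <- character(0)
  for (cl in fundus_classes()) {
    for (j in seq_len(cfg$n_per_class)) {
      sub_seed <- (abs(cfg$seed) * 7919 + j * 104729) %% 2147483647
      img <- with_seed(as.integer(sub_seed), gen_fundus_image(cl, cfg))
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cl)
    }
  }
  labeled_image_set(images, factor(labels, levels = fundus_classes()))
}
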