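# split arithmetic, augmentation, synthetic generator

test_that("split_counts reproduces the reference class table", {
  expect_equal(split_counts(1038),
               c(train = 664L, validation = 166L, test = 208L))
  expect_equal(split_counts(1098),
               c(train = 702L, validation = 176L, test = 220L))
  expect_equal(split_counts(1007),
               c(train = 645L, validation = 161L, test = 201L))
  expect_equal(split_counts(1074),
               c(train = 687L, validation = 172L, test = 215L))
  expect_equal(sum(1038, 1098, 1007, 1074), 4217)

  # tiny class: nearest-integer two-stage arithmetic
  expect_equal(split_counts(5), c(train = 3L, validation = 1L, test = 1L))
  expect_equal(unname(sum(split_counts(5))), 5)
})

test_that("split_dataset yields disjoint, exhaustive, seed-stable partitions", {
  set.seed(81)
  y <- factor(rep(fundus_classes(), times = c(30, 25, 40, 35)))
  sp <- split_dataset(y, seed = 3)
  all_idx <- sort(c(sp$train, sp$validation, sp$test))
  expect_equal(all_idx, seq_along(y))
  expect_equal(anyDuplicated(c(sp$train, sp$validation, sp$test)), 0L)

  # per-class counts follow split_counts exactly
  for (cl in levels(y)) {
    n <- sum(y == cl)
    expect_equal(unname(sp$counts[cl, ]), unname(split_counts(n)))
  }

  # different seed: same counts, different membership
  sp2 <- split_dataset(y, seed = 4)
  expect_equal(sp$counts, sp2$counts)
  expect_false(identical(sp$test, sp2$test))
  # same seed: identical
  expect_identical(split_dataset(y, seed = 3), sp)

  expect_error(split_dataset(factor(rep(c("a", "b"), c(3, 10)))),
               "at least 5")
})

test_that("augment_image produces exactly 9 correct variants", {
  set.seed(82)
  img <- rand_rgb(20, 24)
  v <- augment_image(img)
  expect_length(v, 9)
  expect_named(v, c("flip_h", "flip_v", "rot90", "rot180", "rot270",
                    "rot_p15", "rot_m15", "shift_x", "shift_y"))

  # involution: rotating the 180-degree variant again restores the original
  v180 <- augment_image(v$rot180)
  expect_equal(v180$rot180, img)

  # horizontal flip equals index-reversal oracle
  flipped <- img
  for (ch in 1:3) {
    for (j in seq_len(ncol(img))) {
      flipped[, j, ch] <- img[, ncol(img) - j + 1, ch]
    }
  }
  expect_equal(v$flip_h, flipped)

  # shift: 10% of width to the right with replicated border
  dx <- round(0.1 * 24)
  expect_equal(v$shift_x[, (dx + 1):24, ], img[, 1:(24 - dx), ])
  expect_equal(v$shift_x[, 1, ], img[, 1, ])

  # all variants stay in range and keep the channel count
  for (a in v) {
    expect_true(all(a >= 0 & a <= 255))
    expect_equal(dim(a)[3], 3L)
  }
})

test_that("augment_training_set grows train 9-fold and never touches val/test", {
  set.seed(83)
  imgs <- lapply(1:20, function(i) rand_rgb(8, 8))
  y <- factor(rep(c("a", "b"), each = 10))
  set <- labeled_image_set(imgs, y)
  sp <- split_dataset(y, seed = 1)
  n_tr <- length(sp$train)
  aug <- augment_training_set(set, sp)
  expect_length(aug$split$train, 10 * n_tr)  # originals + 9 variants
  expect_identical(aug$split$validation, sp$validation)
  expect_identical(aug$split$test, sp$test)
  # validation/test images are bit-identical to the originals
  for (i in c(sp$validation, sp$test)) {
    expect_identical(aug$set$images[[i]], set$images[[i]])
  }
  # appended labels match their source class, 9 copies per original
  appended <- aug$set$labels[(length(set$images) + 1):length(aug$set$images)]
  expect_equal(as.character(appended),
               rep(as.character(y[sp$train]), each = 9))
  tab <- table(aug$set$labels[aug$split$train])
  expect_equal(unname(tab), unname(table(y[sp$train]) * 10))
})

test_that("synthetic generator is seeded, class-conditioned and monotone", {
  cfg <- synthetic_config(n_per_class = 10, image_size = c(32, 32), seed = 7)
  d1 <- generate_synthetic_dataset(cfg)
  d2 <- generate_synthetic_dataset(cfg)
  expect_identical(d1$images, d2$images)
  expect_equal(as.character(unique(d1$labels)), fundus_classes())
  expect_true(all(vapply(d1$images, function(im) all(im >= 0 & im <= 255),
                         logical(1))))

  # zero effect sizes: disease classes are bit-identical to normal
  cfg0 <- synthetic_config(n_per_class = 4, image_size = c(32, 32), seed = 7,
                           haze_strength = 0, lesion_count = c(0L, 0L),
                           disc_enlargement = 1)
  d0 <- generate_synthetic_dataset(cfg0)
  for (j in 1:4) {
    nrm <- d0$images[[which(d0$labels == "normal")[j]]]
    expect_identical(d0$images[[which(d0$labels == "cataract")[j]]], nrm)
    expect_identical(
      d0$images[[which(d0$labels == "diabetic_retinopathy")[j]]], nrm)
    expect_identical(d0$images[[which(d0$labels == "glaucoma")[j]]], nrm)
  }

  # cataract haze raises mean luminance over normal (paired by sub-seed)
  cfgL <- synthetic_config(n_per_class = 100, image_size = c(32, 32),
                           seed = 9)
  dL <- generate_synthetic_dataset(cfgL)
  lum <- vapply(dL$images, function(im) mean(as_gray(im)), numeric(1))
  cat_lum <- lum[dL$labels == "cataract"]
  nrm_lum <- lum[dL$labels == "normal"]
  expect_gt(mean(cat_lum), mean(nrm_lum))
  expect_lt(stats::t.test(nrm_lum, cat_lum, alternative = "less")$p.value,
            1e-6)

  # monotone effect: stronger haze, larger luminance shift
  shift <- vapply(c(0.1, 0.3, 0.5), function(hz) {
    cfgH <- synthetic_config(n_per_class = 20, image_size = c(32, 32),
                             seed = 5, haze_strength = hz)
    dH <- generate_synthetic_dataset(cfgH)
    lumH <- vapply(dH$images, function(im) mean(as_gray(im)), numeric(1))
    mean(lumH[dH$labels == "cataract"]) - mean(lumH[dH$labels == "normal"])
  }, numeric(1))
  expect_true(all(diff(shift) > 0))

  expect_error(synthetic_config(n_per_class = 0), "n_per_class")
})

test_that("image folder round trip preserves labels and pixel data", {
  cfg <- synthetic_config(n_per_class = 3, image_size = c(16, 16), seed = 2)
  ds <- generate_synthetic_dataset(cfg)
  root <- withr::local_tempdir()
  write_image_folder(ds, root)
  back <- read_image_folder(root)
  expect_equal(as.character(back$labels), as.character(ds$labels))
  # PNG is lossless up to the 8-bit quantisation of writing
  expect_equal(back$images[[1]], round(ds$images[[1]]), tolerance = 0.51)
  expect_error(read_image_folder(file.path(root, "nope")), "directory")
})
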