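test_that("colour indices behave on pure and achromatic pixels", {
  mk <- function(r, g, b) {
    a <- array(0, c(4, 4, 3))
    a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b
    a
  }
  f <- extract_color_features(mk(0, 4095, 0), "RGGB")
  expect_equal(ncol(f) - 2, 17)
  expect_true(all(f$exg == 2))   # maximal on chromatic coordinates
  expect_true(all(f$exr == -1))  # minimal
  f <- extract_color_features(mk(1000, 1000, 1000), "RGGB")
  expect_true(all(abs(f$exg) < 1e-12))
  expect_true(all(is.finite(as.matrix(f[, -(1:2)]))))
})

test_that("red/blue interpolation at green positions uses the two adjacent
           same-channel pixels", {
  # 4x4 mosaic with distinct per-pixel values in every channel
  a <- array(0, c(4, 4, 3))
  a[, , 1] <- matrix(1:16, 4, 4)        # R channel
  a[, , 2] <- matrix(101:116, 4, 4)     # G
  a[, , 3] <- matrix(201:216, 4, 4)     # B
  f <- extract_color_features(a, "RGGB")
  # RGGB: green at (1,2) has R left/right (rows along dim 1 here):
  # neighbours (1,1) and (1,3) in the R channel -> mean of a[1,1,1], a[1,3,1]
  g12 <- f[f$row == 1 & f$col == 2, ]
  expect_equal(g12$r, (a[1, 1, 1] + a[1, 3, 1]) / 2)
  # B above/below; the above neighbour clamps to the border row
  expect_equal(g12$b, (a[1, 2, 3] + a[2, 2, 3]) / 2)
  # green at (2,1): R above/below -> rows 1 and 3 of column 1
  g21 <- f[f$row == 2 & f$col == 1, ]
  expect_equal(g21$r, (a[1, 1, 1] + a[3, 1, 1]) / 2)
  # B left/right; the left neighbour clamps to the border column
  expect_equal(g21$b, (a[2, 1, 3] + a[2, 2, 3]) / 2)
  # interior green (3,2): no clamping on either axis
  g32 <- f[f$row == 3 & f$col == 2, ]
  expect_equal(g32$r, (a[3, 1, 1] + a[3, 3, 1]) / 2)
  expect_equal(g32$b, (a[2, 2, 3] + a[4, 2, 3]) / 2)
  expect_error(extract_color_features(a, "XYZW"), "arg")
})

test_that("green-position parity flips between pattern families", {
  a <- array(1000, c(4, 4, 3))
  f1 <- extract_color_features(a, "RGGB")
  f2 <- extract_color_features(a, "GRBG")
  expect_true(all((f1$row + f1$col) %% 2 == 1))
  expect_true(all((f2$row + f2$col) %% 2 == 0))
})

test_that("classifier separates separable classes and collapses under
           label permutation", {
  mask <- matrix(0, 40, 40); mask[10:30, 10:30] <- 1
  rgb <- render_rgb(mask, noise_sd = 60, seed = 5)
  f <- extract_color_features(rgb, "RGGB")
  lab <- ifelse(mask[cbind(f$row, f$col)] == 1, "plant", "soil")
  cl <- train_pixel_classifier(f, lab)
  expect_gt(cl$oob_accuracy, 0.99)
  expect_equal(cl$hyperparameters$num_trees, 55)
  expect_equal(cl$hyperparameters$min_split, 4)
  # permutation null: accuracy near the majority-class rate
  perm <- withr::with_seed(9, sample(lab))
  cl0 <- train_pixel_classifier(f, perm)
  maj <- max(table(lab)) / length(lab)
  expect_lt(abs(cl0$oob_accuracy - maj), 0.12)
  expect_error(train_pixel_classifier(f, rep("soil", length(lab))),
               "single class")
})

test_that("a saved and reloaded classifier predicts identically", {
  mask <- matrix(0, 30, 30); mask[5:15, 5:25] <- 1
  rgb <- render_rgb(mask, seed = 6)
  f <- extract_color_features(rgb, "RGGB")
  cl <- train_pixel_classifier(f, ifelse(mask[cbind(f$row, f$col)] == 1,
                                         "plant", "soil"))
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(cl, path)
  cl2 <- readRDS(path)
  expect_identical(segment_image(rgb, cl), segment_image(rgb, cl2))
})

test_that("segmentation fills Bayer gaps, opens noise, keeps squares", {
  mask <- matrix(0, 40, 60); mask[10:25, 15:45] <- 1
  rgb <- render_rgb(mask, noise_sd = 60, seed = 7)
  f <- extract_color_features(rgb, "RGGB")
  cl <- train_pixel_classifier(f, ifelse(mask[cbind(f$row, f$col)] == 1,
                                         "plant", "soil"))
  seg <- segment_image(rgb, cl)
  expect_equal(dim(seg), dim(mask))
  expect_true(all(seg %in% c(0, 1)))
  # interior of the square is fully filled despite checkerboard predictions
  expect_true(all(seg[12:23, 17:43] == 1))
  # all-soil image segments to all-zero
  soil <- render_rgb(matrix(0, 40, 60), noise_sd = 60, seed = 8)
  expect_true(all(segment_image(soil, cl) == 0))
  # determinism
  expect_identical(seg, segment_image(rgb, cl))
})

test_that("3x3 opening removes isolated pixels, keeps blocks, idempotent", {
  m <- matrix(0, 20, 20)
  m[5, 5] <- 1            # isolated pixel
  m[10:19, 8:17] <- 1     # 10x10 block
  o <- open3x3(m)
  expect_equal(o[5, 5], 0)
  expect_gte(sum(o), 64)  # erosion/dilation arithmetic: >= 8x8 survives
  expect_identical(open3x3(o), o)
})

test_that("simulated scenes segment with high pixel F1", {
  withr::with_seed(21, {
    pl <- tibble::tibble(x_m = runif(15, 0.1, 0.9),
                         y_m = runif(15, 0.05, 0.45),
                         la_mm2 = runif(15, 800, 2500))
  })
  views <- sample_view_angles(1, seed = 3)
  mask <- render_views(pl, views, gsd_mm = 9, plot_length_m = 1,
                       plot_width_m = 0.5, erect_height_mm = 0)[[1]]
  rgb <- render_rgb(mask, noise_sd = 120, seed = 9)
  f <- extract_color_features(rgb, "RGGB")
  truth <- ifelse(mask[cbind(f$row, f$col)] == 1, "plant", "soil")
  # train on one half of the pixels, evaluate F1 on the full scene
  idx <- withr::with_seed(10, sample(nrow(f), nrow(f) %/% 2))
  cl <- train_pixel_classifier(f[idx, ], truth[idx])
  seg <- segment_image(rgb, cl)
  tp <- sum(seg == 1 & mask == 1)
  fp <- sum(seg == 1 & mask == 0)
  fn <- sum(seg == 0 & mask == 1)
  expect_gt(2 * tp / (2 * tp + fp + fn), 0.95)
})
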