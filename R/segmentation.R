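#' Bayer-aware colour features for plant/soil pixel classification
#'
#' At a 3 mm ground sampling distance, seedling wheat leaves are a few
#' millimetres wide, so most plant pixels are mixed pixels — and a camera's
#' Bayer mosaic means only every second pixel position carries a measured
#' green value. Features are therefore computed only at the green Bayer
#' positions of a (declared) mosaic; red and blue values at those positions
#' are replaced by the mean of the two adjacent same-channel pixels, which
#' reconstructs what the sensor measured instead of trusting demosaicing
#' output. From the resulting R, G, B triplets, four further colour spaces
#' (XYZ, linearised sRGB, HSV, CIE La*b*, D65 white point) and the
#' plant-sensitive indices ExG and ExR are derived — 17 predictors in
#' total.
#'
#' ExG and ExR are computed on chromatic (sum-normalised) coordinates
#' `r = R/(R+G+B)` etc.: `ExG = 2g - r - b`, `ExR = 1.4r - g`.
#'
#' @param rgb An `H x W x 3` numeric array, values on a `0 ..
#'   2^bit_depth - 1` scale.
#' @param bayer_pattern One of `"RGGB"`, `"BGGR"`, `"GRBG"`, `"GBRG"` —
#'   the (virtual) mosaic layout. For demosaiced imagery this declares
#'   which positions are treated as measured green.
#' @param bit_depth Bit depth of the input scale (default 12). 8-bit input
#'   is accepted; the returned tibble then carries attribute
#'   `scale_flag = "8bit"`.
#' @return A tibble with one row per green Bayer position: `row`, `col`
#'   (1-based) and the 17 predictors `r, g, b, x, y, z, srgb_r, srgb_g,
#'   srgb_b, h, s, v, l_lab, a_lab, b_lab, exr, exg`.
#' @export
extract_color_features <- function(rgb, bayer_pattern = c("RGGB", "BGGR", "GRBG", "GBRG"),
                                   bit_depth = 12) {
  bayer_pattern <- match.arg(bayer_pattern)
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  maxv <- 2^bit_depth - 1
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  idx <- green_positions(h, w, bayer_pattern)
  rows <- idx$rows; cols <- idx$cols
  # horizontal/vertical same-channel neighbour means for R and B
  nb_mean <- function(channel, horizontal) {
    d <- if (horizontal) cbind(0L, c(-1L, 1L)) else cbind(c(-1L, 1L), 0L)
    v1 <- channel[cbind(pmin(pmax(rows + d[1, 1], 1L), h),
                        pmin(pmax(cols + d[1, 2], 1L), w))]
    v2 <- channel[cbind(pmin(pmax(rows + d[2, 1], 1L), h),
                        pmin(pmax(cols + d[2, 2], 1L), w))]
    (v1 + v2) / 2
  }
  r_horiz <- idx$r_horizontal # TRUE where the R neighbours lie left/right
  rch <- rgb[, , 1]; gch <- rgb[, , 2]; bch <- rgb[, , 3]
  r <- ifelse(r_horiz, nb_mean(rch, TRUE), nb_mean(rch, FALSE))
  b <- ifelse(r_horiz, nb_mean(bch, FALSE), nb_mean(bch, TRUE))
  g <- gch[cbind(rows, cols)]

  rgb01 <- cbind(r, g, b) / maxv
  xyz <- grDevices::convertColor(rgb01, from = "sRGB", to = "XYZ")
  lab <- grDevices::convertColor(rgb01, from = "sRGB", to = "Lab")
  lin <- srgb_linearize(rgb01)
  hsv <- t(grDevices::rgb2hsv(r = r, g = g, b = b, maxColorValue = maxv))
  s <- r + g + b
  s[s == 0] <- 1 # achromatic black: chromatic coords 0, indices 0
  rc <- r / s; gc <- g / s; bc <- b / s

  out <- tibble::tibble(
    row = rows, col = cols,
    r = r, g = g, b = b,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    srgb_r = lin[, 1], srgb_g = lin[, 2], srgb_b = lin[, 3],
    h = hsv[, 1], s = hsv[, 2], v = hsv[, 3],
    l_lab = lab[, 1], a_lab = lab[, 2], b_lab = lab[, 3],
    exr = 1.4 * rc - gc, exg = 2 * gc - rc - bc
  )
  if (bit_depth == 8) attr(out, "scale_flag") <- "8bit"
  attr(out, "bayer_pattern") <- bayer_pattern
  out
}

#' @keywords internal
green_positions <- function(h, w, pattern) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  parity <- (rows + cols) %% 2L # 1 where row+col odd (1-based)
  green <- if (pattern %in% c("RGGB", "BGGR")) parity == 1L else parity == 0L
  # orientation of the same-row red neighbours at each green position
  odd_row <- rows %% 2L == 1L
  r_horizontal <- switch(pattern,
    RGGB = odd_row,   # G in R-rows (odd rows) has R left/right
    BGGR = !odd_row,
    GRBG = odd_row,
    GBRG = !odd_row
  )
  list(rows = rows[green], cols = cols[green],
       r_horizontal = r_horizontal[green])
}

srgb_linearize <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

#' Train the plant/soil pixel classifier
#'
#' A random-forest ensemble over the 17 colour predictors of
#' [extract_color_features()], with defaults 55 trees, minimum split size
#' 4, minimum leaf size 6, 6 candidate features per split and maximum tree
#' depth 95. The backing engine is \pkg{ranger}; its `min.node.size`
#' expresses the minimum leaf size, and the minimum split size is recorded
#' with the model but not separately enforced by the backend.
#'
#' @param features A data frame of predictors (any non-feature columns
#'   `row`, `col`, `label` are dropped automatically), or the output of
#'   [extract_color_features()].
#' @param labels A factor or character vector with levels `soil`, `plant`.
#' @param num_trees,min_split,min_leaf,mtry,max_depth Ensemble
#'   hyperparameters (defaults above).
#' @param seed Random seed for training (required for reproducibility;
#'   default 17).
#' @return An object of class `pixel_classifier`: the fitted ensemble, the
#'   feature schema, out-of-bag accuracy and the full hyperparameter
#'   record.
#' @export
train_pixel_classifier <- function(features, labels, num_trees = 55,
                                   min_split = 4, min_leaf = 6, mtry = 6,
                                   max_depth = 95, seed = 17) {
  labels <- factor(labels, levels = c("soil", "plant"))
  if (nlevels(droplevels(labels)) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  feat <- dplyr::select(tibble::as_tibble(features),
                        -dplyr::any_of(c("row", "col", "label")))
  stopifnot(nrow(feat) == length(labels))
  dat <- cbind(feat, .label = labels)
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = dat,
    num.trees = num_trees, mtry = min(mtry, ncol(feat)),
    min.node.size = min_leaf, max.depth = max_depth,
    probability = FALSE, seed = seed
  )
  structure(
    list(model = fit, schema = names(feat),
         oob_accuracy = 1 - fit$prediction.error,
         hyperparameters = list(num_trees = num_trees, min_split = min_split,
                                min_leaf = min_leaf, mtry = mtry,
                                max_depth = max_depth, seed = seed),
         n_train = nrow(feat),
         class_balance = as.list(table(labels)),
         bayer_pattern = attr(features, "bayer_pattern") %||% NA_character_),
    class = "pixel_classifier"
  )
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat("<pixel_classifier>", x$hyperparameters$num_trees, "trees,",
      length(x$schema), "predictors,", x$n_train, "training pixels, OOB accuracy",
      round(x$oob_accuracy, 3), "\n")
  invisible(x)
}

#' Segment an image into plant and soil pixels
#'
#' Predicts the trained ensemble at the green Bayer positions, fills the
#' unpredicted red/blue positions from their 3x3 neighbourhood, and
#' applies one binary morphological opening with a 3x3 window, which
#' removes isolated single-pixel detections.
#'
#' @param rgb An `H x W x 3` array on the classifier's training scale.
#' @param model A [train_pixel_classifier()] fit.
#' @param bayer_pattern Mosaic layout; defaults to the pattern recorded at
#'   training time.
#' @param bit_depth Input bit depth (default 12).
#' @return A binary matrix (`0` soil, `1` plant) of the source dimensions,
#'   with attribute `classifier_oob` recording provenance.
#' @export
segment_image <- function(rgb, model, bayer_pattern = NULL, bit_depth = 12) {
  stopifnot(inherits(model, "pixel_classifier"))
  pattern <- bayer_pattern %||% model$bayer_pattern
  if (is.na(pattern)) pattern <- "RGGB"
  feats <- extract_color_features(rgb, pattern, bit_depth = bit_depth)
  pred <- stats::predict(model$model,
                         data = dplyr::select(feats, dplyr::all_of(model$schema)))
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  seg <- matrix(0, h, w)
  green <- matrix(FALSE, h, w)
  green[cbind(feats$row, feats$col)] <- TRUE
  seg[cbind(feats$row, feats$col)] <- as.numeric(pred$predictions == "plant")
  brush <- EBImage::makeBrush(3, shape = "box")
  filled <- EBImage::dilate(seg, brush)
  seg[!green] <- filled[!green] # fill only the unpredicted positions
  out <- EBImage::opening(seg, brush)
  out <- matrix(as.numeric(out > 0.5), h, w)
  attr(out, "classifier_oob") <- model$oob_accuracy
  out
}

#' Binary morphological opening with a 3x3 window
#'
#' Exposed for diagnostics; [segment_image()] applies it internally.
#'
#' @param mask A binary matrix.
#' @return The opened binary matrix.
#' @export
open3x3 <- function(mask) {
  out <- EBImage::opening(mask, EBImage::makeBrush(3, shape = "box"))
  matrix(as.numeric(out > 0.5), nrow(mask), ncol(mask))
}
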