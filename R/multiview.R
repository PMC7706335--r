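#' Multiview ground-cover image
#'
#' A per-plot raster whose pixel values are the fraction of overlapping
#' views in which that pixel was classified as plant. Values near 1 mark
#' dense canopy or plant parts close to the ground; intermediate values
#' mark erect or sparse plant parts whose footprint moves with the viewing
#' angle; 0 is bare soil. `NA` marks pixels outside the buffered plot.
#'
#' @param values Numeric matrix of plant-pixel fractions in `[0, 1]`
#'   (plot frame; `NA` = masked).
#' @param n_views Number of views aggregated.
#' @param plot_id Plot identifier.
#' @param campaign Campaign label or GDD.
#' @param gsd_eff_mm Effective ground sampling distance (nominal / 3).
#' @return An object of class `mv_image`.
#' @export
mv_image <- function(values, n_views, plot_id = NA, campaign = NA,
                     gsd_eff_mm = NA_real_) {
  stopifnot(is.matrix(values), n_views >= 1)
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    stop("unmasked mv_image values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(values = values, n_views = as.integer(n_views), plot_id = plot_id,
         campaign = campaign, gsd_eff_mm = gsd_eff_mm),
    class = "mv_image"
  )
}

#' @export
print.mv_image <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("<mv_image> plot", format(x$plot_id), "campaign", format(x$campaign),
      "\n  ", nrow(x$values), "x", ncol(x$values), "px,", x$n_views,
      "views, cover range [", signif(min(v), 3), ",", signif(max(v), 3), "]\n")
  invisible(x)
}

#' Aggregate per-view plot-frame masks into a multiview image
#'
#' Pixel-wise mean of binary plant/soil masks over all views of a plot:
#' \deqn{mvImg(x, y) = \frac{1}{n_{Img}} \sum_{i=1}^{n_{Img}} segImg_{res,i}(x, y).}
#' By default every view must cover the full (buffered) plot and a single
#' denominator `n_Img` is used (`denominator = "n_views"`); partially
#' visible views would bias the mean downward. With
#' `denominator = "per_pixel"` each pixel is averaged over the views that
#' actually observe it.
#'
#' @param masks A list of plot-frame binary matrices (from
#'   [resample_to_plot()] or a simulator), identical dimensions; `NA` =
#'   masked.
#' @param denominator `"n_views"` (default) or `"per_pixel"`.
#' @param plot_id,campaign Metadata carried into the result.
#' @param gsd_eff_mm Effective GSD carried into the result (taken from the
#'   first mask's attribute when present).
#' @return An [mv_image()].
#' @export
aggregate_views <- function(masks, denominator = c("n_views", "per_pixel"),
                            plot_id = NA, campaign = NA, gsd_eff_mm = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(is.list(masks), length(masks) >= 1)
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    ids <- vapply(seq_along(masks), function(i) {
      as.character(attr(masks[[i]], "image_id") %||% i)
    }, character(1))
    bad <- ids[dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]]
    stop("mask dimension mismatch for image(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(masks)
  acc <- matrix(0, dims[1, 1], dims[2, 1])
  cnt <- matrix(0L, dims[1, 1], dims[2, 1])
  for (m in masks) {
    ok <- !is.na(m)
    acc[ok] <- acc[ok] + m[ok]
    cnt <- cnt + ok
  }
  if (denominator == "n_views") {
    vals <- acc / n
    vals[cnt < n] <- NA_real_ # pixel not observed by all views -> masked
  } else {
    vals <- acc / cnt
    vals[cnt == 0L] <- NA_real_
  }
  mv_image(vals, n_views = n, plot_id = plot_id, campaign = campaign,
           gsd_eff_mm = gsd_eff_mm %||%
             (attr(masks[[1]], "gsd_eff_mm") %||% NA_real_))
}

#' Multiview ground-cover percentiles
#'
#' For each threshold `i` (percent of the full plant-pixel fraction), the
#' share of unmasked pixels whose multiview value strictly exceeds
#' `i/100`:
#' \deqn{mvGC_i = \frac{1}{n} \sum_{j=1}^{n} [mvImg_j > i/100].}
#' The default thresholds are the ten equally spaced values 10, 20, ...,
#' 100. `mvGC` is nonincreasing in `i`; with strict inequality `i = 100`
#' is always 0.
#'
#' @param mv An [mv_image()] (or bare numeric matrix).
#' @param thresholds Percent thresholds in `(0, 100]`.
#' @return A tibble with columns `threshold` and `mvgc`, plus `plot_id`
#'   and `campaign` when available.
#' @export
gc_percentiles <- function(mv, thresholds = seq(10, 100, by = 10)) {
  if (any(thresholds <= 0) || any(thresholds > 100)) {
    stop("thresholds must lie in (0, 100]", call. = FALSE)
  }
  vals <- if (inherits(mv, "mv_image")) mv$values else mv
  v <- vals[!is.na(vals)]
  if (length(v) == 0L) stop("empty unmasked region", call. = FALSE)
  out <- tibble::tibble(
    threshold = thresholds,
    mvgc = vapply(thresholds, function(i) mean(v > i / 100), numeric(1))
  )
  if (inherits(mv, "mv_image")) {
    out$plot_id <- mv$plot_id
    out$campaign <- mv$campaign
  }
  out
}

#' Apparent leaf area of a multiview image
#'
#' Sum of squared plant-pixel fractions over the unmasked plot:
#' \deqn{LA = \sum_j mvImg_j^2} (pixel^2 units). Squaring down-weights the
#' fractional halo produced by erect plant parts under the off-nadir-heavy
#' zenith-angle distribution of drone imagery, so the sum tracks projected
#' leaf area rather than the blur envelope. The exponent is configurable
#' for other viewing geometries.
#'
#' @param mv An [mv_image()] (or bare numeric matrix).
#' @param exponent Exponent applied to fractions before summing
#'   (default 2).
#' @return The apparent leaf area (numeric, pixel^2 units).
#' @seealso [la_to_mm2()] for conversion to mm^2.
#' @export
apparent_leaf_area <- function(mv, exponent = 2) {
  vals <- if (inherits(mv, "mv_image")) mv$values else mv
  v <- vals[!is.na(vals)]
  if (length(v) == 0L) stop("empty unmasked region", call. = FALSE)
  sum(v^exponent)
}

#' Convert apparent leaf area from pixel^2 units to mm^2
#'
#' @param la Apparent leaf area in pixel units ([apparent_leaf_area()]).
#' @param gsd_eff_mm Effective ground sampling distance (mm/pixel).
#' @return Leaf area in mm^2 (one fully covered pixel contributes
#'   `gsd_eff_mm^2`).
#' @export
la_to_mm2 <- function(la, gsd_eff_mm) {
  stopifnot(gsd_eff_mm > 0)
  la * gsd_eff_mm^2
}
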