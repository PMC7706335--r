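#' Watershed configuration for plant counting
#'
#' @param i_thresh Plant-pixel fraction above which a pixel can belong to
#'   a watershed region (default 0.10).
#' @param i_peak Minimum fraction of a local maximum used as a region seed
#'   (default 0.30). Must satisfy `0 < i_thresh <= i_peak <= 1`.
#' @param d_min Minimum separation of seeds in pixels (default 8,
#'   corresponding to 25 mm at a 3 mm nominal / 1 mm effective GSD).
#' @param a_w,b_w Slope and intercept of the region-size to plant-count
#'   regression ([calibrate_watershed()]); `NA` until calibrated.
#' @return An object of class `watershed_config`.
#' @export
watershed_config <- function(i_thresh = 0.10, i_peak = 0.30, d_min = 8,
                             a_w = NA_real_, b_w = NA_real_) {
  if (!(i_thresh > 0 && i_thresh <= i_peak && i_peak <= 1)) {
    stop("need 0 < i_thresh <= i_peak <= 1", call. = FALSE)
  }
  if (d_min < 1) stop("d_min must be >= 1 pixel", call. = FALSE)
  structure(list(i_thresh = i_thresh, i_peak = i_peak, d_min = d_min,
                 a_w = a_w, b_w = b_w),
            class = "watershed_config")
}

#' Local maxima of a multiview image
#'
#' Peaks are pixels whose value exceeds `i_peak` and is not smaller than
#' any 8-neighbour; a connected plateau counts as one peak at its
#' (rounded) centroid. Peaks closer than `d_min` are suppressed greedily
#' in decreasing-value order, ties broken by scan order (rows, then
#' columns), which makes the result deterministic.
#'
#' @param values Numeric matrix (`NA` treated as background).
#' @param i_peak Minimum peak value.
#' @param d_min Minimum pairwise peak distance in pixels.
#' @return A tibble with `row`, `col`, `value` of the retained peaks.
#' @export
find_peaks <- function(values, i_peak, d_min) {
  v <- values
  v[is.na(v)] <- -Inf
  h <- nrow(v); w <- ncol(v)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- v
  nb_max <- matrix(-Inf, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb_max <- pmax(nb_max, pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)])
  }
  cand <- v > i_peak & v >= nb_max
  if (!any(cand)) return(tibble::tibble(row = integer(), col = integer(),
                                        value = numeric()))
  lab <- EBImage::bwlabel(cand * 1)
  labs <- sort(unique(lab[lab > 0]))
  peaks <- purrr::map(labs, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    tibble::tibble(row = round(mean(idx[, 1])), col = round(mean(idx[, 2])),
                   value = max(v[idx]))
  }) |> dplyr::bind_rows()
  peaks <- peaks[order(-peaks$value, peaks$row, peaks$col), ]
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (peaks$row[keep] - peaks$row[i])^2 + (peaks$col[keep] - peaks$col[i])^2
    keep[i] <- all(d2 >= d_min^2)
  }
  peaks[keep, ]
}

#' Watershed regions of plant cover
#'
#' Partitions the superlevel set `mvImg > i_thresh` among the local maxima
#' of [find_peaks()] by seeded region growing (the watershed of the
#' inverted intensity landscape restricted to the thresholded mask).
#' Region areas, in dependence of the growth stage, correlate with the
#' number of plants they contain and are the predictor of
#' [predict_plant_count()].
#'
#' @param mv An [mv_image()] or numeric matrix.
#' @param cfg A [watershed_config()].
#' @return A tibble with one row per region: `region`, `area_px`,
#'   `peak_row`, `peak_col`, `peak_value`. Zero rows when the image has no
#'   peaks (zero plants).
#' @export
watershed_regions <- function(mv, cfg = watershed_config()) {
  stopifnot(inherits(cfg, "watershed_config"))
  vals <- if (inherits(mv, "mv_image")) mv$values else mv
  v <- vals
  v[is.na(v)] <- 0
  peaks <- find_peaks(vals, cfg$i_peak, cfg$d_min)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(region = integer(), area_px = numeric(),
                          peak_row = integer(), peak_col = integer(),
                          peak_value = numeric()))
  }
  seeds <- matrix(0L, nrow(v), ncol(v))
  seeds[cbind(peaks$row, peaks$col)] <- seq_len(nrow(peaks))
  mask <- (v > cfg$i_thresh) * 1
  lab <- EBImage::propagate(x = v, seeds = seeds, mask = mask)
  lab <- matrix(as.integer(round(lab)), nrow(v), ncol(v))
  areas <- tabulate(lab[lab > 0], nbins = nrow(peaks))
  tibble::tibble(region = seq_len(nrow(peaks)), area_px = as.numeric(areas),
                 peak_row = peaks$row, peak_col = peaks$col,
                 peak_value = peaks$value)
}

#' Calibrate the watershed region-size to plant-count regression
#'
#' Ordinary least squares of true plants-per-region on region area:
#' \eqn{count = a_W \cdot A + b_W}. Truth counts come from manually
#' identified plant positions in high-resolution imagery (or simulator
#' ground truth), assigned to the region containing them. Supports
#' stratified fits (e.g. separate calibrations at 5/10/15 days before
#' GS30) via a grouping column.
#'
#' @param data A data frame with columns `area_px` and `count` (plants in
#'   the region), and optionally the `stratify` column.
#' @param stratify Optional name of a column to fit within (default
#'   `NULL`: one pooled fit).
#' @return A tibble with `a_w`, `b_w`, `r_squared`, `n_regions` (one row
#'   per stratum).
#' @export
calibrate_watershed <- function(data, stratify = NULL) {
  stopifnot(all(c("area_px", "count") %in% names(data)))
  fit1 <- function(d) {
    if (nrow(d) < 2) stop("degenerate calibration: fewer than 2 regions",
                          call. = FALSE)
    if (stats::sd(d$area_px) == 0) {
      stop("zero variance in region areas", call. = FALSE)
    }
    if (nrow(d) < 10) {
      warning("watershed calibration on only ", nrow(d), " regions",
              call. = FALSE)
    }
    fit <- stats::lm(count ~ area_px, data = d)
    tibble::tibble(a_w = stats::coef(fit)[["area_px"]],
                   b_w = stats::coef(fit)[["(Intercept)"]],
                   r_squared = summary(fit)$r.squared,
                   n_regions = nrow(d))
  }
  if (is.null(stratify)) return(fit1(tibble::as_tibble(data)))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(stratify))) |>
    dplyr::group_modify(~ fit1(.x)) |>
    dplyr::ungroup()
}

#' Predict the plant count of a plot from watershed region areas
#'
#' \deqn{\hat N_{plants} = \sum_j (a_W A_j + b_W),} floored at zero. The
#' intercept is applied per region, consistent with the per-region
#' calibration; the alternative convention (intercept applied once per
#' plot) is reported as attribute `intercept_once` for diagnostics.
#'
#' @param areas Numeric vector of region areas (pixels), or the tibble
#'   from [watershed_regions()].
#' @param a_w,b_w Calibration coefficients ([calibrate_watershed()]).
#' @return The predicted plant count (numeric), with attributes
#'   `contributions` (per-region) and `intercept_once`.
#' @export
predict_plant_count <- function(areas, a_w, b_w) {
  if (is.data.frame(areas)) areas <- areas$area_px
  if (is.na(a_w) || is.na(b_w)) {
    stop("watershed calibration (a_w, b_w) required before prediction",
         call. = FALSE)
  }
  contrib <- a_w * areas + b_w
  out <- max(sum(contrib), 0)
  attr(out, "contributions") <- contrib
  attr(out, "intercept_once") <- max(sum(a_w * areas) + b_w * (length(areas) > 0), 0)
  out
}

#' Plant count intermediate-level trait
#'
#' The per-plot median across spatially corrected time-point plant
#' counts — robust to one corrupted campaign among three.
#'
#' @param data A data frame with columns `plot_id` and `value` (corrected
#'   time-point plant counts), or a bare numeric vector.
#' @return A tibble `plot_id`, `plant_count` (or a single median for a
#'   vector input).
#' @export
plant_count_trait <- function(data) {
  if (is.numeric(data)) return(stats::median(data))
  stopifnot(all(c("plot_id", "value") %in% names(data)))
  data |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(plant_count = stats::median(.data$value), .groups = "drop")
}
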