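#' Train the GS30 support-vector regressor
#'
#' The erection of pseudostems around the beginning of stem elongation
#' (growth stage GS30) changes the distribution of plant-pixel fractions
#' in multiview images. A radial-kernel support-vector regressor maps the
#' ten ground-cover percentiles of a plot/campaign to its thermal-time
#' offset from GS30 (`dgdd`). Training pairs are filtered to a window of
#' +/- 20 degree days around GS30, where the structural signal lives.
#'
#' @param data A data frame with the ten percentile columns `mvgc_10`,
#'   `mvgc_20`, ..., `mvgc_100` and a response column `dgdd`
#'   (\eqn{\Delta GDD_{GS30}} from manual reference measurements).
#' @param window Training window in degree days (default 20); rows with
#'   `|dgdd| > window` are dropped.
#' @param cost,gamma SVM hyperparameters (defaults 32 and 0.125).
#' @param min_samples Minimum number of filtered training rows
#'   (default 20).
#' @return An object of class `gs30_model` holding the fitted SVM, the
#'   feature schema and the training response range.
#' @export
train_gs30 <- function(data, window = 20, cost = 32, gamma = 0.125,
                       min_samples = 20) {
  stopifnot(cost > 0, gamma > 0)
  schema <- gs30_schema()
  miss <- setdiff(c(schema, "dgdd"), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  keep <- dplyr::filter(data, abs(.data$dgdd) <= window)
  if (nrow(keep) < min_samples) {
    stop("only ", nrow(keep), " training rows inside +/-", window,
         " degree days (data range ", round(min(data$dgdd), 1), " .. ",
         round(max(data$dgdd), 1), "); need >= ", min_samples, call. = FALSE)
  }
  xm <- as.matrix(keep[, schema])
  # scale features and response ourselves: constant predictors (mvgc_100 is
  # always 0 under the strict threshold) would otherwise disable scaling
  # wholesale and degenerate the RBF kernel
  ctr <- colMeans(xm)
  scl <- apply(xm, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  xs <- sweep(sweep(xm, 2, ctr), 2, scl, `/`)
  y_ctr <- mean(keep$dgdd)
  y_scl <- stats::sd(keep$dgdd)
  if (!is.finite(y_scl) || y_scl < 1e-12) {
    fit <- NULL # constant response: predict the constant
    y_scl <- 1
  } else {
    fit <- e1071::svm(x = xs, y = (keep$dgdd - y_ctr) / y_scl,
                      type = "eps-regression", kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
  }
  structure(
    list(model = fit, schema = schema, window = window,
         cost = cost, gamma = gamma, n_train = nrow(keep),
         x_center = ctr, x_scale = scl, y_center = y_ctr, y_scale = y_scl,
         response_range = range(keep$dgdd)),
    class = "gs30_model"
  )
}

gs30_schema <- function() paste0("mvgc_", seq(10, 100, by = 10))

#' Predict the GS30 index (thermal-time offset) from percentiles
#'
#' @param model A [train_gs30()] fit.
#' @param data A data frame with the model's percentile columns (extra
#'   columns such as `plot_id`, `gdd`, `campaign` are carried through).
#' @return The input tibble with a `dgdd_hat` column appended.
#' @export
predict_gs30_index <- function(model, data) {
  stopifnot(inherits(model, "gs30_model"))
  miss <- setdiff(model$schema, names(data))
  if (length(miss)) {
    stop("feature schema mismatch; missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  xm <- as.matrix(data[, model$schema])
  xs <- sweep(sweep(xm, 2, model$x_center), 2, model$x_scale, `/`)
  pred <- if (is.null(model$model)) {
    rep(0, nrow(xs))
  } else {
    as.numeric(stats::predict(model$model, xs))
  }
  dplyr::mutate(tibble::as_tibble(data),
                dgdd_hat = pred * model$y_scale + model$y_center)
}

#' Blocked cross-validation of the GS30 regressor
#'
#' k-fold cross-validation with folds blocked on a grouping column
#' (genotype or year-site), so that all rows of a group land in the same
#' fold and the reported error reflects prediction for unseen groups.
#'
#' @param data Training data as for [train_gs30()], plus the blocking
#'   column.
#' @param by Name of the blocking column (e.g. `"genotype"` or
#'   `"year_site"`).
#' @param k Number of folds (default 10; capped at the number of groups).
#' @param seed Seed for the fold assignment (default 1).
#' @inheritParams train_gs30
#' @return A list with `folds` (per-fold tibble) and overall `rmse` and
#'   `rrmse` (RMSE relative to the mean absolute response; the response is
#'   centred on GS30 so a plain mean would be near zero).
#' @export
cv_gs30 <- function(data, by = "genotype", k = 10, window = 20, cost = 32,
                    gamma = 0.125, seed = 1) {
  stopifnot(by %in% names(data))
  keep <- dplyr::filter(data, abs(.data$dgdd) <= window)
  groups <- unique(keep[[by]])
  k <- min(k, length(groups))
  fold_of <- withr::with_seed(seed, sample(rep_len(seq_len(k), length(groups))))
  names(fold_of) <- as.character(groups)
  res <- purrr::map(seq_len(k), function(f) {
    test_groups <- groups[fold_of == f]
    tr <- keep[!(keep[[by]] %in% test_groups), ]
    te <- keep[keep[[by]] %in% test_groups, ]
    m <- train_gs30(tr, window = window, cost = cost, gamma = gamma,
                    min_samples = 2)
    pred <- predict_gs30_index(m, te)
    tibble::tibble(fold = f, n_test = nrow(te),
                   rmse = sqrt(mean((pred$dgdd - pred$dgdd_hat)^2)),
                   err = list(pred$dgdd - pred$dgdd_hat))
  }) |> dplyr::bind_rows()
  all_err <- unlist(res$err)
  list(folds = dplyr::select(res, -"err"),
       rmse = sqrt(mean(all_err^2)),
       rrmse = sqrt(mean(all_err^2)) / mean(abs(keep$dgdd)))
}

#' Per-plot GS30 time point from repeated index estimates
#'
#' For each plot, a line \eqn{\widehat{\Delta GDD} = a \cdot GDD + b} is
#' fitted to the index estimates of campaigns near the transition
#' (`|dgdd_hat| <= window`), after discarding campaigns whose spatial
#' repeatability falls below `min_repeatability`. The GS30 time point is
#' the zero crossing `-b/a`. The window is applied as a contiguous run
#' anchored at the steepest index increase: an RBF regressor saturates
#' towards its training mean far from support, so campaigns long before or
#' after the transition can carry index values that merely look close to
#' zero and would otherwise flatten the fitted line.
#'
#' @param estimates A data frame with columns `plot_id`, `gdd` (campaign
#'   thermal time) and `dgdd_hat` ([predict_gs30_index()] output), and
#'   optionally `repeatability` per row/campaign.
#' @param window Index window in degree days (default 20; `Inf` disables).
#' @param min_repeatability Campaigns below this repeatability are
#'   filtered out before fitting (default 0.5).
#' @return A tibble per plot: `plot_id`, `gs30_gdd`, `n_campaigns`,
#'   `slope`, `r_squared` and `status` (`"ok"`, `"too_few_campaigns"` or
#'   `"unresolvable"` for nonpositive slope).
#' @export
gs30_timepoint <- function(estimates, window = 20, min_repeatability = 0.5) {
  stopifnot(all(c("plot_id", "gdd", "dgdd_hat") %in% names(estimates)))
  x <- tibble::as_tibble(estimates)
  if ("repeatability" %in% names(x)) {
    x <- dplyr::filter(x, is.na(.data$repeatability) |
                         .data$repeatability >= min_repeatability)
  }
  x |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$gdd)
      d <- d[transition_run(d$gdd, d$dgdd_hat, window), ]
      if (nrow(d) < 2) {
        return(tibble::tibble(gs30_gdd = NA_real_, n_campaigns = nrow(d),
                              slope = NA_real_, r_squared = NA_real_,
                              status = "too_few_campaigns"))
      }
      fit <- stats::lm(dgdd_hat ~ gdd, data = d)
      a <- stats::coef(fit)[["gdd"]]
      b <- stats::coef(fit)[["(Intercept)"]]
      if (!is.finite(a) || a <= 0) {
        return(tibble::tibble(gs30_gdd = NA_real_, n_campaigns = nrow(d),
                              slope = a, r_squared = NA_real_,
                              status = "unresolvable"))
      }
      tibble::tibble(gs30_gdd = -b / a, n_campaigns = nrow(d), slope = a,
                     r_squared = summary(fit)$r.squared, status = "ok")
    }) |>
    dplyr::ungroup()
}

# Campaigns used for the per-plot zero-crossing fit: estimates within
# +/- window on the index axis AND within +/- window in thermal time of a
# first-pass crossing located by the steepest adjacent-campaign index
# increase. Far from its training support an RBF regressor saturates back
# towards the training mean (~0), so a plain window filter would admit
# early or late campaigns whose index only looks close to the transition
# and flatten the fitted line; the index responds to thermal time with
# slope ~1, so the same window applies on both axes.
transition_run <- function(gdd, dgdd_hat, window) {
  n <- length(gdd)
  if (n < 2 || !is.finite(window)) return(abs(dgdd_hat) <= window)
  slopes <- diff(dgdd_hat) / diff(gdd)
  # candidate pairs must touch the index window
  near <- pmin(abs(dgdd_hat[-n]), abs(dgdd_hat[-1])) <= window
  slopes[!near] <- -Inf
  k <- which.max(slopes)
  if (!is.finite(slopes[k]) || slopes[k] <= 0) {
    return(abs(dgdd_hat) <= window)
  }
  c0 <- gdd[k] - dgdd_hat[k] / slopes[k] # first-pass crossing
  abs(dgdd_hat) <= window & abs(gdd - c0) <= window
}
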