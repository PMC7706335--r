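#' Prediction-error metrics for trait validation
#'
#' Errors follow the reference-minus-estimate convention
#' (\eqn{E = ref - \hat{y}}): a method that overestimates has negative
#' mean error. The relative RMSE is RMSE divided by the mean of the
#' reference values; the determination coefficient comes from the OLS of
#' estimate on reference.
#'
#' @param reference Numeric vector of reference (ground-truth) values.
#' @param estimate Numeric vector of estimated values (same length).
#' @return A one-row tibble: `n`, `bias` (mean reference - estimate),
#'   `rmse`, `rrmse`, `r_squared`, `pearson_r`, `flag` (`"ok"` or
#'   `"zero_reference_mean"` when rRMSE is undefined).
#' @examples
#' error_metrics(c(10, 20, 30), c(12, 18, 33))
#' @export
error_metrics <- function(reference, estimate) {
  stopifnot(length(reference) == length(estimate))
  ok <- is.finite(reference) & is.finite(estimate)
  reference <- reference[ok]; estimate <- estimate[ok]
  if (length(reference) < 2) stop("need at least 2 finite pairs", call. = FALSE)
  err <- reference - estimate
  rmse <- sqrt(mean(err^2))
  mref <- mean(reference)
  flag <- if (mref == 0) "zero_reference_mean" else "ok"
  fit <- stats::lm(estimate ~ reference)
  tibble::tibble(
    n = length(reference),
    bias = mean(err),
    rmse = rmse,
    rrmse = if (mref == 0) NA_real_ else rmse / mref,
    r_squared = summary(fit)$r.squared,
    pearson_r = stats::cor(reference, estimate),
    flag = flag
  )
}
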