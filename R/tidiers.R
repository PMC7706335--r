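#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the logistic LA / shoot model
#'
#' @param x A [la_shoot_model()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`).
#' @export
tidy.la_shoot_model <- function(x, ...) {
  tibble::tibble(
    term = c("asym", "a_xmid", "b_xmid", "a_scal", "b_scal"),
    estimate = c(x$asym, x$a_xmid, x$b_xmid, x$a_scal, x$b_scal)
  )
}

#' @rdname tidy.la_shoot_model
#' @export
glance.la_shoot_model <- function(x, ...) {
  tibble::tibble(
    n_groups = if (is.null(x$groups)) NA_integer_ else nrow(x$groups),
    dgdd_min = if (is.null(x$groups)) NA_real_ else min(x$groups$center),
    dgdd_max = if (is.null(x$groups)) NA_real_ else max(x$groups$center)
  )
}

#' Tidy a shoot-dynamics fit
#'
#' @param x A [fit_shoot_dynamics()] object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`.
#' @export
tidy.shoot_dynamics <- function(x, ...) {
  tibble::tibble(term = c("n_s", "a"),
                 estimate = c(x$n_s, x$a),
                 std_error = unname(x$se[c("n_s", "a")]))
}

#' @rdname tidy.shoot_dynamics
#' @export
glance.shoot_dynamics <- function(x, ...) {
  tibble::tibble(n_points = x$n_points, flag = x$flag)
}

#' Tidy a heritability result
#'
#' @param x A [repeatability_simple()] / [heritability_multi()] result.
#' @param ... Unused.
#' @return A tibble of variance components and the heritability.
#' @export
tidy.heritability_result <- function(x, ...) {
  tibble::tibble(
    term = c("sigma2_g", "sigma2_e", "h2"),
    estimate = c(x$sigma2_g, x$sigma2_e, x$h2)
  )
}

#' @rdname tidy.heritability_result
#' @export
glance.heritability_result <- function(x, ...) {
  tibble::tibble(h2 = x$h2, model = x$model_label)
}

#' Tidy a GS30 regressor
#'
#' @param x A [train_gs30()] model.
#' @param ... Unused.
#' @return A one-row tibble of hyperparameters and training summary.
#' @export
glance.gs30_model <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, window = x$window, cost = x$cost,
                 gamma = x$gamma, n_support = x$model$tot.nSV)
}

#' Tidy a spatial-correction result
#'
#' @param x A [spatial_correct()] result.
#' @param ... Unused.
#' @return The per-plot corrected tibble.
#' @export
tidy.correction_result <- function(x, ...) x$data

#' @rdname tidy.correction_result
#' @export
glance.correction_result <- function(x, ...) {
  tibble::tibble(repeatability = x$repeatability, sigma2_g = x$sigma2_g,
                 surface_used = x$surface_used,
                 kx = unname(x$knots["kx"]), ky = unname(x$knots["ky"]))
}
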