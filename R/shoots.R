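#' Logistic leaf-area / shoot-count model anchored on thermal time
#'
#' Before stem elongation, the apparent leaf area LA of a plot saturates
#' with its shoot count \eqn{N_S} following a logistic in
#' \eqn{\log(1 + N_S)}:
#' \deqn{LA = \frac{Asym}{1 + \exp\{(xmid - \log 1p(N_S)) / scal\}},}
#' with the asymptote fixed at the LA of 90% canopy cover (values above
#' 50% cover are rare before GS30, so genotype differences in the
#' asymptote are negligible) and the midpoint and scale linear in the
#' thermal-time offset from GS30:
#' \eqn{xmid = a_{xmid} \Delta GDD + b_{xmid}},
#' \eqn{scal = a_{scal} \Delta GDD + b_{scal}}.
#'
#' @param asym Asymptote (LA at 90% cover, pixel^2 units; > 0).
#' @param a_xmid,b_xmid,a_scal,b_scal Linear coefficients in
#'   \eqn{\Delta GDD_{GS30}}.
#' @param groups Optional tibble of the per-group nonlinear fits.
#' @param anova Optional ANOVA tables for the thermal-time dependence.
#' @return An object of class `la_shoot_model`.
#' @export
la_shoot_model <- function(asym, a_xmid, b_xmid, a_scal, b_scal,
                           groups = NULL, anova = NULL) {
  stopifnot(asym > 0)
  structure(list(asym = asym, a_xmid = a_xmid, b_xmid = b_xmid,
                 a_scal = a_scal, b_scal = b_scal, groups = groups,
                 anova = anova),
            class = "la_shoot_model")
}

#' @export
print.la_shoot_model <- function(x, ...) {
  cat("<la_shoot_model> Asym =", signif(x$asym, 5),
      "\n  xmid =", signif(x$a_xmid, 4), "* dGDD +", signif(x$b_xmid, 4),
      "\n  scal =", signif(x$a_scal, 4), "* dGDD +", signif(x$b_scal, 4), "\n")
  invisible(x)
}

xmid_at <- function(model, dgdd) model$a_xmid * dgdd + model$b_xmid
scal_at <- function(model, dgdd) model$a_scal * dgdd + model$b_scal

#' Forward evaluation of the logistic LA model
#'
#' @param n_s Shoot count(s).
#' @param dgdd Thermal-time offset(s) from GS30 (degree days).
#' @param model A [la_shoot_model()].
#' @return Apparent leaf area (same units as `model$asym`).
#' @export
logistic_la <- function(n_s, dgdd, model) {
  model$asym / (1 + exp((xmid_at(model, dgdd) - log1p(n_s)) / scal_at(model, dgdd)))
}

#' Fit the logistic LA / shoot model over thermal-time groups
#'
#' Triplets `(la, n_s, dgdd)` are binned into \eqn{\Delta GDD} groups with
#' an aggregation window of +/- `window` degree days. Each group gets a
#' nonlinear least-squares fit of the logistic (asymptote fixed), then the
#' per-group `xmid` and `scal` are regressed on the group centres to give
#' the four linear coefficients. When a `year` column is present, an
#' ANOVA of each parameter against thermal time and year is attached: a
#' significant thermal-time term alongside a non-significant year term
#' justifies pooling years into one model.
#'
#' @param data A data frame with columns `la`, `n_s`, `dgdd` and
#'   optionally `year`.
#' @param asym Fixed asymptote (LA at 90% cover, in the units of `la`).
#' @param window Half-width of the aggregation window in degree days
#'   (default 12.5).
#' @param min_per_group Minimum triplets per group (default 5).
#' @return A [la_shoot_model()] with the per-group fits in `$groups`.
#' @export
fit_la_shoot_model <- function(data, asym, window = 12.5, min_per_group = 5) {
  stopifnot(all(c("la", "n_s", "dgdd") %in% names(data)), asym > 0)
  d <- tibble::as_tibble(data)
  centers <- seq(floor(min(d$dgdd) / (2 * window)) * 2 * window + window,
                 max(d$dgdd) + window, by = 2 * window)
  d$center <- centers[pmin(pmax(findInterval(d$dgdd, centers - window), 1),
                           length(centers))]
  fits <- d |>
    dplyr::group_by(.data$center) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < min_per_group) return(tibble::tibble())
      if (stats::sd(g$n_s) == 0) {
        warning("flat shoot counts in group at ", key$center,
                " dGDD; scal unidentifiable, group dropped", call. = FALSE)
        return(tibble::tibble())
      }
      fit <- tryCatch(
        nls_multistart(
          la ~ asym / (1 + exp((xmid - log1p(n_s)) / scal)),
          data = cbind(g, asym = asym),
          ranges = list(xmid = stats::quantile(log1p(g$n_s), c(0.2, 0.8)),
                        scal = c(0.1, 2))
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        warning("non-convergent logistic fit in group at ", key$center,
                " dGDD; group dropped", call. = FALSE)
        return(tibble::tibble())
      }
      cf <- stats::coef(fit)
      if (cf[["scal"]] <= 0) return(tibble::tibble())
      # regress on the group's observed mean thermal time: edge bins are
      # only partially filled and their nominal centre would bias the slope
      tibble::tibble(xmid = cf[["xmid"]], scal = cf[["scal"]], n = nrow(g),
                     dgdd_mean = mean(g$dgdd),
                     year = if ("year" %in% names(g)) g$year[1] else NA)
    }) |>
    dplyr::ungroup()
  if (nrow(fits) < 3) {
    stop("fewer than 3 thermal-time groups survived fitting", call. = FALSE)
  }
  fx <- stats::lm(xmid ~ dgdd_mean, data = fits)
  fs <- stats::lm(scal ~ dgdd_mean, data = fits)
  an <- NULL
  if ("year" %in% names(data) && length(unique(fits$year)) > 1) {
    an <- list(
      xmid = stats::anova(stats::lm(xmid ~ dgdd_mean + year, data = fits)),
      scal = stats::anova(stats::lm(scal ~ dgdd_mean + year, data = fits)))
  }
  la_shoot_model(asym,
                 a_xmid = stats::coef(fx)[["dgdd_mean"]],
                 b_xmid = stats::coef(fx)[["(Intercept)"]],
                 a_scal = stats::coef(fs)[["dgdd_mean"]],
                 b_scal = stats::coef(fs)[["(Intercept)"]],
                 groups = fits, anova = an)
}

#' Shoot count from apparent leaf area (logistic inversion)
#'
#' Closed-form inverse of [logistic_la()]:
#' \deqn{\hat N_S = \exp\{xmid(\Delta GDD) - scal(\Delta GDD)
#'   \ln(Asym / LA - 1)\} - 1.}
#' Leaf areas at or above the asymptote are clamped to `0.999 * Asym`
#' with a warning; nonpositive leaf areas give zero shoots.
#'
#' @param la Apparent leaf area (units of `model$asym`).
#' @param dgdd Thermal-time offset(s) from GS30.
#' @param model A [la_shoot_model()].
#' @return Estimated shoot count(s).
#' @export
shoots_from_la <- function(la, dgdd, model) {
  stopifnot(inherits(model, "la_shoot_model"))
  la <- as.numeric(la)
  hi <- la >= model$asym
  if (any(hi)) {
    warning("leaf area at or above the asymptote; clamped to 0.999 * Asym",
            call. = FALSE)
    la[hi] <- 0.999 * model$asym
  }
  xm <- rep_len(xmid_at(model, dgdd), length(la))
  sc <- rep_len(scal_at(model, dgdd), length(la))
  out <- numeric(length(la))
  pos <- la > 0
  out[pos] <- exp(xm[pos] - sc[pos] * log(model$asym / la[pos] - 1)) - 1
  out
}

#' Fit per-plot shoot (tillering) dynamics
#'
#' An inverse exponential in the thermal-time offset from GS30,
#' \deqn{N_{S,t} = N_S - \exp(-a \cdot \Delta GDD_{GS30}),}
#' fitted to shoot-count time points in the training range
#' \eqn{-200 \le \Delta GDD < 0} (values outside are filtered to prevent
#' extrapolation). \eqn{N_S} is the final shoot count before cessation
#' (tiller abortion) and `a` the tillering rate. With fewer than three
#' usable time points, \eqn{N_S} falls back to the median of the
#' observations and `a` is left missing — the behaviour used for trials
#' with sparse early campaigns.
#'
#' @param data A data frame with columns `n_s_t` (estimated shoots at a
#'   time point) and `dgdd`.
#' @param range Inclusive lower / exclusive upper \eqn{\Delta GDD} filter
#'   (default `c(-200, 0)`).
#' @return An object of class `shoot_dynamics`: `n_s`, `a`, standard
#'   errors, `n_points` and `flag` (`"fitted"`, `"median_fallback"`).
#' @export
fit_shoot_dynamics <- function(data, range = c(-200, 0)) {
  stopifnot(all(c("n_s_t", "dgdd") %in% names(data)))
  d <- dplyr::filter(tibble::as_tibble(data),
                     .data$dgdd >= range[1], .data$dgdd < range[2])
  fallback <- function(flag) {
    structure(list(n_s = stats::median(d$n_s_t), a = NA_real_,
                   se = c(n_s = NA_real_, a = NA_real_),
                   n_points = nrow(d), flag = flag),
              class = "shoot_dynamics")
  }
  if (nrow(d) < 3) return(fallback("median_fallback"))
  fit <- tryCatch(
    nls_multistart(
      n_s_t ~ n_s - exp(-a * dgdd), data = d,
      ranges = list(n_s = c(max(d$n_s_t), max(d$n_s_t) + 30),
                    a = c(0.001, 0.05))
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fallback("median_fallback"))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(n_s = NA_real_, a = NA_real_))
  structure(list(n_s = cf[["n_s"]], a = cf[["a"]],
                 se = c(n_s = unname(se["n_s"]), a = unname(se["a"])),
                 n_points = nrow(d), flag = "fitted"),
            class = "shoot_dynamics")
}

#' @export
print.shoot_dynamics <- function(x, ...) {
  cat("<shoot_dynamics> N_S =", signif(x$n_s, 5), " a =", signif(x$a, 4),
      " (", x$flag, ",", x$n_points, "time points )\n")
  invisible(x)
}

#' Evaluate a fitted shoot-dynamics curve
#'
#' The model can yield negative values at very early thermal times; for
#' reporting the curve is clamped at zero (never during fitting).
#'
#' @param x A [fit_shoot_dynamics()] object.
#' @param dgdd Thermal-time offsets.
#' @return Predicted shoot counts, clamped at 0.
#' @export
predict_shoots <- function(x, dgdd) {
  stopifnot(inherits(x, "shoot_dynamics"))
  if (is.na(x$a)) return(rep(x$n_s, length(dgdd)))
  pmax(x$n_s - exp(-x$a * dgdd), 0)
}

# Deterministic multi-start Levenberg-Marquardt least squares: 5 starts on
# an even lattice across the given parameter ranges, best converged fit by
# residual sum of squares. Tolerance 1e-8 relative.
nls_multistart <- function(formula, data, ranges, n_starts = 5) {
  grid <- lapply(ranges, function(r) seq(min(r), max(r), length.out = n_starts))
  best <- NULL
  for (i in seq_len(n_starts)) {
    start <- lapply(grid, `[[`, i)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = start,
        control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                             maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("no multi-start fit converged", call. = FALSE)
  best$fit
}
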