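#' Spatial correction of plot values with a P-spline surface
#'
#' Field trends (soil, moisture, management gradients) are removed by
#' fitting, per campaign and trait,
#' `value ~ smooth2D(x, y) + random(row) + random(range) +
#' random(genotype)`, where the smooth is a tensor-product penalized
#' B-spline surface (second-order difference penalties, smoothing selected
#' by REML) with knots per direction equal to `ceil(knots_factor *
#' plots-in-direction)`. Corrected plot values are the sum of the
#' genotype effect (plus intercept) and the residual — i.e. the value with
#' surface, row and range trends stripped. The per-campaign repeatability
#' is the generalized heritability of the genotype effect (Cullis form,
#' \eqn{1 - \bar v_{\Delta BLUP} / (2 \hat\sigma^2_g)}), computed from the
#' full posterior covariance of the genotype coefficients.
#'
#' With very small trials the surface can have more coefficients than
#' there are plots; the basis is then shrunk and, if that is not enough,
#' the surface term is dropped with a message (row/range/genotype effects
#' are kept).
#'
#' @param values A data frame with columns `plot_id` and `value`.
#' @param design A data frame with columns `plot_id`, `x`, `y` (metric
#'   planar coordinates), `row`, `range`, `genotype`, `rep`.
#' @param knots_factor Knots per direction as a fraction of plots in that
#'   direction (default 2/3).
#' @return An object of class `correction_result`: `$data` (per-plot
#'   tibble with `corrected`, the fitted `surface`, `row_effect`,
#'   `range_effect`, `geno_effect`, `residual`), `$repeatability`,
#'   `$var_components` and the fitted `$model`.
#' @export
spatial_correct <- function(values, design, knots_factor = 2 / 3) {
  stopifnot(all(c("plot_id", "value") %in% names(values)),
            all(c("plot_id", "x", "y", "row", "range", "genotype", "rep")
                %in% names(design)))
  d <- dplyr::inner_join(tibble::as_tibble(values),
                         tibble::as_tibble(design), by = "plot_id")
  if (length(unique(d$genotype)) < 2) {
    stop("spatial correction needs >= 2 genotypes", call. = FALSE)
  }
  if (length(unique(d$rep)) < 2) {
    stop("spatial correction needs >= 2 replications", call. = FALSE)
  }
  if (all(table(d$genotype, d$rep) %in% 0:1) == FALSE &&
      length(unique(d$genotype)) == nrow(d)) {
    stop("genotype confounded with plots", call. = FALSE)
  }
  d$row_f <- factor(d$row); d$range_f <- factor(d$range)
  d$geno_f <- factor(d$genotype)
  kx <- max(3, ceiling(knots_factor * length(unique(d$row))))
  ky <- max(3, ceiling(knots_factor * length(unique(d$range))))
  n <- nrow(d)
  p_re <- nlevels(d$row_f) + nlevels(d$range_f) + nlevels(d$geno_f)
  while (kx * ky + p_re + 1 > n - 1 && (kx > 3 || ky > 3)) {
    if (kx >= ky && kx > 3) kx <- kx - 1 else if (ky > 3) ky <- ky - 1 else break
  }
  use_surface <- kx * ky + p_re + 1 <= n - 1
  if (!use_surface) {
    message("too few plots for a spline surface; fitting row/range/genotype only")
  }
  form <- if (use_surface) {
    value ~ te(x, y, k = c(kx, ky), bs = "ps", m = 2) +
      s(row_f, bs = "re") + s(range_f, bs = "re") + s(geno_f, bs = "re")
  } else {
    value ~ s(row_f, bs = "re") + s(range_f, bs = "re") + s(geno_f, bs = "re")
  }
  env <- environment()
  fit <- mgcv::gam(form, data = d, method = "REML")
  tm <- stats::predict(fit, type = "terms")
  col_of <- function(pat) {
    j <- grep(pat, colnames(tm), fixed = TRUE)
    if (length(j)) tm[, j[1]] else rep(0, n)
  }
  surface <- col_of("te(x,y)")
  row_eff <- col_of("s(row_f)")
  range_eff <- col_of("s(range_f)")
  geno_eff <- col_of("s(geno_f)")
  resid <- d$value - as.numeric(stats::fitted(fit))
  intercept <- stats::coef(fit)[["(Intercept)"]]
  out <- tibble::tibble(
    plot_id = d$plot_id, genotype = d$genotype, value = d$value,
    surface = surface, row_effect = row_eff, range_effect = range_eff,
    geno_effect = geno_eff, residual = resid,
    corrected = intercept + geno_eff + resid
  )
  # genotype variance and posterior covariance of genotype coefficients
  vc <- NULL
  utils::capture.output(vc <- mgcv::gam.vcomp(fit, rescale = TRUE))
  sg_row <- grep("geno_f", rownames(vc))
  sigma2_g <- if (length(sg_row)) vc[sg_row[1], "std.dev"]^2 else 0
  idx <- grep("s(geno_f)", names(stats::coef(fit)), fixed = TRUE)
  V <- fit$Vp[idx, idx, drop = FALSE]
  h2 <- cullis_h2(sigma2_g, V)
  structure(
    list(data = out, repeatability = h2,
         var_components = tibble::tibble(
           component = rownames(vc), std_dev = vc[, "std.dev"]),
         sigma2_g = sigma2_g, knots = c(kx = kx, ky = ky),
         surface_used = use_surface, model = fit),
    class = "correction_result"
  )
}

#' @export
print.correction_result <- function(x, ...) {
  cat("<correction_result>", nrow(x$data), "plots, repeatability",
      round(x$repeatability, 3),
      if (x$surface_used) paste0("(P-spline surface, knots ", x$knots["kx"],
                                 "x", x$knots["ky"], ")") else "(no surface)",
      "\n")
  invisible(x)
}

# Cullis generalized heritability: 1 - mean pairwise variance of BLUP
# differences / (2 sigma2_g), clamped to [0, 1].
cullis_h2 <- function(sigma2_g, V) {
  if (!is.finite(sigma2_g) || sigma2_g <= 1e-10) return(0)
  q <- nrow(V)
  if (is.null(q) || q < 2) return(0)
  vd <- 2 * (q * sum(diag(V)) - sum(V)) / (q * (q - 1))
  min(max(1 - vd / (2 * sigma2_g), 0), 1)
}

# Cullis form from lme4: only the conditional variance diagonals are
# exposed, so covariances between genotype BLUPs are ignored.
cullis_h2_lmer <- function(fit, group = "genotype") {
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_g <- vc$vcov[vc$grp == group & is.na(vc$var2) &
                        vc$var1 == "(Intercept)"][1]
  if (!is.finite(sigma2_g) || sigma2_g <= 1e-10) return(list(h2 = 0, sigma2_g = 0))
  re <- lme4::ranef(fit, condVar = TRUE)[[group]]
  pv <- as.numeric(attr(re, "postVar"))
  vd <- 2 * mean(pv)
  list(h2 = min(max(1 - vd / (2 * sigma2_g), 0), 1), sigma2_g = sigma2_g)
}

#' Within-environment repeatability of a trait
#'
#' Linear mixed model with replication fixed and genotype random
#' (`Y = R | G`); repeatability is the generalized heritability of the
#' genotype effect. For a balanced trend-free design this approaches the
#' classical \eqn{\sigma^2_g / (\sigma^2_g + \sigma^2_e / r)}.
#'
#' @param data A data frame with columns `value`, `genotype`, `rep`.
#' @return An object of class `heritability_result`.
#' @export
repeatability_simple <- function(data) {
  stopifnot(all(c("value", "genotype", "rep") %in% names(data)))
  if (length(unique(data$rep)) < 2) {
    stop("repeatability needs >= 2 replications", call. = FALSE)
  }
  d <- dplyr::mutate(tibble::as_tibble(data),
                     rep_f = factor(.data$rep), geno_f = factor(.data$genotype))
  fit <- lme4::lmer(value ~ rep_f + (1 | geno_f), data = d,
                    control = lme4::lmerControl(check.conv.singular =
                                                  lme4::.makeCC(action = "ignore", tol = 1e-4)))
  cc <- cullis_h2_lmer(fit, "geno_f")
  vc <- as.data.frame(lme4::VarCorr(fit))
  heritability_result(cc$h2, sigma2_g = cc$sigma2_g,
                      sigma2_e = vc$vcov[vc$grp == "Residual"],
                      model_label = "R | G", fit = fit)
}

#' Multi-environment generalized heritability
#'
#' Fits `Y = Yr/R | G` (year and replication-within-year fixed, genotype
#' random) when at least two replications per year-site are used, else
#' `Y = Yr | G`. Only genotypes present in every year-site enter the
#' model; heritability can be recomputed with the replication number
#' subsampled to 1 or 2 to compare against manual reference protocols.
#'
#' @param data A data frame with columns `value`, `genotype`, `year_site`,
#'   `rep`.
#' @param reps_to_use Optional number of replications per year-site to
#'   retain (first `reps_to_use` in sorted rep order, deterministic).
#' @return An object of class `heritability_result`.
#' @export
heritability_multi <- function(data, reps_to_use = NULL) {
  stopifnot(all(c("value", "genotype", "year_site", "rep") %in% names(data)))
  d <- tibble::as_tibble(data)
  if (length(unique(d$year_site)) < 2) {
    stop("multi-environment heritability needs >= 2 year-sites", call. = FALSE)
  }
  common <- d |>
    dplyr::distinct(.data$genotype, .data$year_site) |>
    dplyr::count(.data$genotype) |>
    dplyr::filter(.data$n == length(unique(d$year_site))) |>
    dplyr::pull(.data$genotype)
  if (length(common) == 0) {
    stop("genotype sets are disjoint across year-sites", call. = FALSE)
  }
  d <- dplyr::filter(d, .data$genotype %in% common)
  if (!is.null(reps_to_use)) {
    d <- d |>
      dplyr::group_by(.data$year_site) |>
      dplyr::filter(.data$rep %in% sort(unique(.data$rep))[seq_len(reps_to_use)]) |>
      dplyr::ungroup()
  }
  reps_per_ys <- d |>
    dplyr::distinct(.data$year_site, .data$rep) |>
    dplyr::count(.data$year_site) |>
    dplyr::pull(.data$n)
  d <- dplyr::mutate(d, yr_f = factor(.data$year_site),
                     rep_f = factor(.data$rep), geno_f = factor(.data$genotype))
  ctrl <- lme4::lmerControl(check.conv.singular =
                              lme4::.makeCC(action = "ignore", tol = 1e-4))
  if (min(reps_per_ys) >= 2) {
    fit <- lme4::lmer(value ~ yr_f / rep_f + (1 | geno_f), data = d,
                      control = ctrl)
    label <- "Yr/R | G"
  } else {
    fit <- lme4::lmer(value ~ yr_f + (1 | geno_f), data = d, control = ctrl)
    label <- "Yr | G"
  }
  cc <- cullis_h2_lmer(fit, "geno_f")
  vc <- as.data.frame(lme4::VarCorr(fit))
  heritability_result(cc$h2, sigma2_g = cc$sigma2_g,
                      sigma2_e = vc$vcov[vc$grp == "Residual"],
                      model_label = label, fit = fit)
}

heritability_result <- function(h2, sigma2_g, sigma2_e, model_label, fit = NULL) {
  stopifnot(h2 >= 0, h2 <= 1)
  structure(list(h2 = h2, sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 model_label = model_label, fit = fit),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat("<heritability_result>", x$model_label, " H2 =", round(x$h2, 3),
      " sigma2_g =", signif(x$sigma2_g, 4),
      " sigma2_e =", signif(x$sigma2_e, 4), "\n")
  invisible(x)
}

#' Relative efficiency of indirect selection
#'
#' Expected gain from selecting on a high-throughput proxy trait relative
#' to direct selection on the manually measured target:
#' \deqn{RE = \frac{h_{HTFP} \cdot r_G}{h_{manual}},}
#' with \eqn{h} the square roots of the heritabilities and \eqn{r_G} the
#' genotypic correlation between the methods. A zero manual heritability
#' gives an infinite relative efficiency, returned as `Inf` with
#' attribute `flag = "infinite_re"` — the regime in which the manual
#' protocol carries no selectable signal at all.
#'
#' @param h2_htfp Heritability of the high-throughput method, in `[0, 1]`.
#' @param h2_manual Heritability of the manual reference, in `[0, 1]`.
#' @param r_g Genotypic correlation in `[-1, 1]`.
#' @return The relative efficiency (numeric).
#' @examples
#' relative_efficiency(0.64, 0.16, 0.5) # = 1
#' @export
relative_efficiency <- function(h2_htfp, h2_manual, r_g) {
  stopifnot(h2_htfp >= 0, h2_htfp <= 1, h2_manual >= 0, h2_manual <= 1,
            r_g >= -1, r_g <= 1)
  if (h2_manual == 0) {
    out <- Inf
    attr(out, "flag") <- "infinite_re"
    return(out)
  }
  sqrt(h2_htfp) * r_g / sqrt(h2_manual)
}
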