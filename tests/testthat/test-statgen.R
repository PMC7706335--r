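test_that("repeatability matches the balanced closed form", {
  # sigma2_g = 4, sigma2_e = 1, 2 reps: H2 = 4 / (4 + 0.5) = 8/9
  h <- withr::with_seed(81, vapply(1:10, function(i) {
    des <- balanced_design()
    d <- dplyr::inner_join(balanced_values(des, 4, 1), des, by = "plot_id")
    repeatability_simple(d)$h2
  }, numeric(1)))
  expect_lt(abs(mean(h) - 8 / 9), 0.05)
})

test_that("permuted genotypes and duplicated plots hit the H2 extremes", {
  withr::with_seed(82, {
    # permutation null: averaged, at a trial size where the null bias of
    # the variance-component estimate is small
    h0 <- vapply(1:4, function(i) {
      des <- balanced_design(ng = 100, r = 2, n_ranges = 10)
      d <- dplyr::inner_join(balanced_values(des, 4, 1), des, by = "plot_id")
      d$genotype <- sample(d$genotype)
      repeatability_simple(d)$h2
    }, numeric(1))
    expect_lt(mean(h0), 0.25)
    des <- balanced_design()
    # exact duplicates: no within-genotype error, H2 -> 1
    d2 <- dplyr::inner_join(balanced_values(des, 4, 0.0001), des,
                            by = "plot_id")
    d2$value <- ave(d2$value, d2$genotype)
    expect_gt(suppressWarnings(repeatability_simple(d2)$h2), 0.99)
  })
  expect_error(repeatability_simple(
    tibble::tibble(value = 1:3, genotype = 1:3, rep = 1)), "replications")
})

test_that("spatial correction reproduces trend-free repeatability and
           absorbs a planar trend", {
  res <- withr::with_seed(83, lapply(1:10, function(i) {
    des <- balanced_design()
    g <- stats::rnorm(36)
    base <- 10 + g[des$genotype] + stats::rnorm(72)
    flat <- spatial_correct(
      tibble::tibble(plot_id = des$plot_id, value = base), des)
    trended <- spatial_correct(
      tibble::tibble(plot_id = des$plot_id,
                     value = base + 0.8 * des$x + 0.5 * des$y), des)
    c(flat = flat$repeatability, trended = trended$repeatability,
      rank_cor = stats::cor(
        tapply(flat$data$corrected, des$genotype[match(flat$data$plot_id,
                                                       des$plot_id)], mean),
        tapply(trended$data$corrected, des$genotype[match(trended$data$plot_id,
                                                          des$plot_id)], mean),
        method = "spearman"))
  }))
  m <- colMeans(do.call(rbind, res))
  # closed form sigma2_g/(sigma2_g + sigma2_e/r) = 2/3 within MC error
  expect_lt(abs(m["flat"] - 2 / 3), 0.1)
  # the surface absorbs the trend: repeatability shift < 0.05
  expect_lt(abs(m["trended"] - m["flat"]), 0.05)
  # genotype ranking preserved under a pure additive trend
  expect_gt(m["rank_cor"], 0.95)
})

test_that("zero genotype variance gives near-zero repeatability", {
  h <- withr::with_seed(84, vapply(1:4, function(i) {
    des <- balanced_design(ng = 100, r = 2, n_ranges = 10)
    spatial_correct(
      tibble::tibble(plot_id = des$plot_id, value = rnorm(200)),
      des)$repeatability
  }, numeric(1)))
  expect_lt(mean(h), 0.25)
})

test_that("spatial correction rejects degenerate designs", {
  des <- balanced_design()
  vals <- tibble::tibble(plot_id = des$plot_id, value = rnorm(72))
  expect_error(spatial_correct(vals, dplyr::mutate(des, genotype = 1)),
               "genotypes")
  expect_error(spatial_correct(vals, dplyr::mutate(des, rep = 1)),
               "replications")
})

test_that("corrected values decompose into intercept + genotype + residual", {
  withr::with_seed(85, {
    des <- balanced_design()
    d <- balanced_values(des, 2, 1)
    sc <- spatial_correct(d, des)
  })
  expect_true(all(is.finite(sc$data$corrected)))
  expect_gte(sc$repeatability, 0)
  expect_lte(sc$repeatability, 1)
  recon <- sc$data$surface + sc$data$row_effect + sc$data$range_effect +
    sc$data$geno_effect + sc$data$residual +
    (sc$data$corrected - sc$data$geno_effect - sc$data$residual)
  expect_equal(unname(recon), sc$data$value, tolerance = 1e-8)
})

test_that("multi-environment heritability matches the balanced closed form", {
  # sigma2_g = 1, sigma2_yr = 1, sigma2_e = 1, 2 years x 2 reps: H2 = 0.8
  h <- withr::with_seed(86, vapply(1:8, function(i) {
    g <- stats::rnorm(36)
    d <- tidyr::crossing(genotype = 1:36, rep = 1:2, year_site = 1:2)
    yr <- stats::rnorm(2)
    d$value <- 10 + g[d$genotype] + yr[d$year_site] + stats::rnorm(nrow(d))
    heritability_multi(d)$h2
  }, numeric(1)))
  expect_lt(abs(mean(h) - 0.8), 0.1)
})

test_that("heritability is nondecreasing in replications on average", {
  hh <- withr::with_seed(87, vapply(1:8, function(i) {
    g <- stats::rnorm(36)
    d <- tidyr::crossing(genotype = 1:36, rep = 1:4, year_site = 1:2)
    d$value <- 10 + g[d$genotype] + stats::rnorm(nrow(d), 0, 1.5)
    c(heritability_multi(d, reps_to_use = 1)$h2,
      heritability_multi(d, reps_to_use = 4)$h2)
  }, numeric(2)))
  expect_gt(mean(hh[2, ] - hh[1, ]), 0)
})

test_that("multi-year edge cases error or collapse as specified", {
  d <- tidyr::crossing(genotype = 1:30, rep = 1:2, year_site = 1:2)
  d$value <- withr::with_seed(89, rnorm(nrow(d)))
  # no genetic signal
  expect_lt(heritability_multi(d)$h2, 0.25)
  # disjoint genotype sets
  d2 <- d
  d2$genotype <- d2$genotype + 100 * d2$year_site
  expect_error(heritability_multi(d2), "disjoint")
  expect_error(heritability_multi(dplyr::filter(d, year_site == 1)),
               "year-sites")
  # single replication selects the Yr | G model
  h1 <- heritability_multi(d, reps_to_use = 1)
  expect_equal(h1$model_label, "Yr | G")
})

test_that("relative efficiency arithmetic and monotonicity", {
  expect_equal(relative_efficiency(0.5, 0.5, 1), 1)
  expect_equal(as.numeric(relative_efficiency(0.64, 0.16, 0.5)), 1)
  expect_equal(relative_efficiency(0.8, 0.4, 0), 0)
  re0 <- relative_efficiency(0.4, 0.5, 0.6)
  expect_gt(relative_efficiency(0.6, 0.5, 0.6), re0)
  expect_gt(relative_efficiency(0.4, 0.5, 0.8), re0)
  expect_lt(relative_efficiency(0.4, 0.7, 0.6), re0)
  inf <- relative_efficiency(0.5, 0, 0.5)
  expect_true(is.infinite(inf))
  expect_equal(attr(inf, "flag"), "infinite_re")
  expect_error(relative_efficiency(1.2, 0.5, 0.5))
})

test_that("heritability tidiers report components", {
  withr::with_seed(88, {
    des <- balanced_design(ng = 12, r = 2, n_ranges = 4)
    d <- dplyr::inner_join(balanced_values(des, 4, 1), des, by = "plot_id")
    h <- repeatability_simple(d)
  })
  td <- generics::tidy(h)
  expect_setequal(td$term, c("sigma2_g", "sigma2_e", "h2"))
  expect_equal(generics::glance(h)$model, "R | G")
})
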