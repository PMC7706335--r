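test_that("leaf-area allometry multiplies length, width and 0.835", {
  expect_equal(single_leaf_area(100, 4), 334)
  expect_equal(single_leaf_area(120, 3.5), 350.7)
  expect_error(single_leaf_area(0, 4), "positive")
})

test_that("main-stem leaves follow thermal time over the phyllochron", {
  dev <- plant_development(400, phyllochron = 75, t0 = 100,
                           leaf_area_mm2 = 340)
  expect_equal(dev$n_leaves_ms, 4)
  # pre-emergence: nothing
  dev0 <- plant_development(80, 75, 100, 340)
  expect_equal(dev0$n_shoots, 0)
  expect_equal(dev0$la_mm2, 0)
})

test_that("tiller n exists only while a * N_l_MS - b * n stays positive", {
  a <- 1.0; b <- 2.5
  for (gdd in seq(120, 900, by = 60)) {
    dev <- plant_development(gdd, 75, 100, 340, tiller_a = a, tiller_b = b,
                             max_shoots = 50)
    n_ms <- max((gdd - 100) / 75, 0)
    n_ti <- dev$n_tillers
    if (n_ti > 0) expect_gt(a * n_ms - b * n_ti, 0)
    expect_lte(a * n_ms - b * (n_ti + 1), 1e-9)
    # leaf bookkeeping: sum over existing tillers
    manual <- if (n_ti >= 1) sum(a * n_ms - b * seq_len(n_ti)) else 0
    expect_equal(dev$la_mm2, 340 * (n_ms + manual))
  }
})

test_that("leaf area is linear in the single-leaf area", {
  d1 <- plant_development(500, 75, 100, 340)
  d2 <- plant_development(500, 75, 100, 680)
  expect_equal(d2$la_mm2, 2 * d1$la_mm2)
})

test_that("shoot counts never decrease before GS30", {
  g <- genotype_params(5, seed = 9)
  grid <- seq(100, 700, by = 25)
  for (i in 1:5) {
    dev <- plant_development(grid, g$phyllochron[i], g$t0[i],
                             g$leaf_area_mm2[i])
    expect_true(all(diff(dev$n_shoots) >= 0))
    expect_true(all(dev$la_mm2 >= 0))
  }
})

test_that("genotype parameters respect the reported spreads", {
  g <- genotype_params(500, seed = 10)
  expect_true(all(g$phyllochron >= 54 & g$phyllochron <= 98))
  expect_true(all(g$t0 >= 60 & g$t0 <= 160))
  expect_true(all(g$leaf_area_mm2 >= 200 & g$leaf_area_mm2 <= 500))
  expect_lt(abs(stats::median(g$phyllochron) - 75), 2)
  # GS30 spread parameter controls the range
  g20 <- genotype_params(500, gs30_spread_days = 20, seed = 10)
  expect_lt(diff(range(g20$gs30_gdd)), 201)
  expect_gt(diff(range(g20$gs30_gdd)), 150)
})

test_that("trials are deterministic given the seed", {
  t1 <- make_trial(seed = 11)
  t2 <- make_trial(seed = 11)
  expect_identical(t1$truth_plots, t2$truth_plots)
  expect_identical(t1$plants, t2$plants)
  t3 <- make_trial(seed = 12)
  expect_false(identical(t1$truth_plots$gs30_gdd, t3$truth_plots$gs30_gdd))
})

test_that("the layout is a randomized complete block design", {
  des <- make_field_layout(sprintf("G%02d", 1:8), n_reps = 3, seed = 13)
  expect_equal(nrow(des), 24)
  tab <- table(des$genotype, des$rep)
  expect_true(all(tab == 1))
  expect_equal(anyDuplicated(des[, c("row", "range")]), 0L)
})

test_that("all-nadir views aggregate to a binary image; jittered views
           produce a fractional annulus", {
  pl <- tibble::tibble(x_m = 0.25, y_m = 0.125, la_mm2 = 1500)
  nadir <- sample_view_angles(10, seed = 14)
  nadir$zenith_deg <- 0
  mv0 <- aggregate_views(render_views(pl, nadir, gsd_mm = 3,
                                      plot_length_m = 0.5,
                                      plot_width_m = 0.25))
  expect_true(all(mv0$values %in% c(0, 1)))
  oblique <- sample_view_angles(40, seed = 15)
  mv1 <- aggregate_views(render_views(pl, oblique, gsd_mm = 3,
                                      plot_length_m = 0.5,
                                      plot_width_m = 0.25,
                                      erect_height_mm = 40))
  # centre fully covered in every view; edges fractional
  ctr <- mv1$values[round(0.125 * 3000 / 3), round(0.25 * 3000 / 3)]
  expect_equal(ctr, 1)
  expect_true(any(mv1$values > 0 & mv1$values < 1))
  expect_gte(ctr, max(mv1$values[mv1$values < 1]))
})

test_that("per-view rendered pixel counts match the returned truth exactly", {
  withr::with_seed(16, {
    pl <- tibble::tibble(x_m = runif(10, 0.05, 0.45),
                         y_m = runif(10, 0.05, 0.2),
                         la_mm2 = runif(10, 400, 2000))
  })
  views <- sample_view_angles(5, seed = 16)
  masks <- render_views(pl, views, gsd_mm = 6, plot_length_m = 0.5,
                        plot_width_m = 0.25)
  truth <- attr(masks, "truth")
  expect_equal(vapply(masks, sum, numeric(1)), truth$plant_px,
               ignore_attr = TRUE)
})

test_that("zero-parallax aggregate leaf area matches truth bookkeeping", {
  withr::with_seed(17, {
    pl <- tibble::tibble(x_m = runif(15, 0.1, 0.9),
                         y_m = runif(15, 0.05, 0.45),
                         la_mm2 = runif(15, 500, 2500))
  })
  views <- sample_view_angles(8, seed = 17)
  masks <- render_views(pl, views, gsd_mm = 3, plot_length_m = 1,
                        plot_width_m = 0.5, erect_height_mm = 0)
  mv <- aggregate_views(masks)
  la <- la_to_mm2(apparent_leaf_area(mv), attr(masks[[1]], "gsd_eff_mm"))
  # rasterization and footprint overlap cost at most a few percent
  expect_lt(abs(la - sum(pl$la_mm2)) / sum(pl$la_mm2), 0.05)
})

test_that("oversized footprints are truncated with a warning", {
  pl <- tibble::tibble(x_m = 0.05, y_m = 0.05, la_mm2 = 1e6)
  views <- sample_view_angles(1, seed = 18)
  expect_warning(render_views(pl, views, gsd_mm = 9, plot_length_m = 0.1,
                              plot_width_m = 0.1), "truncated")
})

test_that("trajectory generator encodes GS30 in the percentile shape", {
  trial <- make_trial(n_genotypes = 6, n_reps = 2, n_campaigns = 8,
                      seed = 19, gs30_spread_days = 15)
  traj <- sim_percentile_trajectories(trial, noise_gdd = 0, noise_pct = 0,
                                      seed = 19)
  # monotone nonincreasing across thresholds per row
  mv <- as.matrix(traj[, paste0("mvgc_", seq(10, 100, 10))])
  expect_true(all(apply(mv, 1, function(r) all(diff(r) <= 1e-12))))
  # determinism
  traj2 <- sim_percentile_trajectories(trial, noise_gdd = 0, noise_pct = 0,
                                       seed = 19)
  expect_identical(traj, traj2)
})

test_that("zero genotype variance in GS30 propagates to zero heritability", {
  trial <- make_trial(n_genotypes = 8, n_reps = 2, seed = 20,
                      gs30_spread_days = 0, gs30_plot_sd = 3)
  d <- dplyr::transmute(trial$truth_plots, value = gs30_gdd, genotype,
                        rep = rep)
  expect_lt(repeatability_simple(d)$h2, 0.35)
})
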