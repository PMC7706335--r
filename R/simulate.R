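#' Single-leaf area from length and width
#'
#' The standard allometric approximation for wheat leaves:
#' `LA = L x W x 0.835`.
#'
#' @param length_mm Leaf length, collar to tip (mm, > 0).
#' @param width_mm Maximum leaf width (mm, > 0).
#' @return Leaf area in mm^2.
#' @examples
#' single_leaf_area(100, 4) # 334
#' @export
single_leaf_area <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    stop("leaf length and width must be positive", call. = FALSE)
  }
  length_mm * width_mm * 0.835
}

#' Draw genotype developmental parameters
#'
#' Elite winter-wheat seedling parameters, drawn from truncated normal
#' distributions matched to the spreads observed in breeding material:
#' phyllochron with half the genotypes between 70 and 80 degree days per
#' leaf (full range 54-98), emergence thermal time with half the values
#' between 75 and 140 degree days, single-leaf area with half the values
#' between 300 and 380 mm^2 (full range 200-500), and a GS30 thermal time
#' spread over a configurable window (about 20 days in contrasting
#' year-sites, under 10 in a fast spring).
#'
#' The tiller relation constants `tiller_a`, `tiller_b` (leaves on tiller
#' n = `a * leaves_on_main_stem - b * n`) have no published values for
#' this material; the defaults 1.0 and 2.5 make the first tiller appear
#' after about three main-stem leaves, standard wheat ontogeny.
#'
#' @param n Number of genotypes.
#' @param gs30_center Centre of the GS30 distribution in GDD
#'   (default 650).
#' @param gs30_spread_days GS30 spread in days (default 20); converted at
#'   `gdd_per_day`.
#' @param gdd_per_day Thermal time per calendar day in the GS30 period
#'   (default 10 degree days).
#' @param phyllochron_mean Centre of the phyllochron distribution in
#'   degree days per leaf (default 75).
#' @param tiller_a,tiller_b Tiller relation constants (defaults 1.0, 2.5).
#' @param max_shoots Cap on shoots per plant (default 8).
#' @param seed Random seed.
#' @return A tibble with one row per genotype: `genotype`, `phyllochron`,
#'   `t0`, `leaf_area_mm2`, `gs30_gdd`, `tiller_a`, `tiller_b`,
#'   `max_shoots`.
#' @export
genotype_params <- function(n, gs30_center = 650, gs30_spread_days = 20,
                            gdd_per_day = 10, phyllochron_mean = 75,
                            tiller_a = 1.0, tiller_b = 2.5,
                            max_shoots = 8, seed = 1) {
  rtnorm <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    pmin(pmax(x, lo), hi)
  }
  spread_gdd <- gs30_spread_days * gdd_per_day
  withr::with_seed(seed, tibble::tibble(
    genotype = sprintf("G%02d", seq_len(n)),
    phyllochron = rtnorm(n, phyllochron_mean, 7.4, 54, 98),
    t0 = rtnorm(n, 107.5, 24, 60, 160),
    leaf_area_mm2 = rtnorm(n, 340, 30, 200, 500),
    gs30_gdd = stats::runif(n, gs30_center - spread_gdd / 2,
                            gs30_center + spread_gdd / 2),
    tiller_a = tiller_a, tiller_b = tiller_b, max_shoots = max_shoots
  ))
}

#' Shoots and leaf area of one plant at given thermal times
#'
#' Main-stem leaf number `(GDD - t0) / P` (clamped at 0); tiller `n`
#' exists while `a * N_l_MS - b * n > 0` and carries
#' `a * N_l_MS - b * n` leaves; plant leaf area is the single-leaf area
#' times the total leaf number.
#'
#' @param gdd Thermal-time vector.
#' @param phyllochron,t0,leaf_area_mm2,tiller_a,tiller_b,max_shoots
#'   Genotype parameters ([genotype_params()]).
#' @return A tibble with `gdd`, `n_leaves_ms`, `n_tillers`, `n_shoots`
#'   (0 before emergence), `la_mm2`.
#' @export
plant_development <- function(gdd, phyllochron, t0, leaf_area_mm2,
                              tiller_a = 1.0, tiller_b = 2.5, max_shoots = 8) {
  n_ms <- pmax((gdd - t0) / phyllochron, 0)
  n_ti <- pmin(pmax(floor(tiller_a * n_ms / tiller_b - 1e-9), 0),
               max_shoots - 1)
  # leaves summed over tillers 1..n_ti: sum(a*Nms - b*k)
  leaves_ti <- tiller_a * n_ms * n_ti - tiller_b * n_ti * (n_ti + 1) / 2
  emerged <- gdd > t0
  tibble::tibble(
    gdd = gdd,
    n_leaves_ms = n_ms,
    n_tillers = ifelse(emerged, n_ti, 0),
    n_shoots = ifelse(emerged, 1 + n_ti, 0),
    la_mm2 = ifelse(emerged, leaf_area_mm2 * (n_ms + leaves_ti), 0)
  )
}

#' Lay out a field trial
#'
#' Plots on a row-of-ranges grid; `row` indexes across the field, `range`
#' along the sowing direction. Genotypes are assigned in randomized
#' complete blocks (one block per replication).
#'
#' @param genotypes Character vector of genotype labels.
#' @param n_reps Replications (blocks).
#' @param plot_length_m,plot_width_m Plot dimensions in meters.
#' @param n_ranges Plots per range direction within a block (default: one
#'   column of plots per block).
#' @param year_site Year-site label (default "SIM1").
#' @param seed Randomization seed.
#' @return A tibble (`FieldDesign`): `plot_id`, `x`, `y`, `row`, `range`,
#'   `genotype`, `rep`, `year_site`.
#' @export
make_field_layout <- function(genotypes, n_reps, plot_length_m = 1,
                              plot_width_m = 0.5, n_ranges = NULL,
                              year_site = "SIM1", seed = 1) {
  ng <- length(genotypes)
  n_ranges <- n_ranges %||% max(1, floor(sqrt(ng)))
  n_rows <- ceiling(ng / n_ranges)
  withr::with_seed(seed + 101, {
    purrr::map(seq_len(n_reps), function(r) {
      ord <- sample(genotypes)
      idx <- seq_len(ng)
      tibble::tibble(
        genotype = ord,
        rep = r,
        range = (idx - 1) %% n_ranges + 1,
        row = (idx - 1) %/% n_ranges + 1 + (r - 1) * n_rows
      )
    }) |>
      dplyr::bind_rows() |>
      dplyr::mutate(
        plot_id = sprintf("%s_P%03d", year_site, dplyr::row_number()),
        x = (.data$range - 0.5) * plot_length_m,
        y = (.data$row - 0.5) * plot_width_m,
        year_site = year_site
      ) |>
      dplyr::select("plot_id", "x", "y", "row", "range", "genotype", "rep",
                    "year_site")
  })
}

#' Simulate a seedling wheat canopy for a trial
#'
#' Places plants along sowing rows (Poisson counts per row, positions
#' uniform or clustered around clump centres for `clumping > 0`), gives
#' each plant an emergence jitter, and evaluates shoot counts and leaf
#' area per plant on a thermal-time grid via [plant_development()]. A
#' planar spatial trend (amplitude `trend_gs30` GDD across the field
#' diagonal) and plot-level noise are added to the per-plot GS30.
#'
#' @param design A [make_field_layout()] tibble.
#' @param genos A [genotype_params()] tibble.
#' @param gdd_grid Thermal-time grid on which truth series are evaluated.
#' @param density_per_m Mean plants per meter of sowing row (default 45).
#' @param row_spacing_m Sowing-row spacing within the plot (default
#'   0.125 m).
#' @param plot_length_m,plot_width_m Plot dimensions (default 1 x 0.5 m).
#' @param clumping In `[0, 1)`: fraction of plants drawn around clump
#'   centres (seed clusters) instead of uniformly (default 0.2).
#' @param emergence_jitter_sd Per-plant emergence jitter in GDD
#'   (default 10).
#' @param trend_gs30 Amplitude of the planar GS30 field trend in GDD
#'   (default 0).
#' @param gs30_plot_sd Plot-level GS30 noise in GDD (default 4).
#' @param seed Random seed.
#' @return A list with `plants` (per-plant tibble: `plot_id`, `x_m`,
#'   `y_m`, genotype parameters with jittered `t0`), `truth_plots`
#'   (per-plot: `plant_count`, `gs30_gdd`, `trend`), and `truth_series`
#'   (per plot x gdd: `n_shoots`, `la_mm2`).
#' @export
simulate_canopy <- function(design, genos, gdd_grid, density_per_m = 45,
                            row_spacing_m = 0.125, plot_length_m = 1,
                            plot_width_m = 0.5, clumping = 0.2,
                            emergence_jitter_sd = 10, trend_gs30 = 0,
                            gs30_plot_sd = 4, seed = 1) {
  stopifnot(clumping >= 0, clumping < 1, density_per_m > 0)
  d <- dplyr::inner_join(tibble::as_tibble(design),
                         tibble::as_tibble(genos), by = "genotype")
  n_rows_plot <- max(1, floor(plot_width_m / row_spacing_m))
  xmax <- max(d$x); ymax <- max(d$y)
  withr::with_seed(seed + 202, {
    plants <- purrr::map(seq_len(nrow(d)), function(i) {
      p <- d[i, ]
      per_row <- purrr::map(seq_len(n_rows_plot), function(r) {
        n <- stats::rpois(1, density_per_m * plot_length_m)
        if (n == 0) return(NULL)
        n_clumped <- stats::rbinom(1, n, clumping)
        xs <- stats::runif(n - n_clumped, 0, plot_length_m)
        if (n_clumped > 0) {
          centers <- stats::runif(max(1, round(n_clumped / 3)), 0, plot_length_m)
          xs <- c(xs, pmin(pmax(
            sample(centers, n_clumped, replace = TRUE) +
              stats::rnorm(n_clumped, 0, 0.01), 0), plot_length_m))
        }
        tibble::tibble(x_m = xs, y_m = (r - 0.5) * row_spacing_m +
                         stats::rnorm(n, 0, 0.004))
      }) |> dplyr::bind_rows()
      if (nrow(per_row) == 0) return(NULL)
      dplyr::mutate(per_row,
                    plot_id = p$plot_id, genotype = p$genotype,
                    phyllochron = p$phyllochron,
                    t0 = p$t0 + stats::rnorm(dplyr::n(), 0, emergence_jitter_sd),
                    leaf_area_mm2 = p$leaf_area_mm2,
                    tiller_a = p$tiller_a, tiller_b = p$tiller_b,
                    max_shoots = p$max_shoots)
    }) |> dplyr::bind_rows()
    trend <- if (xmax + ymax > 0) {
      trend_gs30 * (d$x / max(xmax, 1e-9) + d$y / max(ymax, 1e-9)) / 2
    } else rep(0, nrow(d))
    truth_plots <- tibble::tibble(
      plot_id = d$plot_id, genotype = d$genotype, year_site = d$year_site,
      rep = d$rep, trend = trend,
      gs30_gdd = d$gs30_gdd + trend + stats::rnorm(nrow(d), 0, gs30_plot_sd),
      plant_count = as.numeric(table(factor(plants$plot_id,
                                            levels = d$plot_id)))
    )
  })
  truth_series <- purrr::map(gdd_grid, function(g) {
    dev <- plant_development(g, plants$phyllochron, plants$t0,
                             plants$leaf_area_mm2, plants$tiller_a,
                             plants$tiller_b, plants$max_shoots)
    tibble::tibble(plot_id = plants$plot_id, gdd = g,
                   n_shoots = dev$n_shoots, la_mm2 = dev$la_mm2) |>
      dplyr::group_by(.data$plot_id, .data$gdd) |>
      dplyr::summarise(n_shoots = sum(.data$n_shoots),
                       la_mm2 = sum(.data$la_mm2), .groups = "drop")
  }) |> dplyr::bind_rows()
  list(plants = plants, truth_plots = truth_plots, truth_series = truth_series)
}

#' Sample multiview zenith/azimuth angles
#'
#' Zenith angles in 0-20 degrees with the highest frequency near 10 (a
#' scaled Beta(2, 2)), azimuth uniform — the viewing-geometry signature of
#' gridded drone flights over plot centres.
#'
#' @param n_views Number of views (default 40).
#' @param seed Random seed.
#' @return A tibble `image_id`, `zenith_deg`, `azimuth_deg`.
#' @export
sample_view_angles <- function(n_views = 40, seed = 1) {
  withr::with_seed(seed + 303, tibble::tibble(
    image_id = sprintf("V%03d", seq_len(n_views)),
    zenith_deg = 20 * stats::rbeta(n_views, 2, 2),
    azimuth_deg = stats::runif(n_views, 0, 360)
  ))
}

#' Render per-view binary plant masks for one plot
#'
#' Each plant is a flat-top disk whose area equals its current leaf area.
#' A fraction of the plant (its erect parts, at effective height
#' `erect_height_mm`) shifts with the viewing direction: in a view with
#' zenith angle theta and azimuth phi the disk centre moves by
#' `tan(theta) * erect_height_mm` along `phi`. Averaging the binary masks
#' over views therefore produces the fractional annulus around each plant
#' that multiview ground-cover images show for erect or sparse plant
#' parts; with all-nadir views the aggregate stays binary.
#'
#' @param plants_la A tibble with `x_m`, `y_m`, `la_mm2` (one row per
#'   plant; e.g. [simulate_canopy()] plants joined with a campaign's
#'   leaf area).
#' @param views A [sample_view_angles()] tibble.
#' @param gsd_mm Nominal GSD (mm/pixel); rendering happens at the
#'   effective GSD `gsd_mm / 3`.
#' @param plot_length_m,plot_width_m Plot-frame extent (m).
#' @param erect_height_mm Effective height of erect plant parts (mm,
#'   default 20); 0 disables parallax.
#' @param projection_factor Fraction of a plant's leaf area that appears
#'   as ground footprint (default 1: footprint area equals leaf area).
#'   Erect seedling leaves project a reduced area; the pipeline uses 0.4
#'   so that simulated plots stay below canopy closure before GS30.
#' @return A list of binary matrices (one per view, `gsd_eff_mm`
#'   attribute set) with attribute `truth` (tibble `image_id`,
#'   `plant_px`: exact rendered plant-pixel count per view).
#' @export
render_views <- function(plants_la, views, gsd_mm = 3, plot_length_m = 1,
                         plot_width_m = 0.5, erect_height_mm = 20,
                         projection_factor = 1) {
  gsd_eff <- gsd_mm / 3
  nx <- round(plot_length_m * 1000 / gsd_eff)
  ny <- round(plot_width_m * 1000 / gsd_eff)
  r_px <- sqrt(projection_factor * pmax(plants_la$la_mm2, 0) / pi) / gsd_eff
  big <- r_px > min(nx, ny) / 2
  if (any(big)) {
    warning(sum(big), " footprint(s) larger than the plot; truncated",
            call. = FALSE)
    r_px[big] <- min(nx, ny) / 2
  }
  cx0 <- plants_la$x_m * 1000 / gsd_eff
  cy0 <- plants_la$y_m * 1000 / gsd_eff
  masks <- vector("list", nrow(views))
  truth_px <- numeric(nrow(views))
  for (v in seq_len(nrow(views))) {
    th <- views$zenith_deg[v] * pi / 180
    ph <- views$azimuth_deg[v] * pi / 180
    off <- tan(th) * erect_height_mm / gsd_eff
    m <- matrix(0, ny, nx)
    m <- stamp_disks(m, cx0 + off * cos(ph), cy0 + off * sin(ph), r_px)
    attr(m, "gsd_eff_mm") <- gsd_eff
    attr(m, "image_id") <- views$image_id[v]
    masks[[v]] <- m
    truth_px[v] <- sum(m)
  }
  attr(masks, "truth") <- tibble::tibble(image_id = views$image_id,
                                         plant_px = truth_px)
  masks
}

# stamp filled disks into a binary matrix (pixel-centre convention)
stamp_disks <- function(m, cx, cy, r) {
  ny <- nrow(m); nx <- ncol(m)
  for (i in seq_along(cx)) {
    if (r[i] <= 0) next
    jj <- max(1, floor(cx[i] - r[i])):min(nx, ceiling(cx[i] + r[i]) + 1)
    ii <- max(1, floor(cy[i] - r[i])):min(ny, ceiling(cy[i] + r[i]) + 1)
    if (length(jj) == 0 || length(ii) == 0) next
    dx2 <- ((jj - 0.5) - cx[i])^2
    dy2 <- ((ii - 0.5) - cy[i])^2
    m[ii, jj][outer(dy2, dx2, `+`) <= r[i]^2] <- 1
  }
  m
}

#' Render a colour image from a binary plant mask
#'
#' Soil pixels get a brown-grey distribution, plant pixels a green one,
#' on a 12-bit scale — the minimal colour model needed to train and test
#' the pixel classifier against a known truth mask.
#'
#' @param mask A binary matrix (1 = plant).
#' @param noise_sd Channel noise standard deviation on the 12-bit scale
#'   (default 120).
#' @param seed Random seed.
#' @param bit_depth Output bit depth (default 12).
#' @return An `H x W x 3` array.
#' @export
render_rgb <- function(mask, noise_sd = 120, seed = 1, bit_depth = 12) {
  maxv <- 2^bit_depth - 1
  sc <- maxv / 4095
  h <- nrow(mask); w <- ncol(mask)
  withr::with_seed(seed + 404, {
    soil <- c(1900, 1500, 1100) * sc
    plant <- c(900, 2300, 700) * sc
    arr <- array(0, c(h, w, 3))
    for (k in 1:3) {
      base <- ifelse(mask == 1, plant[k], soil[k])
      arr[, , k] <- pmin(pmax(base + stats::rnorm(h * w, 0, noise_sd * sc), 0),
                         maxv)
    }
    arr
  })
}

#' Assemble a complete synthetic trial
#'
#' Draws genotype parameters, lays out the field for one or more
#' year-sites, simulates the canopy, and generates a campaign schedule
#' with at least two flights per week (default interval 25 GDD at about
#' 10 GDD per day).
#'
#' @param n_genotypes,n_reps Trial dimensions (defaults 4 and 2 — the
#'   miniature fixture trial; use 36 x 2 for a realistic nursery).
#' @param n_campaigns Number of flight campaigns (default 6).
#' @param n_year_sites Number of year-sites (default 1).
#' @param campaign_interval_gdd Thermal time between campaigns
#'   (default 25).
#' @param campaign_center_offset Offset of the campaign-window centre
#'   from the mean GS30 in GDD (default 0).
#' @param plot_length_m,plot_width_m Plot dimensions (defaults 0.5 x
#'   0.25 m for the fixture; breeding nurseries typically use plots
#'   around 1 x 1.5 m).
#' @param gsd_mm Nominal ground sampling distance (default 3 mm).
#' @param density_per_m Mean plants per meter of row (default 45).
#' @param seed Master seed; all module substreams derive from it by fixed
#'   offsets.
#' @param ... Passed to [genotype_params()] (e.g. `gs30_spread_days`) and
#'   [simulate_canopy()] (e.g. `trend_gs30`, `clumping`).
#' @return A list of class `sim_trial`: `design`, `genotypes`, `plants`,
#'   `truth_plots`, `truth_series`, `campaigns` (tibble `campaign`,
#'   `gdd`), and the geometry parameters.
#' @export
make_trial <- function(n_genotypes = 4, n_reps = 2, n_campaigns = 6,
                       n_year_sites = 1, campaign_interval_gdd = 25,
                       campaign_center_offset = 0,
                       plot_length_m = 0.5, plot_width_m = 0.25,
                       gsd_mm = 3, density_per_m = 45, seed = 1, ...) {
  dots <- list(...)
  gp_args <- dots[names(dots) %in% names(formals(genotype_params))]
  sc_args <- dots[names(dots) %in% setdiff(names(formals(simulate_canopy)),
                                           c("design", "genos", "gdd_grid",
                                             "plot_length_m", "plot_width_m",
                                             "density_per_m", "seed"))]
  genos <- do.call(genotype_params,
                   c(list(n = n_genotypes, seed = seed), gp_args))
  center <- mean(genos$gs30_gdd) + campaign_center_offset
  camp_gdd <- center + (seq_len(n_campaigns) - (n_campaigns + 1) / 2) *
    campaign_interval_gdd
  campaigns <- tibble::tibble(campaign = seq_len(n_campaigns), gdd = camp_gdd)
  sites <- purrr::map(seq_len(n_year_sites), function(ys) {
    label <- sprintf("SIM%d", ys)
    design <- make_field_layout(genos$genotype, n_reps,
                                plot_length_m = plot_length_m,
                                plot_width_m = plot_width_m,
                                year_site = label, seed = seed + ys)
    canopy <- do.call(simulate_canopy,
                      c(list(design = design, genos = genos,
                             gdd_grid = camp_gdd,
                             plot_length_m = plot_length_m,
                             plot_width_m = plot_width_m,
                             density_per_m = density_per_m,
                             seed = seed + 1000 * ys), sc_args))
    list(design = design, canopy = canopy)
  })
  structure(
    list(design = dplyr::bind_rows(purrr::map(sites, "design")),
         genotypes = genos,
         plants = dplyr::bind_rows(purrr::map(sites, ~ .x$canopy$plants)),
         truth_plots = dplyr::bind_rows(purrr::map(sites, ~ .x$canopy$truth_plots)),
         truth_series = dplyr::bind_rows(purrr::map(sites, ~ .x$canopy$truth_series)),
         campaigns = campaigns,
         plot_length_m = plot_length_m, plot_width_m = plot_width_m,
         gsd_mm = gsd_mm, density_per_m = density_per_m, seed = seed),
    class = "sim_trial"
  )
}

#' @export
print.sim_trial <- function(x, ...) {
  cat("<sim_trial>", nrow(x$design), "plots (",
      nrow(x$genotypes), "genotypes ),", nrow(x$campaigns), "campaigns, seed",
      x$seed, "\n")
  invisible(x)
}

#' Simulated ground-cover percentile trajectories
#'
#' Generates the ten multiview ground-cover percentiles for every plot and
#' campaign of a trial directly from a smooth canopy-development model —
#' the fast path for testing the GS30 regression chain at scale without
#' rendering rasters. The pixel-fraction survival function is
#' `mvGC_i = c(d) * (1 - i/100)^k(d)` where the cover level `c` and shape
#' `k` both evolve smoothly with the thermal-time offset `d` from GS30
#' (the shape change encodes the pseudostem erection signal). Noise is
#' injected as a GDD-equivalent jitter of the trajectory (`noise_gdd`)
#' plus iid percentile noise (`noise_pct`).
#'
#' @param trial A [make_trial()] object.
#' @param noise_gdd GDD-equivalent trajectory noise (default 10).
#' @param noise_pct iid percentile noise SD (default 0.005).
#' @param seed Random seed (default: the trial's seed).
#' @return A tibble per plot x campaign: `plot_id`, `genotype`,
#'   `year_site`, `rep`, `campaign`, `gdd`, true `dgdd`, and `mvgc_10` ..
#'   `mvgc_100`.
#' @export
sim_percentile_trajectories <- function(trial, noise_gdd = 10,
                                        noise_pct = 0.005, seed = NULL) {
  stopifnot(inherits(trial, "sim_trial"))
  seed <- seed %||% trial$seed
  grid <- tidyr::crossing(
    dplyr::select(trial$truth_plots, "plot_id", "genotype", "year_site",
                  "rep", "gs30_gdd"),
    trial$campaigns
  ) |>
    dplyr::mutate(dgdd = .data$gdd - .data$gs30_gdd)
  th <- seq(10, 100, by = 10)
  withr::with_seed(seed + 505, {
    d_eff <- grid$dgdd + stats::rnorm(nrow(grid), 0, noise_gdd)
    cover <- 0.55 * stats::plogis((d_eff + 150) / 90)
    shape <- 1.2 + 0.8 * stats::plogis(d_eff / 40)
    mv <- purrr::map(th, function(i) {
      pmin(pmax(cover * (1 - i / 100)^shape +
                  stats::rnorm(nrow(grid), 0, noise_pct), 0), 1)
    })
    names(mv) <- paste0("mvgc_", th)
    dplyr::bind_cols(dplyr::select(grid, -"gs30_gdd"),
                     tibble::as_tibble(mv))
  })
}
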