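# shared fixtures, all generated in code

# hourly temperature table: one row per hour, `temps` degrees for each day
hourly_temps <- function(temps_per_day, start = "2019-03-02") {
  n_days <- length(temps_per_day)
  ts <- seq(as.POSIXct(paste(start, "00:00"), tz = "UTC"),
            by = "hour", length.out = 24 * n_days)
  tibble::tibble(timestamp = ts,
                 temp_c = unlist(lapply(temps_per_day, function(d) {
                   if (length(d) == 1) rep(d, 24) else d
                 })))
}

# image with Gaussian bumps at given centres (matrix ny x nx)
gaussian_blobs <- function(ny, nx, centers, sigma = 3, amplitude = 0.8) {
  x <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  y <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  v <- matrix(0, ny, nx)
  for (i in seq_len(nrow(centers))) {
    v <- v + amplitude *
      exp(-((x - centers[i, 2])^2 + (y - centers[i, 1])^2) / (2 * sigma^2))
  }
  pmin(v, 1)
}

# balanced trend-free trial: ng genotypes x r reps on a grid
balanced_design <- function(ng = 36, r = 2, n_ranges = 6) {
  n <- ng * r
  tibble::tibble(
    plot_id = sprintf("P%03d", seq_len(n)),
    genotype = unlist(lapply(seq_len(r), function(i) sample(seq_len(ng)))),
    rep = rep(seq_len(r), each = ng),
    range = (seq_len(n) - 1) %% n_ranges + 1,
    row = (seq_len(n) - 1) %/% n_ranges + 1
  ) |>
    dplyr::mutate(x = range * 1.0, y = row * 0.5)
}

balanced_values <- function(design, sigma2_g = 1, sigma2_e = 1,
                            trend = function(x, y) 0) {
  ng <- length(unique(design$genotype))
  g <- stats::rnorm(ng, 0, sqrt(sigma2_g))
  tibble::tibble(
    plot_id = design$plot_id,
    value = 10 + g[design$genotype] +
      trend(design$x, design$y) +
      stats::rnorm(nrow(design), 0, sqrt(sigma2_e))
  )
}

# simulated watershed plots: known plant positions, sigma-px footprints
sim_count_plot <- function(n_plants, ny = 80, nx = 150, sigma = 3, seed = 1) {
  withr::with_seed(seed, {
    rows_y <- c(20, 40, 60)
    centers <- cbind(
      sample(rows_y, n_plants, replace = TRUE) + stats::rnorm(n_plants, 0, 1),
      stats::runif(n_plants, 5, nx - 5)
    )
    list(values = gaussian_blobs(ny, nx, centers, sigma = sigma),
         centers = centers, n_plants = n_plants)
  })
}

# la-shoot truth model used in generate-and-refit tests
true_la_model <- function(asym = 1000) {
  la_shoot_model(asym = asym, a_xmid = 0.004, b_xmid = 4.3,
                 a_scal = 0.0015, b_scal = 0.8)
}
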