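#' Pipeline configuration
#'
#' Assembles and defaults the configuration for [run_pipeline()]. The
#' blocks mirror the pipeline stages: `simulate` (synthetic trial;
#' ignored when real feature tables are supplied), `views` (rendering),
#' `traits` (watershed and model thresholds) and `statgen` (spatial
#' correction). All randomness derives from the single `seed`.
#'
#' @param out_dir Output directory for trait tables and the manifest.
#' @param seed Master seed (default 1).
#' @param simulate,views,traits,statgen Named lists overriding the
#'   defaults of the corresponding block.
#' @param stages Named logical list switching stages on/off.
#' @return A validated config object (class `pipeline_config`).
#' @export
pipeline_config <- function(out_dir, seed = 1, simulate = list(),
                            views = list(), traits = list(),
                            statgen = list(), stages = list()) {
  config <- list(
    seed = seed, out_dir = out_dir,
    simulate = utils::modifyList(list(
      n_genotypes = 4, n_reps = 2, n_campaigns = 6, n_year_sites = 1,
      campaign_interval_gdd = 25, plot_length_m = 0.5, plot_width_m = 0.25,
      gsd_mm = 9, density_per_m = 45, gs30_spread_days = 6,
      gs30_plot_sd = 3, clumping = 0.2, trend_gs30 = 0,
      phyllochron_mean = 75
    ), simulate),
    views = utils::modifyList(list(
      n_views = 40, erect_height_mm = 20, projection_factor = 0.4
    ), views),
    traits = utils::modifyList(list(
      i_thresh = 0.10, i_peak = 0.30, d_min_mm = 25,
      gs30_window = 30, gs30_min_samples = 12, gs30_cost = 32,
      gs30_gamma = 0.125, shoot_window = 12.5, max_cover = 0.9,
      shoot_range = c(-200, 0), calib_dgdd = c(-150, -25)
    ), traits),
    statgen = utils::modifyList(list(
      knots_factor = 2 / 3, reps_to_use = NULL, min_repeatability = 0.5
    ), statgen),
    stages = utils::modifyList(list(
      simulate = TRUE, multiview = TRUE, traits = TRUE, stats = TRUE
    ), stages)
  )
  class(config) <- "pipeline_config"
  validate_config(config)
  config
}

#' Validate a pipeline configuration
#'
#' Strict schema check (unknown keys are errors, nothing is silently
#' corrected), plus range checks against the module invariants the values
#' feed into.
#'
#' @param config A `pipeline_config`, a plain named list, or the path of
#'   a YAML file.
#' @return The config, invisibly; errors list every violation.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  allowed <- list(
    top = c("seed", "out_dir", "simulate", "views", "traits", "statgen",
            "stages"),
    simulate = c("n_genotypes", "n_reps", "n_campaigns", "n_year_sites",
                 "campaign_interval_gdd", "campaign_center_offset",
                 "plot_length_m", "plot_width_m", "gsd_mm", "density_per_m",
                 "gs30_spread_days", "gs30_plot_sd", "clumping", "trend_gs30",
                 "phyllochron_mean"),
    views = c("n_views", "erect_height_mm", "projection_factor"),
    traits = c("i_thresh", "i_peak", "d_min_mm", "gs30_window",
               "gs30_min_samples", "gs30_cost", "gs30_gamma", "shoot_window",
               "max_cover", "shoot_range", "calib_dgdd"),
    statgen = c("knots_factor", "reps_to_use", "min_repeatability"),
    stages = c("simulate", "multiview", "traits", "stats")
  )
  errors <- character()
  chk_keys <- function(block, name) {
    unknown <- setdiff(names(block), allowed[[name]])
    if (length(unknown)) {
      errors <<- c(errors, paste0("unknown key(s) in ", name, ": ",
                                  paste(unknown, collapse = ", ")))
    }
  }
  chk_keys(config, "top")
  for (b in c("simulate", "views", "traits", "statgen", "stages")) {
    if (!is.null(config[[b]])) chk_keys(config[[b]], b)
  }
  tr <- config$traits
  if (!is.null(tr$i_thresh) && !is.null(tr$i_peak) &&
      !(tr$i_thresh > 0 && tr$i_thresh <= tr$i_peak && tr$i_peak <= 1)) {
    errors <- c(errors,
                "watershed thresholds violate 0 < i_thresh <= i_peak <= 1")
  }
  sm <- config$simulate
  pos <- c("n_genotypes", "n_reps", "n_campaigns", "campaign_interval_gdd",
           "plot_length_m", "plot_width_m", "gsd_mm", "density_per_m",
           "phyllochron_mean")
  for (k in pos) {
    if (!is.null(sm[[k]]) && sm[[k]] <= 0) {
      errors <- c(errors, paste0("simulate$", k, " must be positive"))
    }
  }
  if (!is.null(config$views$n_views) && config$views$n_views < 1) {
    errors <- c(errors, "views$n_views must be >= 1")
  }
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()]: a `pipeline_config`;
#'   [write_pipeline_config()]: the path, invisibly.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, c(
    list(out_dir = x$out_dir, seed = x$seed %||% 1),
    x[intersect(names(x), c("simulate", "views", "traits", "statgen",
                            "stages"))]
  ))
  cfg
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full multiview phenotyping pipeline on a synthetic trial
#'
#' Executes the stages in processing order — canopy simulation, per-view
#' rendering and multiview aggregation, feature extraction (percentiles,
#' apparent leaf area, watershed regions), time-point traits, spatial
#' correction, dynamic modeling (GS30 zero crossing, plant-count median,
#' shoot dynamics) and summary statistics — and writes the trait tables,
#' a repeatability table and a run manifest (config hash, per-file
#' checksums, warnings) to `config$out_dir`. All stages are pure
#' functions of (config, seed), so a rerun with an identical config
#' reproduces identical output checksums.
#'
#' Plots whose GS30 zero crossing cannot be resolved (too few campaigns
#' in the index window) fall back to the campaign whose predicted index
#' is closest to zero, flagged in the output.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `$manifest`, `$tables`
#'   (named list of tibbles), `$trial`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warn <- character()
  withCallingHandlers({
    res <- pipeline_stages(config)
  }, warning = function(w) {
    warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  files <- character()
  for (nm in names(res$tables)) {
    f <- file.path(config$out_dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(res$tables[[nm]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    config_hash = rlang::hash(unclass(config)[setdiff(names(config), "out_dir")]),
    package_version = as.character(utils::packageVersion("mvgc")),
    seed = config$seed,
    stages_run = names(which(unlist(config$stages))),
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))),
    warnings = warn
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(manifest = manifest, tables = res$tables,
                 trial = res$trial, elapsed_s = as.numeric(Sys.time() - t0,
                                                           units = "secs")),
            class = "pipeline_result")
}

pipeline_stages <- function(config) {
  seed <- config$seed
  sm <- config$simulate
  trial <- make_trial(
    n_genotypes = sm$n_genotypes, n_reps = sm$n_reps,
    n_campaigns = sm$n_campaigns, n_year_sites = sm$n_year_sites,
    campaign_interval_gdd = sm$campaign_interval_gdd,
    plot_length_m = sm$plot_length_m, plot_width_m = sm$plot_width_m,
    gsd_mm = sm$gsd_mm, density_per_m = sm$density_per_m,
    gs30_spread_days = sm$gs30_spread_days, gs30_plot_sd = sm$gs30_plot_sd,
    clumping = sm$clumping, trend_gs30 = sm$trend_gs30,
    phyllochron_mean = sm$phyllochron_mean, seed = seed
  )
  tables <- list(truth_plots = trial$truth_plots)
  if (!config$stages$multiview) {
    return(list(tables = tables, trial = trial))
  }
  feats <- extract_trial_features(trial, config)
  tables$features <- dplyr::select(feats$features, -"areas")
  if (!config$stages$traits) {
    return(list(tables = tables, trial = trial))
  }
  tr <- compute_trial_traits(trial, feats, config)
  tables <- c(tables, tr$tables)
  if (config$stages$stats) {
    tables$repeatability <- trial_repeatability(tr$plot_traits, trial, config)
  }
  list(tables = tables, trial = trial)
}

# Render, aggregate and extract per-plot x campaign features.
extract_trial_features <- function(trial, config) {
  gsd_eff <- trial$gsd_mm / 3
  d_min_px <- max(1, round(config$traits$d_min_mm / gsd_eff))
  cfg_ws <- watershed_config(config$traits$i_thresh, config$traits$i_peak,
                             d_min_px)
  plots <- trial$design$plot_id
  rows <- tidyr::crossing(plot_id = plots, campaign = trial$campaigns$campaign)
  rows <- dplyr::left_join(rows, trial$campaigns, by = "campaign")
  gs30_of <- stats::setNames(trial$truth_plots$gs30_gdd,
                             trial$truth_plots$plot_id)
  feats <- purrr::map(seq_len(nrow(rows)), function(i) {
    pid <- rows$plot_id[i]; gdd <- rows$gdd[i]
    pl <- trial$plants[trial$plants$plot_id == pid, ]
    dev <- plant_development(gdd, pl$phyllochron, pl$t0, pl$leaf_area_mm2,
                             pl$tiller_a, pl$tiller_b, pl$max_shoots)
    pla <- tibble::tibble(x_m = pl$x_m, y_m = pl$y_m, la_mm2 = dev$la_mm2)
    views <- sample_view_angles(config$views$n_views,
                                seed = trial$seed + 17 * i)
    # pseudostem erection: erect plant parts gain height around GS30, which
    # widens the per-view parallax - the structural signal the GS30
    # regressor reads from the percentile distribution
    dgdd_true <- gdd - gs30_of[[pid]]
    erect_h <- config$views$erect_height_mm *
      (0.4 + 1.2 * stats::plogis(dgdd_true / 15))
    masks <- render_views(pla, views, gsd_mm = trial$gsd_mm,
                          plot_length_m = trial$plot_length_m,
                          plot_width_m = trial$plot_width_m,
                          erect_height_mm = erect_h,
                          projection_factor = config$views$projection_factor)
    mv <- aggregate_views(masks, plot_id = pid, campaign = rows$campaign[i])
    pct <- gc_percentiles(mv)
    regions <- watershed_regions(mv, cfg_ws)
    counts <- region_plant_counts(regions, mv, pl, gsd_eff)
    wide <- stats::setNames(as.list(pct$mvgc), paste0("mvgc_", pct$threshold))
    tibble::tibble(
      plot_id = pid, campaign = rows$campaign[i], gdd = gdd,
      !!!wide,
      la_px = apparent_leaf_area(mv),
      n_px = sum(!is.na(mv$values)),
      areas = list(dplyr::left_join(regions, counts, by = "region"))
    )
  }) |> dplyr::bind_rows()
  list(features = feats, d_min_px = d_min_px)
}

# Assign true plant positions to watershed regions.
region_plant_counts <- function(regions, mv, plants, gsd_eff) {
  if (nrow(regions) == 0 || nrow(plants) == 0) {
    return(tibble::tibble(region = integer(), count = numeric()))
  }
  pr <- pmin(pmax(round(plants$y_m * 1000 / gsd_eff), 1), nrow(mv$values))
  pc <- pmin(pmax(round(plants$x_m * 1000 / gsd_eff), 1), ncol(mv$values))
  d2 <- outer(regions$peak_row, pr, `-`)^2 + outer(regions$peak_col, pc, `-`)^2
  nearest <- apply(d2, 2, which.min)
  tibble::tibble(region = regions$region) |>
    dplyr::left_join(tibble::as_tibble(table(region = nearest)) |>
                       dplyr::mutate(region = as.integer(.data$region)),
                     by = "region") |>
    dplyr::mutate(count = tidyr::replace_na(.data$n, 0)) |>
    dplyr::select("region", "count")
}

compute_trial_traits <- function(trial, feats, config) {
  tcfg <- config$traits
  f <- feats$features
  truth <- dplyr::select(trial$truth_plots, "plot_id", "gs30_gdd",
                         "plant_count")
  # --- GS30: train on reference anchors, predict, zero crossing ---
  train_tbl <- dplyr::inner_join(f, truth, by = "plot_id") |>
    dplyr::mutate(dgdd = .data$gdd - .data$gs30_gdd)
  gs30_fit <- train_gs30(train_tbl, window = tcfg$gs30_window,
                         cost = tcfg$gs30_cost, gamma = tcfg$gs30_gamma,
                         min_samples = tcfg$gs30_min_samples)
  est <- predict_gs30_index(gs30_fit, f)
  gs30_tbl <- gs30_timepoint(est, window = tcfg$gs30_window)
  # fallback: campaign with index nearest zero
  nearest0 <- est |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::slice_min(abs(.data$dgdd_hat), n = 1, with_ties = FALSE) |>
    dplyr::summarise(gs30_nearest = .data$gdd - .data$dgdd_hat)
  gs30_tbl <- dplyr::left_join(gs30_tbl, nearest0, by = "plot_id") |>
    dplyr::mutate(
      gs30_gdd = dplyr::coalesce(.data$gs30_gdd, .data$gs30_nearest),
      status = ifelse(is.na(.data$slope) | .data$status != "ok",
                      "nearest_zero_fallback", .data$status)
    ) |>
    dplyr::select(-"gs30_nearest")
  # --- plant count: calibrate watershed before GS30, predict, median ---
  fa <- dplyr::inner_join(f, dplyr::select(gs30_tbl, "plot_id",
                                           gs30_est = "gs30_gdd"),
                          by = "plot_id") |>
    dplyr::mutate(dgdd_est = .data$gdd - .data$gs30_est)
  calib_rows <- dplyr::filter(fa, .data$dgdd_est >= tcfg$calib_dgdd[1],
                              .data$dgdd_est <= tcfg$calib_dgdd[2])
  if (nrow(calib_rows) == 0) calib_rows <- fa # degenerate schedule
  calib <- calibrate_watershed(dplyr::bind_rows(calib_rows$areas))
  counts_tp <- fa |>
    dplyr::mutate(value = purrr::map_dbl(.data$areas, function(a) {
      as.numeric(predict_plant_count(a, calib$a_w, calib$b_w))
    })) |>
    dplyr::select("plot_id", "campaign", "gdd", "dgdd_est", "value")
  count_campaigns <- counts_tp |>
    dplyr::distinct(.data$campaign, .data$gdd) |>
    dplyr::arrange(.data$gdd) |>
    dplyr::slice_head(n = 3) |>
    dplyr::pull(.data$campaign)
  corrected_counts <- counts_tp |>
    dplyr::filter(.data$campaign %in% count_campaigns) |>
    dplyr::group_by(.data$campaign) |>
    dplyr::group_modify(function(g, key) {
      sc <- spatial_correct_or_raw(g, trial$design, config)
      tibble::tibble(plot_id = sc$plot_id, value = sc$corrected,
                     repeatability = sc$repeatability)
    }) |>
    dplyr::ungroup()
  plant_tbl <- plant_count_trait(corrected_counts)
  # --- shoots: logistic LA model, inversion, dynamics ---
  asym <- tcfg$max_cover * stats::median(f$n_px)
  shoot_train <- dplyr::inner_join(
    dplyr::select(f, "plot_id", "campaign", "gdd", la = "la_px"),
    trial$truth_series, by = c("plot_id", "gdd")
  ) |>
    dplyr::inner_join(truth, by = "plot_id") |>
    dplyr::mutate(dgdd = .data$gdd - .data$gs30_gdd, n_s = .data$n_shoots)
  la_model <- fit_la_shoot_model(shoot_train, asym = asym,
                                 window = tcfg$shoot_window)
  shoots_tp <- fa |>
    dplyr::mutate(n_s_t = shoots_from_la(.data$la_px, .data$dgdd_est,
                                         la_model)) |>
    dplyr::select("plot_id", "campaign", "gdd", dgdd = "dgdd_est", "n_s_t")
  dyn <- shoots_tp |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::group_modify(function(g, key) {
      fitd <- fit_shoot_dynamics(g, range = tcfg$shoot_range)
      tibble::tibble(n_s = fitd$n_s, tiller_rate = fitd$a, flag = fitd$flag)
    }) |>
    dplyr::ungroup()
  plot_traits <- gs30_tbl |>
    dplyr::select("plot_id", "gs30_gdd", gs30_status = "status") |>
    dplyr::left_join(plant_tbl, by = "plot_id") |>
    dplyr::left_join(dyn, by = "plot_id") |>
    dplyr::left_join(dplyr::select(trial$design, "plot_id", "genotype",
                                   "rep", "year_site"), by = "plot_id")
  list(tables = list(
    gs30 = gs30_tbl,
    plant_count_timepoint = counts_tp,
    plant_count = plant_tbl,
    shoots_timepoint = shoots_tp,
    shoots = dyn,
    plot_traits = plot_traits,
    la_shoot_coefficients = tibble::tibble(
      asym = la_model$asym, a_xmid = la_model$a_xmid,
      b_xmid = la_model$b_xmid, a_scal = la_model$a_scal,
      b_scal = la_model$b_scal),
    watershed_calibration = calib
  ), plot_traits = plot_traits)
}

spatial_correct_or_raw <- function(values, design, config) {
  sc <- tryCatch(
    suppressMessages(spatial_correct(values, design,
                                     knots_factor = config$statgen$knots_factor)),
    error = function(e) NULL
  )
  if (is.null(sc)) {
    return(tibble::tibble(plot_id = values$plot_id,
                          corrected = values$value, repeatability = NA_real_))
  }
  tibble::tibble(plot_id = sc$data$plot_id, corrected = sc$data$corrected,
                 repeatability = sc$repeatability)
}

trial_repeatability <- function(plot_traits, trial, config) {
  traits <- c("gs30_gdd", "plant_count", "n_s", "tiller_rate")
  purrr::map(traits, function(tr) {
    purrr::map(unique(plot_traits$year_site), function(ys) {
      d <- plot_traits[plot_traits$year_site == ys, ]
      v <- d[[tr]]
      if (all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0) return(NULL)
      h <- tryCatch(
        repeatability_simple(tibble::tibble(value = v, genotype = d$genotype,
                                            rep = d$rep)),
        error = function(e) NULL
      )
      if (is.null(h)) return(NULL)
      tibble::tibble(trait = tr, year_site = ys, repeatability = h$h2,
                     sigma2_g = h$sigma2_g, sigma2_e = h$sigma2_e)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", length(x$tables), "tables,",
      length(x$manifest$outputs), "files, seed", x$manifest$seed,
      "(", round(x$elapsed_s, 1), "s )\n")
  invisible(x)
}
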