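test_that("buffer relation matches the closed form and its inversion", {
  expect_equal(min_buffer(40, 0.41, 0.1), tan(20 * pi / 180) * 0.41 + 0.1)
  expect_equal(min_buffer(40, 0.41, 0.1), 0.249, tolerance = 0.002)
  expect_equal(min_buffer(0, 5, 0.1), 0.1)
  expect_equal(min_buffer(40, 0, 0.05), 0.05)
  expect_error(min_buffer(180, 1, 0.1), "aov")
  # inversion recovers the quoted maximum canopy height
  expect_lt(abs(max_canopy_height(0.25, 40, 0.1) - 0.41), 0.005)
})

test_that("buffer size is nondecreasing in every argument", {
  withr::with_seed(11, {
    for (i in 1:20) {
      a <- stats::runif(1, 0, 170); h <- stats::runif(1, 0, 2)
      e <- stats::runif(1, 0, 0.5)
      b0 <- min_buffer(a, h, e)
      expect_gte(min_buffer(min(a + 5, 179), h, e), b0)
      expect_gte(min_buffer(a, h + 0.1, e), b0)
      expect_gte(min_buffer(a, h, e + 0.05), b0)
    }
  })
})

square_plot <- function(buffer = 0.05) {
  plot_polygon("P1", rbind(c(0, 0), c(1, 0), c(1, 0.5), c(0, 0.5)),
               buffer_m = buffer)
}

test_that("nadir back-projection is centred, symmetric and invertible", {
  pp <- square_plot()
  cam <- camera_nadir("V1", 0.5, 0.25, 28, focal_px = 18000,
                      image_size = c(6000, 4000))
  msk <- backproject_polygon(pp, 0, cam)
  expect_true(msk$fully_visible)
  expect_lt(msk$residual_px, 1e-6)
  expect_equal(colMeans(msk$polygon_px), cam$principal_point, tolerance = 1e-9)
  # square up to symmetry: edge lengths in x equal
  expect_equal(abs(diff(msk$polygon_px[1:2, 1])),
               abs(diff(msk$polygon_px[3:4, 1])))
  # ray through projected corners recovers world corners on flat ground
  w <- pixel_to_ground(cam, msk$polygon_px, 0)
  expect_lt(max(abs(w[, 1:2] - pp$corners[, 1:2])), 1e-6)
})

test_that("camera translation shifts the projection by focal * dx / height", {
  pp <- square_plot()
  f <- 18000; hgt <- 28
  cam0 <- camera_nadir("V1", 0.5, 0.25, hgt, f, c(6000, 4000))
  cam1 <- camera_nadir("V2", 1.5, 0.25, hgt, f, c(6000, 4000))
  m0 <- backproject_polygon(pp, 0, cam0)
  m1 <- backproject_polygon(pp, 0, cam1)
  expect_equal(m0$polygon_px[, 1] - m1$polygon_px[, 1],
               rep(f * 1 / hgt, 4), tolerance = 1e-9)
})

test_that("oblique viewing shrinks the projected area by about cos(zenith)", {
  pp <- square_plot()
  f <- 18000
  cam0 <- camera_nadir("V1", 0.5, 0.25, 28, f, c(6000, 4000))
  # tilt 20 degrees about the x axis, keeping the plot centre on axis
  th <- 20 * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  pos <- c(0.5, 0.25 + 28 * tan(th), 28)
  cam1 <- camera_view("V2", pos, rx %*% cam0$rotation, f / cos(th),
                      c(6000, 4000))
  area <- function(uv) {
    n <- nrow(uv)
    abs(sum(uv[, 1] * uv[c(2:n, 1), 2] - uv[c(2:n, 1), 1] * uv[, 2])) / 2
  }
  # forward-projection oracle on a dense boundary grid
  dense <- rbind(
    cbind(seq(0, 1, length.out = 50), 0, 0),
    cbind(1, seq(0, 0.5, length.out = 25), 0),
    cbind(seq(1, 0, length.out = 50), 0.5, 0),
    cbind(0, seq(0.5, 0, length.out = 25), 0)
  )
  a0 <- area(project_points(cam0, dense))
  a1 <- area(project_points(cam1, dense))
  expect_equal(a1 / a0, cos(th), tolerance = 0.05)
})

test_that("corner behind the camera excludes the view with a warning", {
  pp <- square_plot()
  cam <- camera_nadir("V1", 0.5, 0.25, -1, 18000, c(6000, 4000))
  expect_warning(out <- backproject_polygon(pp, 0, cam), "behind")
  expect_null(out)
})

test_that("elevation rasters are looked up and out-of-range rejected", {
  pp <- square_plot()
  cam <- camera_nadir("V1", 0.5, 0.25, 28, 18000, c(6000, 4000))
  elev <- list(z = matrix(0.2, 20, 30), x0 = 0, y0 = 0, res = 0.1)
  msk <- backproject_polygon(pp, elev, cam)
  w <- pixel_to_ground(cam, msk$polygon_px, 0.2)
  expect_lt(max(abs(w[, 1:2] - pp$corners[, 1:2])), 1e-6)
  far <- plot_polygon("P2", rbind(c(10, 10), c(11, 10), c(11, 10.5),
                                  c(10, 10.5)), buffer_m = 0.05)
  expect_error(backproject_polygon(far, elev, cam), "outside raster")
})

test_that("self-intersecting polygons and oversized buffers are rejected", {
  expect_error(plot_polygon("P1", rbind(c(0, 0), c(1, 0.5), c(1, 0),
                                        c(0, 0.5))), "self-intersecting")
  expect_error(plot_polygon("P1", rbind(c(0, 0), c(1, 0), c(1, 0.5),
                                        c(0, 0.5)), buffer_m = 0.3), "buffer")
})

test_that("resampling upsamples threefold with nearest-neighbour semantics", {
  # identity-scaled map: 2x2 checkerboard -> 6x6 of constant 3x3 blocks
  seg <- rbind(c(1, 0), c(0, 1))
  msk <- list(M = rbind(c(1000, 0, 0), c(0, 1000, 0)), length_m = 0.002,
              width_m = 0.002, buffer_m = 0, image_id = "V1")
  out <- resample_to_plot(seg, msk, gsd_mm = 1)
  expect_equal(dim(out), c(6L, 6L))
  expect_equal(out, kronecker(seg, matrix(1, 3, 3)), ignore_attr = TRUE)
  # all-plant input: all ones inside the polygon, masked outside
  msk$buffer_m <- 0.0005
  out <- resample_to_plot(matrix(1, 2, 2), msk, gsd_mm = 1)
  expect_true(all(out[!is.na(out)] == 1))
  expect_true(any(is.na(out)))
})

test_that("a transposing affine map equals the transposed identity result", {
  withr::with_seed(7, seg <- matrix(rbinom(100, 1, 0.4), 10, 10))
  ident <- list(M = rbind(c(1000, 0, 0), c(0, 1000, 0)), length_m = 0.01,
                width_m = 0.01, buffer_m = 0)
  swap <- list(M = rbind(c(0, 1000, 0), c(1000, 0, 0)), length_m = 0.01,
               width_m = 0.01, buffer_m = 0)
  a <- resample_to_plot(seg, ident, gsd_mm = 1)
  b <- resample_to_plot(seg, swap, gsd_mm = 1)
  expect_equal(b, t(a), ignore_attr = TRUE)
})

test_that("identity resampling preserves the plant-pixel fraction", {
  withr::with_seed(8, seg <- matrix(rbinom(60 * 40, 1, 0.3), 40, 60))
  msk <- list(M = rbind(c(1000, 0, 0), c(0, 1000, 0)), length_m = 0.06,
              width_m = 0.04, buffer_m = 0)
  out <- resample_to_plot(seg, msk, gsd_mm = 3)
  expect_equal(mean(out), mean(seg), tolerance = 1 / (3 * 40))
})

test_that("pose CSV with omega-phi-kappa angles reproduces a nadir camera", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(image_id = "V1", x = 0.5, y = 0.25, z = 28,
                              omega = 0, phi = 0, kappa = 0),
                   f, row.names = FALSE)
  cams <- read_camera_poses(f, focal_px = 18000, image_size = c(6000, 4000))
  pp <- square_plot()
  m <- backproject_polygon(pp, 0, cams[[1]])
  ref <- backproject_polygon(pp, 0, camera_nadir("V1", 0.5, 0.25, 28, 18000,
                                                 c(6000, 4000)))
  expect_equal(m$polygon_px, ref$polygon_px, tolerance = 1e-9)
})

test_that("plot polygons are read from GeoJSON with properties", {
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = list(plot_id = "A1", genotype = "G01", row = 2, range = 3),
    geometry = list(type = "Polygon", coordinates = list(list(
      list(0, 0), list(1, 0), list(1, 0.5), list(0, 0.5), list(0, 0)
    )))
  )))
  f <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE)
  pps <- read_plot_polygons(f, buffer_m = 0.05)
  expect_length(pps, 1)
  expect_equal(pps[[1]]$plot_id, "A1")
  expect_equal(pps[[1]]$genotype, "G01")
  expect_equal(pps[[1]]$length_m, 1)
})

test_that("5x5 median smoothing removes single-cell elevation spikes", {
  z <- matrix(1, 10, 10); z[5, 5] <- 50
  zs <- smooth_elevation(z)
  expect_equal(zs[5, 5], 1)
  expect_equal(smooth_elevation(matrix(2, 6, 6)), matrix(2, 6, 6))
})
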