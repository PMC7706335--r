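#' Minimum plot-polygon buffer for multiview imaging
#'
#' Plot polygons are shrunk by a buffer before sampling pixels so that (a)
#' imprecise georeferencing cannot sample the wrong plot and (b) leaning
#' canopy parts of neighbouring plots, seen under oblique viewing angles,
#' are excluded. The minimum buffer is
#' \deqn{B = \tan(AOV/2)\, h_{canopy} + E_{ref},}
#' where AOV is the maximum angle of view of the imaging system,
#' \eqn{h_{canopy}} the canopy height and \eqn{E_{ref}} the georeferencing
#' precision (all heights/precisions in meters).
#'
#' @param aov_deg Maximum angle of view in degrees, in `[0, 180)`.
#' @param h_canopy Canopy height in meters (>= 0).
#' @param e_ref Georeferencing precision in meters (>= 0).
#' @return Buffer size in meters.
#' @examples
#' min_buffer(40, 0.41, 0.1) # ~0.249 m
#' @seealso [max_canopy_height()] for the inverse relation.
#' @export
min_buffer <- function(aov_deg, h_canopy, e_ref) {
  if (any(aov_deg < 0) || any(aov_deg >= 180)) {
    stop("`aov_deg` must be in [0, 180)", call. = FALSE)
  }
  stopifnot(all(h_canopy >= 0), all(e_ref >= 0))
  tan(aov_deg / 2 * pi / 180) * h_canopy + e_ref
}

#' Maximum monitorable canopy height for a given buffer
#'
#' Inverts the buffer relation of [min_buffer()] for canopy height:
#' \eqn{h_{canopy} = (B - E_{ref}) / \tan(AOV/2)}. With the defaults used
#' in seedling-stage wheat monitoring (0.25 m buffer, 40 degree angle of
#' view, 0.1 m georeferencing precision) canopies up to about 0.41 m can
#' be monitored.
#'
#' @param buffer_m Buffer size in meters.
#' @param aov_deg Maximum angle of view in degrees, in `(0, 180)`.
#' @param e_ref Georeferencing precision in meters (must not exceed
#'   `buffer_m`).
#' @return Canopy height in meters.
#' @examples
#' max_canopy_height(0.25, 40, 0.1) # ~0.41 m
#' @export
max_canopy_height <- function(buffer_m, aov_deg, e_ref) {
  if (any(aov_deg <= 0) || any(aov_deg >= 180)) {
    stop("`aov_deg` must be in (0, 180)", call. = FALSE)
  }
  if (any(e_ref > buffer_m)) {
    stop("`e_ref` must not exceed `buffer_m`", call. = FALSE)
  }
  (buffer_m - e_ref) / tan(aov_deg / 2 * pi / 180)
}

#' Plot polygon in world coordinates
#'
#' @param plot_id Plot identifier.
#' @param corners A 4(+) x 2 or x 3 matrix of world XY(Z) corner
#'   coordinates in meters, in ring order. The first corner is taken as
#'   the plot-frame origin; the edge to the second corner defines the
#'   plot-length (sowing-row) direction.
#' @param buffer_m Buffer in meters applied before pixel sampling
#'   (default 0.25).
#' @param row,range Field row/range indices (optional).
#' @param genotype Genotype label (optional).
#' @return An object of class `plot_polygon`.
#' @export
plot_polygon <- function(plot_id, corners, buffer_m = 0.25, row = NA_integer_,
                         range = NA_integer_, genotype = NA_character_) {
  corners <- as.matrix(corners)
  stopifnot(nrow(corners) >= 4, ncol(corners) %in% c(2L, 3L))
  if (ncol(corners) == 2L) corners <- cbind(corners, 0)
  if (!polygon_is_simple(corners[, 1:2, drop = FALSE])) {
    stop("plot polygon is self-intersecting", call. = FALSE)
  }
  # plot frame: origin at corner 1, x along edge 1->2 (plot length)
  ex <- corners[2, 1:2] - corners[1, 1:2]
  len <- sqrt(sum(ex^2))
  ex <- ex / len
  ey <- c(-ex[2], ex[1])
  rel <- sweep(corners[, 1:2, drop = FALSE], 2, corners[1, 1:2])
  frame_xy <- cbind(rel %*% ex, rel %*% ey)
  if (mean(frame_xy[, 2]) < 0) { # keep plot-frame y positive
    ey <- -ey
    frame_xy[, 2] <- -frame_xy[, 2]
  }
  wid <- max(frame_xy[, 2])
  if (2 * buffer_m >= min(len, wid)) {
    stop("buffer (", buffer_m, " m) leaves no interior for a ",
         round(len, 3), " x ", round(wid, 3), " m plot", call. = FALSE)
  }
  structure(
    list(plot_id = plot_id, corners = corners, frame_xy = frame_xy,
         origin = corners[1, 1:2], ex = ex, ey = ey,
         length_m = len, width_m = wid, buffer_m = buffer_m,
         row = row, range = range, genotype = genotype),
    class = "plot_polygon"
  )
}

polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  seg <- function(i) list(a = xy[i, ], b = xy[i %% n + 1, ])
  inter <- function(p, q) {
    d1 <- cross2(q$b - q$a, p$a - q$a)
    d2 <- cross2(q$b - q$a, p$b - q$a)
    d3 <- cross2(p$b - p$a, q$a - p$a)
    d4 <- cross2(p$b - p$a, q$b - p$a)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) %in% c(0, 1, n - 1)) next
      if (inter(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Camera view (pose + intrinsics)
#'
#' The camera frame follows the computer-vision convention: +z along the
#' optical axis (viewing direction), +x to the image right, +y down.
#' A world point `W` maps to camera coordinates `p = R (W - C)` and to the
#' image as `u = f * p_x / p_z + cx`, `v = f * p_y / p_z + cy`.
#'
#' @param image_id Image identifier.
#' @param position Numeric XYZ world position of the projection centre (m).
#' @param rotation 3x3 orthonormal world-to-camera rotation matrix.
#' @param focal_px Focal length in pixels (> 0).
#' @param image_size Integer `c(width, height)` in pixels.
#' @param principal_point `c(cx, cy)` in pixels; defaults to the image
#'   centre.
#' @param gsd_mm Nominal ground sampling distance in mm/pixel.
#' @return An object of class `camera_view`.
#' @export
camera_view <- function(image_id, position, rotation, focal_px, image_size,
                        principal_point = image_size / 2, gsd_mm = NA_real_) {
  rotation <- as.matrix(rotation)
  stopifnot(length(position) == 3, all(dim(rotation) == c(3, 3)),
            focal_px > 0, length(image_size) == 2)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("`rotation` must be orthonormal", call. = FALSE)
  }
  structure(
    list(image_id = image_id, position = as.numeric(position),
         rotation = rotation, focal_px = focal_px,
         image_size = as.numeric(image_size),
         principal_point = as.numeric(principal_point), gsd_mm = gsd_mm),
    class = "camera_view"
  )
}

#' Nadir camera above a point
#'
#' Convenience constructor: a camera at `(x, y, altitude)` looking straight
#' down, with image x aligned to world x and image y to world -y.
#'
#' @inheritParams camera_view
#' @param x,y,altitude World position in meters.
#' @export
camera_nadir <- function(image_id, x, y, altitude, focal_px, image_size,
                         gsd_mm = NA_real_) {
  # cam x = world x, cam y = world -y, cam z = world -z (looking down)
  rot <- rbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  camera_view(image_id, c(x, y, altitude), rot, focal_px, image_size,
              gsd_mm = gsd_mm)
}

#' Project world points into a camera view
#'
#' @param view A [camera_view()].
#' @param xyz An n x 3 matrix of world coordinates (m).
#' @return An n x 2 matrix of image pixel coordinates; rows for points at
#'   or behind the camera plane are `NA`.
#' @export
project_points <- function(view, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  pc <- t(view$rotation %*% (t(xyz) - view$position))
  uv <- cbind(
    view$focal_px * pc[, 1] / pc[, 3] + view$principal_point[1],
    view$focal_px * pc[, 2] / pc[, 3] + view$principal_point[2]
  )
  uv[pc[, 3] <= 0, ] <- NA_real_
  uv
}

#' Intersect a pixel's viewing ray with a horizontal ground plane
#'
#' @param view A [camera_view()].
#' @param uv An n x 2 matrix of pixel coordinates.
#' @param z_ground Ground elevation (m), a constant plane.
#' @return An n x 3 matrix of world coordinates.
#' @export
pixel_to_ground <- function(view, uv, z_ground = 0) {
  uv <- matrix(as.numeric(uv), ncol = 2)
  dir_cam <- cbind((uv[, 1] - view$principal_point[1]) / view$focal_px,
                   (uv[, 2] - view$principal_point[2]) / view$focal_px, 1)
  dir_w <- dir_cam %*% view$rotation # = t(R) %*% dir per row
  lambda <- (z_ground - view$position[3]) / dir_w[, 3]
  sweep(dir_w * lambda, 2, view$position, `+`)
}

#' Back-project a plot polygon into an image
#'
#' Looks up corner elevations (constant plane or elevation raster),
#' projects the world corners through the pinhole model of `view`, and
#' fits the affine map `M` from plot-frame coordinates (meters) to image
#' pixel coordinates by least squares over the corner correspondences.
#' A fit residual above 2 px — the typical multiview coregistration
#' precision — triggers a warning.
#'
#' @param plot A [plot_polygon()].
#' @param elevation Either a single ground elevation in meters or a list
#'   `list(z = matrix, x0, y0, res)` giving a north-up elevation raster
#'   (cell `[i, j]` covers `x0 + (j-1)*res`, `y0 + (i-1)*res`).
#' @param view A [camera_view()].
#' @return An object of class `plot_image_mask`: the projected polygon in
#'   pixel coordinates, the affine matrix `M` (2 x 3, mapping
#'   `(x_plot, y_plot, 1)` in meters to pixels), a `fully_visible` flag
#'   and the fit residual.
#' @export
backproject_polygon <- function(plot, elevation, view) {
  stopifnot(inherits(plot, "plot_polygon"), inherits(view, "camera_view"))
  xyz <- plot$corners
  xyz[, 3] <- lookup_elevation(elevation, xyz[, 1], xyz[, 2])
  if (anyNA(xyz[, 3])) stop("elevation lookup outside raster", call. = FALSE)
  uv <- project_points(view, xyz)
  if (anyNA(uv)) {
    warning("plot corner behind camera plane; view ", view$image_id,
            " excluded", call. = FALSE)
    return(NULL)
  }
  # affine fit: [u v] = [x y 1] %*% t(M)
  A <- cbind(plot$frame_xy, 1)
  M <- t(qr.solve(A, uv)) # 2 x 3
  resid <- sqrt(max(rowSums((A %*% t(M) - uv)^2)))
  if (resid > 2) {
    warning("affine fit residual ", signif(resid, 3), " px exceeds 2 px for view ",
            view$image_id, call. = FALSE)
  }
  fully <- all(uv[, 1] >= 0 & uv[, 1] <= view$image_size[1] &
               uv[, 2] >= 0 & uv[, 2] <= view$image_size[2])
  structure(
    list(image_id = view$image_id, plot_id = plot$plot_id, polygon_px = uv,
         M = M, residual_px = resid, fully_visible = fully,
         length_m = plot$length_m, width_m = plot$width_m,
         buffer_m = plot$buffer_m),
    class = "plot_image_mask"
  )
}

lookup_elevation <- function(elevation, x, y) {
  if (is.numeric(elevation) && length(elevation) == 1) {
    return(rep(elevation, length(x)))
  }
  stopifnot(is.list(elevation), all(c("z", "x0", "y0", "res") %in% names(elevation)))
  j <- round((x - elevation$x0) / elevation$res) + 1
  i <- round((y - elevation$y0) / elevation$res) + 1
  z <- rep(NA_real_, length(x))
  ok <- i >= 1 & i <= nrow(elevation$z) & j >= 1 & j <= ncol(elevation$z)
  z[ok] <- elevation$z[cbind(i[ok], j[ok])]
  z
}

#' 5x5 moving-median smoothing of an elevation raster
#'
#' Optional denoising of digital elevation models before corner lookup;
#' borders are handled by shrinking the window to the raster.
#'
#' @param z An elevation matrix.
#' @return The smoothed matrix.
#' @export
smooth_elevation <- function(z) {
  n <- nrow(z); m <- ncol(z)
  out <- z
  for (i in seq_len(n)) {
    ii <- max(1, i - 2):min(n, i + 2)
    for (j in seq_len(m)) {
      jj <- max(1, j - 2):min(m, j + 2)
      out[i, j] <- stats::median(z[ii, jj])
    }
  }
  out
}

#' Resample a segmented view into the plot coordinate frame
#'
#' Cuts the plot out of a full-frame binary segmented image and resamples
#' it, at threefold resolution relative to the nominal ground sampling
#' distance (oversampling absorbs round-off so nearest-neighbour sampling
#' loses no binary detail), onto a grid with axes parallel to the plot
#' borders:
#' \deqn{segImg_{res}(x, y) = segImg(M \cdot (x, y)),}
#' for `x in 1..3*plot_l/GSD`, `y in 1..3*plot_w/GSD`. Pixels outside the
#' buffered plot polygon, or mapping outside the source image, are set to
#' `NA` (masked sentinel).
#'
#' @param seg_img A binary matrix (rows = image y, columns = image x,
#'   values 0/1).
#' @param mask A `plot_image_mask` from [backproject_polygon()], or any
#'   list with elements `M`, `length_m`, `width_m`, `buffer_m`.
#' @param gsd_mm Nominal ground sampling distance in mm/pixel.
#' @return A numeric matrix in the plot frame (rows = plot y/width,
#'   columns = plot x/length), values in `{0, 1, NA}`, with attributes
#'   `gsd_eff_mm` (= `gsd_mm / 3`) and `image_id`.
#' @export
resample_to_plot <- function(seg_img, mask, gsd_mm) {
  stopifnot(is.matrix(seg_img), gsd_mm > 0)
  nx <- round(3 * mask$length_m * 1000 / gsd_mm)
  ny <- round(3 * mask$width_m * 1000 / gsd_mm)
  if (nx <= 0 || ny <= 0) stop("non-positive output dimensions", call. = FALSE)
  step <- gsd_mm / 3 / 1000 # m per output pixel
  xp <- (seq_len(nx) - 0.5) * step
  yp <- (seq_len(ny) - 0.5) * step
  g <- expand.grid(x = xp, y = yp)
  uv <- cbind(g$x, g$y, 1) %*% t(mask$M)
  # nearest-neighbour: pixel-centre convention, 0-based pixel indices
  ci <- floor(uv[, 1]) + 1L
  ri <- floor(uv[, 2]) + 1L
  val <- rep(NA_real_, nrow(uv))
  ok <- ri >= 1L & ri <= nrow(seg_img) & ci >= 1L & ci <= ncol(seg_img)
  val[ok] <- seg_img[cbind(ri[ok], ci[ok])]
  out <- matrix(val, nrow = ny, ncol = nx, byrow = TRUE)
  b <- mask$buffer_m %||% 0
  if (b > 0) {
    inside_x <- xp >= b & xp <= mask$length_m - b
    inside_y <- yp >= b & yp <= mask$width_m - b
    out[!inside_y, ] <- NA_real_
    out[, !inside_x] <- NA_real_
  }
  attr(out, "gsd_eff_mm") <- gsd_mm / 3
  attr(out, "image_id") <- mask$image_id %||% NA_character_
  out
}

#' Read plot polygons from a GeoJSON file
#'
#' Expects a FeatureCollection of Polygon features with properties
#' `plot_id`, and optionally `genotype`, `row`, `range`.
#'
#' @param path GeoJSON file path.
#' @param buffer_m Buffer applied to every plot (default 0.25 m).
#' @return A list of [plot_polygon()] objects.
#' @export
read_plot_polygons <- function(path, buffer_m = 0.25) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  lapply(gj$features, function(f) {
    stopifnot(identical(f$geometry$type, "Polygon"))
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
    pr <- f$properties
    plot_polygon(pr$plot_id %||% NA, xy, buffer_m = buffer_m,
                 row = pr$row %||% NA_integer_, range = pr$range %||% NA_integer_,
                 genotype = pr$genotype %||% NA_character_)
  })
}

#' Read camera poses from a CSV of photogrammetric exports
#'
#' Expects columns `image_id, x, y, z, omega, phi, kappa` (angles in
#' degrees, the usual photogrammetry-suite export). The
#' omega-phi-kappa rotation (camera x right, y up, z backward) is
#' converted to this package's computer-vision camera frame.
#'
#' @param path CSV file path.
#' @param focal_px Focal length in pixels.
#' @param image_size `c(width, height)` in pixels.
#' @param gsd_mm Nominal GSD in mm/pixel.
#' @return A list of [camera_view()] objects.
#' @export
read_camera_poses <- function(path, focal_px, image_size, gsd_mm = NA_real_) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x", "y", "z", "omega", "phi", "kappa")
  stopifnot(all(need %in% names(x)))
  lapply(seq_len(nrow(x)), function(i) {
    r <- x[i, ]
    camera_view(r$image_id, c(r$x, r$y, r$z),
                rotation_opk(r$omega, r$phi, r$kappa),
                focal_px, image_size, gsd_mm = gsd_mm)
  })
}

#' Omega-phi-kappa angles to a world-to-camera rotation
#'
#' @param omega,phi,kappa Angles in degrees.
#' @return A 3x3 world-to-camera rotation matrix in the computer-vision
#'   camera frame (+z viewing direction, +y image-down).
#' @export
rotation_opk <- function(omega, phi, kappa) {
  d <- pi / 180
  o <- omega * d; p <- phi * d; k <- kappa * d
  rx <- rbind(c(1, 0, 0), c(0, cos(o), -sin(o)), c(0, sin(o), cos(o)))
  ry <- rbind(c(cos(p), 0, sin(p)), c(0, 1, 0), c(-sin(p), 0, cos(p)))
  rz <- rbind(c(cos(k), -sin(k), 0), c(sin(k), cos(k), 0), c(0, 0, 1))
  r_cw_photo <- rx %*% ry %*% rz # camera-to-world, photo frame (z backward)
  flip <- diag(c(1, -1, -1))     # photo frame -> CV frame
  t(r_cw_photo %*% flip)
}
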