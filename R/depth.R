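# Depth-image measurement chain: pinhole back-projection, Z-threshold
# segmentation, planar 1 cm/pixel histogram, landmark distance measurement,
# plus the ellipsoid phantom renderer that stands in for a depth sensor.

#' Pinhole camera intrinsics
#'
#' Default focal length is 292.5 px at 320 x 240 — half the focal length
#' commonly used for the 640 x 480 mode of consumer structured-light depth
#' sensors — with the principal point at the image centre.
#'
#' @param fx,fy Focal lengths, px.
#' @param cx,cy Principal point, px.
#' @param width,height Image size, px.
#' @return List of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx = 292.5, fy = 292.5,
                              cx = 159.5, cy = 119.5,
                              width = 320L, height = 240L) {
  stopifnot(fx > 0, fy > 0, width >= 1L, height >= 1L)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' A metric depth frame
#'
#' @param depth `height x width` matrix of metric depth along the optical
#'   axis, metres; 0 encodes "no return".
#' @param intrinsics A [camera_intrinsics()].
#' @return List of class `depth_frame`.
#' @export
depth_frame <- function(depth, intrinsics = camera_intrinsics()) {
  depth <- as.matrix(depth)
  if (nrow(depth) != intrinsics$height || ncol(depth) != intrinsics$width)
    stop("depth matrix must be height x width of the intrinsics", call. = FALSE)
  if (any(!is.finite(depth)) || any(depth < 0))
    stop("depths must be finite and non-negative", call. = FALSE)
  structure(list(depth = depth, intrinsics = intrinsics),
            class = "depth_frame")
}

#' Ellipsoid phantom specification
#'
#' An axis-aligned ellipsoid (semi-axes in cm: horizontal, vertical, depth)
#' centred on the optical axis at `distance` metres, with ground-truth
#' landmark pairs defined as directions (degrees) from the centre of its
#' mid cross-section; the true landmark points lie on the cross-section
#' ellipse boundary along those directions.
#'
#' @param semi_axes Length-3 positive numeric, cm: (horizontal `a`,
#'   vertical `b`, depth `c`).
#' @param distance Centre distance from the camera, m (default 1.5, the
#'   nominal sensor stand-off).
#' @param landmarks Data frame with columns `theta1`, `theta2` in degrees;
#'   defaults to five pairs spanning width, height and three obliques.
#' @return List of class `phantom_spec`; `$truth` holds the true pair
#'   separations in cm.
#' @export
phantom_spec <- function(semi_axes = c(50, 30, 18), distance = 1.5,
                         landmarks = NULL) {
  stopifnot(length(semi_axes) == 3L, all(semi_axes > 0), distance > 0)
  if (distance - semi_axes[3] / 100 <= 0)
    stop("phantom surface reaches behind the camera", call. = FALSE)
  if (is.null(landmarks))
    landmarks <- data.frame(theta1 = c(180, 90, 180, 135, 150),
                            theta2 = c(0, 270, 90, 315, 30))
  a <- semi_axes[1]; b <- semi_axes[2]
  bpt <- function(th) {
    r <- a * b / sqrt((b * cos(th * pi / 180))^2 + (a * sin(th * pi / 180))^2)
    c(r * cos(th * pi / 180), r * sin(th * pi / 180))
  }
  truth <- mapply(function(t1, t2) sqrt(sum((bpt(t1) - bpt(t2))^2)),
                  landmarks$theta1, landmarks$theta2)
  structure(list(semi_axes = semi_axes, distance = distance,
                 landmarks = landmarks, truth = truth),
            class = "phantom_spec")
}

#' Render an ellipsoid phantom to a depth frame
#'
#' Per pixel, the nearest ray-ellipsoid intersection under the pinhole
#' model (depth is the Z coordinate, as for a structured-light sensor);
#' misses are set to the far background depth.  Optional additive Gaussian
#' depth noise is applied to phantom pixels.
#'
#' @param spec A [phantom_spec()].
#' @param intrinsics A [camera_intrinsics()].
#' @param background Background depth, m.
#' @param noise_sd Additive depth noise SD, m.
#' @param seed Optional integer seed for the noise.
#' @return A [depth_frame()]; its `silhouette` attribute is the logical
#'   hit mask (the renderer's own ground-truth silhouette).
#' @export
render_phantom <- function(spec, intrinsics = camera_intrinsics(),
                           background = 2.5, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  A <- spec$semi_axes[1] / 100; B <- spec$semi_axes[2] / 100
  C <- spec$semi_axes[3] / 100; z0 <- spec$distance

  u <- matrix(seq_len(intrinsics$width) - 1, intrinsics$height,
              intrinsics$width, byrow = TRUE)
  v <- matrix(seq_len(intrinsics$height) - 1, intrinsics$height,
              intrinsics$width)
  dx <- (u - intrinsics$cx) / intrinsics$fx
  dy <- (v - intrinsics$cy) / intrinsics$fy

  # ray p = t (dx, dy, 1); t equals depth Z
  qa <- dx^2 / A^2 + dy^2 / B^2 + 1 / C^2
  qb <- -2 * z0 / C^2
  qc <- z0^2 / C^2 - 1
  disc <- qb^2 - 4 * qa * qc
  hit <- disc >= 0
  t1 <- matrix(NA_real_, nrow(dx), ncol(dx))
  t1[hit] <- (-qb - sqrt(disc[hit])) / (2 * qa[hit])
  hit <- hit & !is.na(t1) & t1 > 0

  depth <- matrix(background, nrow(dx), ncol(dx))
  depth[hit] <- t1[hit]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    depth[hit] <- pmax(depth[hit] + stats::rnorm(sum(hit), 0, noise_sd), 0.01)
  }
  frame <- depth_frame(depth, intrinsics)
  attr(frame, "silhouette") <- hit
  frame
}

#' Z-threshold segmentation of a depth frame
#'
#' Keeps pixels whose depth lies in `[near, far]`; zero ("no return")
#' pixels are always removed.  Segmenting an already segmented frame is a
#' no-op.
#'
#' @param frame A [depth_frame()].
#' @param near,far Depth window, m (defaults 1.2 and 1.8, the working
#'   range of the calibrated sensor).
#' @return List of class `depth_segmentation`: `mask` (logical matrix),
#'   `frame` (depth outside the mask zeroed) and `points` (data frame of
#'   retained pixel coordinates `u`, `v` and depth `z`).
#' @export
segment_depth <- function(frame, near = 1.2, far = 1.8) {
  stopifnot(inherits(frame, "depth_frame"))
  if (near >= far) stop("`near` must be below `far`", call. = FALSE)
  mask <- frame$depth >= near & frame$depth <= far & frame$depth > 0
  seg <- frame
  seg$depth[!mask] <- 0
  idx <- which(mask, arr.ind = TRUE)
  points <- data.frame(u = idx[, 2L] - 1L, v = idx[, 1L] - 1L,
                       z = frame$depth[mask])
  structure(list(mask = mask, frame = seg, points = points),
            class = "depth_segmentation")
}

#' Back-project retained pixels and flatten to a 1 cm/pixel histogram
#'
#' Each retained pixel is back-projected to metric camera coordinates
#' `X = (u - cx) Z / fx`, `Y = (v - cy) Z / fy`, converted to cm and binned
#' into 1 cm x 1 cm cells; the cell value is the number of points that fell
#' in it (a two-dimensional histogram).
#'
#' @param segmentation A `depth_segmentation` from [segment_depth()], or a
#'   [depth_frame()] plus explicit `mask`.
#' @param mask Optional logical matrix when passing a raw frame.
#' @return List of class `planar_image`: `counts` (rows = Y, cols = X),
#'   `origin` (cm coordinates of the lower cell corner of `counts[1, 1]`).
#'   Cell `[i, j]` covers `origin + (j-1, i-1)` to `origin + (j, i)` cm.
#' @export
backproject_and_flatten <- function(segmentation, mask = NULL) {
  if (inherits(segmentation, "depth_frame")) {
    if (is.null(mask)) stop("a raw frame needs an explicit mask", call. = FALSE)
    frame <- segmentation
  } else {
    stopifnot(inherits(segmentation, "depth_segmentation"))
    frame <- segmentation$frame
    mask <- segmentation$mask
  }
  if (!any(mask)) stop("empty mask: nothing to project", call. = FALSE)
  K <- frame$intrinsics
  idx <- which(mask, arr.ind = TRUE)
  z <- frame$depth[mask]
  X <- ((idx[, 2L] - 1L) - K$cx) * z / K$fx * 100   # cm
  Y <- ((idx[, 1L] - 1L) - K$cy) * z / K$fy * 100
  x0 <- floor(min(X)); y0 <- floor(min(Y))
  xi <- pmin(floor(X) - x0, ceiling(max(X)) - x0 - 1L) + 1L
  yi <- pmin(floor(Y) - y0, ceiling(max(Y)) - y0 - 1L) + 1L
  nx <- max(xi); ny <- max(yi)
  counts <- matrix(0L, ny, nx)
  for (k in seq_along(xi))
    counts[yi[k], xi[k]] <- counts[yi[k], xi[k]] + 1L
  structure(list(counts = counts, origin = c(x = x0, y = y0)),
            class = "planar_image")
}

in_planar_bounds <- function(image, p) {
  p[1] >= image$origin[["x"]] &&
    p[1] <= image$origin[["x"]] + ncol(image$counts) &&
    p[2] >= image$origin[["y"]] &&
    p[2] <= image$origin[["y"]] + nrow(image$counts)
}

#' Euclidean distance between two points of a planar image
#'
#' At 1 cm per pixel the pixel distance equals the metric distance, so this
#' is a plain Euclidean distance in cm, with a bounds check against the
#' image extent.
#'
#' @param image A `planar_image`.
#' @param p1,p2 Length-2 numeric points, cm, in image coordinates.
#' @return Distance in cm.
#' @export
measure_distance <- function(image, p1, p2) {
  stopifnot(inherits(image, "planar_image"))
  if (!in_planar_bounds(image, p1) || !in_planar_bounds(image, p2))
    stop("point outside the planar image", call. = FALSE)
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
}

# Occupancy centroid of a planar image, cm
planar_centroid <- function(image) {
  idx <- which(image$counts > 0, arr.ind = TRUE)
  c(x = image$origin[["x"]] + mean(idx[, 2L]) - 0.5,
    y = image$origin[["y"]] + mean(idx[, 1L]) - 0.5)
}

# Farthest occupied cell along a ray from `center` in direction `theta`
# (degrees), marching in 0.5 cm steps and tolerating gaps up to 2 cm.
silhouette_boundary_point <- function(image, theta, center = planar_centroid(image)) {
  ux <- cos(theta * pi / 180); uy <- sin(theta * pi / 180)
  occupied <- function(p) {
    j <- floor(p[1] - image$origin[["x"]]) + 1
    i <- floor(p[2] - image$origin[["y"]]) + 1
    i >= 1 && i <= nrow(image$counts) && j >= 1 && j <= ncol(image$counts) &&
      image$counts[i, j] > 0
  }
  tmax <- sqrt(nrow(image$counts)^2 + ncol(image$counts)^2)
  t_last <- NA_real_; gap <- 0
  for (t in seq(0, tmax, by = 0.5)) {
    if (occupied(c(center[1] + t * ux, center[2] + t * uy))) {
      t_last <- t; gap <- 0
    } else if (!is.na(t_last)) {
      gap <- gap + 0.5
      if (gap > 2) break
    }
  }
  if (is.na(t_last))
    stop("no occupied cell along direction ", theta, call. = FALSE)
  c(center[1] + t_last * ux, center[2] + t_last * uy)
}

#' End-to-end phantom measurement
#'
#' Renders a phantom, segments the frame with the default working range,
#' flattens it to the 1 cm/pixel planar histogram, locates the silhouette
#' boundary along each landmark direction from the silhouette centroid and
#' measures the pair distances, comparing them with the spec's ground
#' truth.
#'
#' @param spec A [phantom_spec()].
#' @param intrinsics A [camera_intrinsics()].
#' @param near,far Segmentation window, m.
#' @param noise_sd Additive depth-noise SD, m.
#' @param seed Optional seed for the noise.
#' @return Data frame with one row per landmark pair: `theta1`, `theta2`,
#'   `truth_cm`, `measured_cm`, `rel_error_pct`.
#' @export
measure_phantom <- function(spec, intrinsics = camera_intrinsics(),
                            near = 1.2, far = 1.8, noise_sd = 0,
                            seed = NULL) {
  frame <- render_phantom(spec, intrinsics, noise_sd = noise_sd, seed = seed)
  seg <- segment_depth(frame, near, far)
  img <- backproject_and_flatten(seg)
  ctr <- planar_centroid(img)
  measured <- mapply(function(t1, t2) {
    p1 <- silhouette_boundary_point(img, t1, ctr)
    p2 <- silhouette_boundary_point(img, t2, ctr)
    measure_distance(img, p1, p2)
  }, spec$landmarks$theta1, spec$landmarks$theta2)
  data.frame(theta1 = spec$landmarks$theta1, theta2 = spec$landmarks$theta2,
             truth_cm = spec$truth, measured_cm = measured,
             rel_error_pct = 100 * abs(measured - spec$truth) / spec$truth)
}

#' Write / read a depth frame as a CSV matrix
#'
#' Depth frames are stored as plain CSV matrices of metric depth (one row
#' per image row), the storage format of the original acquisition chain.
#'
#' @param frame A [depth_frame()].
#' @param path CSV file.
#' @return `path` invisibly (write); a [depth_frame()] (read).
#' @export
write_depth_csv <- function(frame, path) {
  stopifnot(inherits(frame, "depth_frame"))
  utils::write.table(frame$depth, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_csv
#' @param intrinsics Intrinsics to attach on read.
#' @export
read_depth_csv <- function(path, intrinsics = camera_intrinsics()) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  depth_frame(m, intrinsics)
}

#' Export a depth frame as a normalized grayscale PNG
#'
#' For visualization only: depths are min-max scaled to \[0, 1\] (zeros
#' stay black).
#'
#' @param frame A [depth_frame()].
#' @param path PNG file.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(frame, path) {
  stopifnot(inherits(frame, "depth_frame"))
  d <- frame$depth
  pos <- d > 0
  g <- matrix(0, nrow(d), ncol(d))
  if (any(pos)) {
    rng <- range(d[pos])
    g[pos] <- if (diff(rng) == 0) 1 else (d[pos] - rng[1]) / diff(rng)
  }
  png::writePNG(g, path)
  invisible(path)
}

#' Silhouette height at a horizontal station
#'
#' Vertical extent (cm) of the occupied cells in the 1 cm column band
#' starting at `x_cm`, used to read body heights off the planar silhouette
#' at, e.g., the girth or abdomen station.
#'
#' @param image A `planar_image`.
#' @param x_cm Station (left edge of the 1 cm band), cm, image coordinates.
#' @return Height in cm.
#' @export
silhouette_height <- function(image, x_cm) {
  stopifnot(inherits(image, "planar_image"))
  j <- floor(x_cm - image$origin[["x"]]) + 1
  if (j < 1 || j > ncol(image$counts))
    stop("station outside the planar image", call. = FALSE)
  rows <- which(image$counts[, j] > 0)
  if (!length(rows)) stop("no silhouette at station ", x_cm, call. = FALSE)
  diff(range(rows)) + 1
}

#' Semi-circumference from a single side view (half-ellipse reconstruction)
#'
#' A single lateral view cannot observe a girth directly; this estimates a
#' body semi-circumference as half the perimeter of an ellipse whose
#' vertical axis is the silhouette height at the station and whose
#' (unobserved) transverse axis defaults to the same value.  The perimeter
#' uses Ramanujan's approximation.  This is a documented reconstruction, not
#' a measurement: its accuracy depends entirely on the assumed transverse
#' depth.
#'
#' @param height_cm Silhouette height at the station, cm.
#' @param depth_cm Assumed transverse body depth, cm (default `height_cm`,
#'   i.e. a circular cross-section).
#' @return Semi-circumference in cm.
#' @export
semi_circumference <- function(height_cm, depth_cm = height_cm) {
  if (any(height_cm <= 0) || any(depth_cm <= 0))
    stop("height and depth must be strictly positive", call. = FALSE)
  a <- height_cm / 2; b <- depth_cm / 2
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h))) / 2
}
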