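test_that("the renderer agrees with closed-form ray geometry", {
  spec <- phantom_spec(semi_axes = c(40, 25, 15), distance = 1.5)
  frame <- render_phantom(spec)
  K <- frame$intrinsics

  # centre pixel depth = distance - front semi-axis (ray along the axis)
  centre <- frame$depth[round(K$cy) + 1, round(K$cx) + 1]
  expect_equal(centre, 1.5 - 0.15, tolerance = 1e-3)

  # doubling the distance halves the projected pixel extent (similar triangles)
  sil1 <- attr(frame, "silhouette")
  spec2 <- phantom_spec(semi_axes = c(40, 25, 15), distance = 3.0)
  sil2 <- attr(render_phantom(spec2, background = 4), "silhouette")
  w1 <- diff(range(which(colSums(sil1) > 0)))
  w2 <- diff(range(which(colSums(sil2) > 0)))
  expect_equal(w1 / w2, 2, tolerance = 0.05)

  expect_error(phantom_spec(semi_axes = c(40, 25, 15), distance = 0.1),
               "behind")
})

test_that("Z-threshold segmentation keeps exactly the in-range pixels", {
  K <- camera_intrinsics()
  flat <- function(z) depth_frame(matrix(z, K$height, K$width), K)

  expect_equal(sum(segment_depth(flat(2.5))$mask), 0)     # background only
  expect_equal(sum(segment_depth(flat(1.5))$mask),
               K$height * K$width)                         # uniform in-range
  # zeros ("no return") are always removed
  d <- matrix(1.5, K$height, K$width); d[1:10, 1:10] <- 0
  expect_equal(sum(segment_depth(depth_frame(d, K))$mask),
               K$height * K$width - 100)

  # phantom on background: mask equals the renderer's own silhouette
  spec <- phantom_spec(semi_axes = c(45, 28, 16), distance = 1.5)
  frame <- render_phantom(spec)
  seg <- segment_depth(frame)
  expect_identical(seg$mask, attr(frame, "silhouette"))

  # idempotence: segmenting an already segmented frame is a no-op
  seg2 <- segment_depth(seg$frame)
  expect_identical(seg2$mask, seg$mask)
  expect_identical(seg2$frame$depth, seg$frame$depth)

  expect_error(segment_depth(frame, near = 2, far = 1), "below")
})

test_that("back-projection places points by the pinhole equations", {
  K <- camera_intrinsics()
  # a single pixel at the principal point maps to a single cell at the origin
  d <- matrix(0, K$height, K$width)
  u0 <- round(K$cx); v0 <- round(K$cy)
  d[v0 + 1, u0 + 1] <- 1.5
  seg <- segment_depth(depth_frame(d, K))
  img <- backproject_and_flatten(seg)
  expect_equal(sum(img$counts > 0), 1)
  idx <- which(img$counts > 0, arr.ind = TRUE)
  x_cm <- unname(img$origin[["x"]] + idx[1, 2] - 1)
  expect_equal(x_cm, floor((u0 - K$cx) * 1.5 / K$fx * 100))

  # a phantom of known width: occupied horizontal extent within 2 cm
  spec <- phantom_spec(semi_axes = c(50, 30, 15), distance = 1.5)
  img <- backproject_and_flatten(segment_depth(render_phantom(spec)))
  occ <- which(img$counts > 0, arr.ind = TRUE)
  width_cm <- diff(range(occ[, 2])) + 1
  expect_lt(abs(width_cm - 100), 2 + 100 * (0.15 / 1.5)^2)  # bin + contour terms

  # scaling all depths by k scales the occupied extent by k
  spec2 <- phantom_spec(semi_axes = c(50, 30, 15) * 0.8, distance = 1.2)
  frame <- render_phantom(spec2)
  seg <- segment_depth(frame, 1.0, 1.4)
  k <- 1.3
  scaled <- depth_frame(frame$depth * k, frame$intrinsics)
  seg_k <- segment_depth(scaled, 1.0 * k, 1.4 * k)
  e1 <- backproject_and_flatten(seg)
  e2 <- backproject_and_flatten(seg_k)
  w1 <- diff(range(which(colSums(e1$counts > 0) > 0)))
  w2 <- diff(range(which(colSums(e2$counts > 0) > 0)))
  expect_equal(w2 / w1, k, tolerance = 0.05)

  expect_error(backproject_and_flatten(frame, matrix(FALSE, 240, 320)),
               "empty")
})

test_that("planar distances are Euclidean, symmetric and metric", {
  img <- structure(list(counts = matrix(1L, 20, 20), origin = c(x = 0, y = 0)),
                   class = "planar_image")
  expect_equal(measure_distance(img, c(3, 4), c(3, 4)), 0)
  expect_equal(measure_distance(img, c(0, 0), c(3, 4)), 5)
  set.seed(6)
  for (i in 1:20) {
    p <- matrix(runif(6, 0, 20), 3, 2)
    d12 <- measure_distance(img, p[1, ], p[2, ])
    d21 <- measure_distance(img, p[2, ], p[1, ])
    d13 <- measure_distance(img, p[1, ], p[3, ])
    d23 <- measure_distance(img, p[2, ], p[3, ])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
  expect_error(measure_distance(img, c(-5, 0), c(1, 1)), "outside")
})

test_that("noise-free phantoms are measured within 5% end to end", {
  specs <- list(phantom_spec(c(50, 30, 18), 1.5),
                phantom_spec(c(55, 33, 20), 1.4),
                phantom_spec(c(42, 26, 14), 1.6),
                phantom_spec(c(60, 28, 16), 1.5),
                phantom_spec(c(45, 35, 15), 1.3))
  for (spec in specs) {
    res <- measure_phantom(spec)
    expect_equal(nrow(res), 5)
    expect_true(all(res$rel_error_pct < 5))
  }
})

test_that("2 cm depth noise keeps landmark errors within 8%", {
  spec <- phantom_spec(c(50, 30, 18), 1.5)
  res <- measure_phantom(spec, noise_sd = 0.02, seed = 42)
  expect_true(all(res$rel_error_pct < 8))
})

test_that("depth frames round-trip through CSV and export to PNG", {
  spec <- phantom_spec(c(40, 25, 15), 1.5)
  frame <- render_phantom(spec)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_depth_csv(frame, csv)
  back <- read_depth_csv(csv)
  expect_equal(back$depth, frame$depth, tolerance = 1e-10)

  png_path <- withr::local_tempfile(fileext = ".png")
  write_depth_png(frame, png_path)
  g <- png::readPNG(png_path)
  expect_equal(dim(g), c(240, 320))
  expect_true(all(g >= 0 & g <= 1))
})

test_that("semi-circumference reconstruction matches the ellipse perimeter", {
  # circular cross-section: half-perimeter is exactly pi * d / 2
  expect_equal(semi_circumference(10, 10), pi * 10 / 2, tolerance = 1e-12)
  # Ramanujan approximation vs numeric arc-length integral
  a <- 30 / 2; b <- 18 / 2
  arc <- integrate(function(t) sqrt((a * sin(t))^2 + (b * cos(t))^2),
                   0, 2 * pi, rel.tol = 1e-10)$value
  expect_equal(semi_circumference(30, 18), arc / 2, tolerance = 1e-5)
  expect_error(semi_circumference(0), "positive")

  # silhouette height at the phantom centre ~ the vertical diameter
  spec <- phantom_spec(c(50, 30, 18), 1.5)
  img <- backproject_and_flatten(segment_depth(render_phantom(spec)))
  ctr <- bwestim:::planar_centroid(img)
  h <- silhouette_height(img, ctr[["x"]])
  expect_lt(abs(h - 60) / 60, 0.05)
  expect_error(silhouette_height(img, 1e4), "outside")
})
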