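test_that("Gaussian field evaluation matches closed forms", {
  f <- gaussian_field(height = 20, width = 15.7, center = -40)
  expect_equal(field_value(f, -40), 20)
  expect_equal(field_value(f, -40 + 15.7), 20 * exp(-1 / 2))
  g <- gaussian_field(1, 1, center = 1.5)
  expect_equal(field_value(g, 0), exp(-1.125), tolerance = 1e-12)
  # strictly positive everywhere, even far out
  expect_true(all(field_value(f, seq(-500, 500, by = 50)) > 0))
})

test_that("field gradient is the analytic derivative", {
  f <- gaussian_field(1, 1, center = 1.5)
  expect_equal(field_gradient(f, 1.5), 0)
  expect_equal(field_gradient(f, 0), 1.5 * exp(-1.125), tolerance = 1e-12)
  # central finite difference agreement at random points
  set.seed(11)
  xs <- runif(100, -60, 60)
  f2 <- gaussian_field(7.3, 12.1, center = -8)
  h <- 1e-6
  fd <- (field_value(f2, xs + h) - field_value(f2, xs - h)) / (2 * h)
  an <- field_gradient(f2, xs)
  expect_lt(max(abs(fd - an) / (abs(an) + 1e-12)), 1e-5)
  # sign pattern of a Gaussian bump
  expect_true(all(field_gradient(f2, seq(-60, -9, by = 1)) > 0))
  expect_true(all(field_gradient(f2, seq(-7, 60, by = 1)) < 0))
})

test_that("degenerate field parameters are rejected at construction", {
  expect_error(gaussian_field(10, 0), "width")
  expect_error(gaussian_field(10, -3), "width")
  expect_error(gaussian_field(0, 5), "height")
})

test_that("equal-parameter environments are mirror symmetric", {
  env <- chemokine_env(10, 25, k = 50)
  expect_equal(env$f1$center, -50)
  expect_equal(env$f2$center, 50)
  set.seed(3)
  xs <- runif(100, -150, 150)
  expect_equal(field_value(env$f1, xs), field_value(env$f2, -xs))
  expect_equal(field_gradient(env$f1, xs), -field_gradient(env$f2, -xs))
})

test_that("voxel grids reproduce centroid values exactly", {
  env <- chemokine_env(10, 25, k = 50)
  b <- rbind(c(-120, 120), c(-30, 30), c(-30, 30))
  gr <- discretize_env(env, b, spacing = 5)
  # a handful of centroids across the grid
  for (idx in list(c(1, 1, 1), c(10, 3, 7), c(48, 12, 12))) {
    p <- b[, 1] + (idx - 0.5) * 5
    expect_identical(grid_interpolate(gr$grid1, p),
                     field_value(env$f1, p[1]))
  }
  # midpoint of two adjacent centroids along x: arithmetic mean
  p1 <- b[, 1] + (c(10, 3, 7) - 0.5) * 5
  p2 <- p1 + c(5, 0, 0)
  mid <- (p1 + p2) / 2
  expect_equal(grid_interpolate(gr$grid1, mid),
               (field_value(env$f1, p1[1]) + field_value(env$f1, p2[1])) / 2)
})

test_that("trilinear interpolation is exact on linear fields and constants", {
  vals <- array(0, c(6, 6, 6))
  orig <- c(0, 0, 0); h <- 2
  cent <- (seq_len(6) - 0.5) * h
  for (i in 1:6) for (j in 1:6) for (l in 1:6)
    vals[i, j, l] <- 3 + 0.5 * cent[i] + 1.25 * cent[j] - 0.75 * cent[l] + 20
  g <- voxel_grid(vals, orig, h)
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(3, min = h, max = 5 * h)  # inside centroid hull
    expect_equal(grid_interpolate(g, p),
                 23 + 0.5 * p[1] + 1.25 * p[2] - 0.75 * p[3],
                 tolerance = 1e-12)
    expect_equal(grid_interpolate_gradient(g, p), c(0.5, 1.25, -0.75),
                 tolerance = 1e-10)
  }
  cg <- voxel_grid(array(4.2, c(4, 4, 4)), orig, h)
  p <- c(3.3, 5.1, 2.2)
  expect_equal(grid_interpolate(cg, p), 4.2)
  expect_equal(grid_interpolate_gradient(cg, p), c(0, 0, 0))
})

test_that("grid interpolation error is bounded and converges with spacing", {
  env <- chemokine_env(10, 25, k = 50)
  b <- rbind(c(-130, 130), c(-20, 20), c(-20, 20))
  # second-derivative bound of the field: |f''| <= c / w^2 for a Gaussian
  fmax2 <- 10 / 25^2
  err_at <- function(spacing) {
    gr <- discretize_env(env, b, spacing = spacing)
    set.seed(17)
    pts <- cbind(runif(1000, -100, 100), runif(1000, -10, 10),
                 runif(1000, -10, 10))
    max(vapply(seq_len(nrow(pts)), function(i)
      abs(grid_interpolate(gr$grid1, pts[i, ]) -
            field_value(env$f1, pts[i, 1])), numeric(1)))
  }
  e5 <- err_at(5)
  expect_lt(e5, (5^2 / 8) * fmax2)
  e2.5 <- err_at(2.5)
  expect_lt(e2.5, e5 / 3.8)  # halving spacing at least ~quarters the error
})

test_that("invalid discretization requests are rejected", {
  env <- chemokine_env(10, 25, k = 50)
  b <- rbind(c(-120, 120), c(-30, 30), c(-30, 30))
  expect_error(discretize_env(env, b, spacing = 0), "positive")
  b_off <- rbind(c(60, 120), c(-30, 30), c(-30, 30))
  expect_error(discretize_env(env, b_off, 5), "centers")
  gr <- discretize_env(env, b, 5)
  expect_error(grid_interpolate(gr$grid1, c(1000, 0, 0)), "hull")
})

test_that("voxel grids round-trip through the text format", {
  env <- chemokine_env(3, 10, k = 20)
  b <- rbind(c(-50, 50), c(-10, 10), c(-10, 10))
  gr <- discretize_env(env, b, 5)$grid1
  path <- tempfile(fileext = ".txt")
  write_voxel_grid(gr, path)
  gr2 <- read_voxel_grid(path)
  expect_equal(gr2$values, gr$values)
  expect_equal(gr2$origin, gr$origin)
  expect_equal(gr2$spacing, gr$spacing)
  unlink(path)
})
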