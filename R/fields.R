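#' Static Gaussian chemokine field
#'
#' A one-dimensional chemokine concentration profile of the form
#' \deqn{f(x) = c \exp\left(-\frac{(x - x_0)^2}{2 w^2}\right)}
#' where \code{height} (c) is the peak concentration, \code{width} (w) the
#' Gaussian width in micrometres and \code{center} (x0) the peak position.
#' Concentration is expressed in arbitrary units; positions in micrometres.
#'
#' @param height Peak concentration (> 0).
#' @param width Gaussian width in micrometres (> 0).
#' @param center Peak position in micrometres.
#' @return An object of class \code{gaussian_field}.
#' @examples
#' f <- gaussian_field(height = 20, width = 15.7, center = -40)
#' field_value(f, -40)      # equals the height
#' field_gradient(f, -40)   # zero at the peak
#' @export
gaussian_field <- function(height, width, center = 0) {
  stopifnot(is.numeric(height), length(height) == 1L, is.finite(height),
            is.numeric(width), length(width) == 1L, is.finite(width),
            is.numeric(center), length(center) == 1L, is.finite(center))
  if (height <= 0) stop("'height' must be positive")
  if (width <= 0) stop("'width' must be positive")
  structure(list(height = height, width = width, center = center),
            class = "gaussian_field")
}

#' @export
print.gaussian_field <- function(x, ...) {
  cat(sprintf("Gaussian chemokine field: height %g, width %g um, center %g um\n",
              x$height, x$width, x$center))
  invisible(x)
}

#' Evaluate a Gaussian chemokine field
#'
#' @param field A \code{\link{gaussian_field}}.
#' @param x Numeric vector of cell displacements (micrometres).
#' @return Concentration at \code{x} (strictly positive).
#' @export
field_value <- function(field, x) {
  stopifnot(inherits(field, "gaussian_field"))
  field$height * exp(-(x - field$center)^2 / (2 * field$width^2))
}

#' Analytic spatial gradient of a Gaussian chemokine field
#'
#' @inheritParams field_value
#' @return d f / d x at \code{x}; zero at the peak and odd about it.
#' @export
field_gradient <- function(field, x) {
  stopifnot(inherits(field, "gaussian_field"))
  -((x - field$center) / field$width^2) * field_value(field, x)
}

#' Two-zone chemokine environment
#'
#' The germinal-center environment: a CXCL12 field centred at \code{-k}
#' (dark-zone side in this package's sign convention) and a CXCL13 field at
#' \code{+k}, where \code{k} is the half-distance between the zone centroids
#' in micrometres. Equal heights/widths give an environment that is mirror
#' symmetric under \code{x -> -x} with the two fields exchanged.
#'
#' @param c1,w1 Height and width of the CXCL12 field.
#' @param c2,w2 Height and width of the CXCL13 field (default equal to field 1).
#' @param k Half-separation between zone centroids (>= 0), micrometres.
#' @return An object of class \code{chemokine_env} with elements \code{f1},
#'   \code{f2} (\code{\link{gaussian_field}}s) and \code{k}.
#' @examples
#' env <- chemokine_env(c1 = 10, w1 = 25, k = 50)
#' env_values(env, 0)
#' @export
chemokine_env <- function(c1, w1, c2 = c1, w2 = w1, k) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k >= 0)
  structure(list(f1 = gaussian_field(c1, w1, -k),
                 f2 = gaussian_field(c2, w2, +k),
                 k = k),
            class = "chemokine_env")
}

#' @export
print.chemokine_env <- function(x, ...) {
  cat(sprintf("Chemokine environment: zones at +/-%g um\n", x$k))
  cat(" CXCL12: "); print(x$f1)
  cat(" CXCL13: "); print(x$f2)
  invisible(x)
}

#' Concentrations and gradients of both chemokines
#'
#' @param env A \code{\link{chemokine_env}}.
#' @param x Cell displacement(s), micrometres.
#' @return For \code{env_values}, a list with vectors \code{f1}, \code{f2};
#'   for \code{env_gradients}, vectors \code{g1}, \code{g2}.
#' @export
env_values <- function(env, x) {
  stopifnot(inherits(env, "chemokine_env"))
  list(f1 = field_value(env$f1, x), f2 = field_value(env$f2, x))
}

#' @rdname env_values
#' @export
env_gradients <- function(env, x) {
  stopifnot(inherits(env, "chemokine_env"))
  list(g1 = field_gradient(env$f1, x), g2 = field_gradient(env$f2, x))
}

## ---------------------------------------------------------------------------
## Voxel grids: 3D discretization with trilinear interpolation between
## voxel centroids, as used by the individual-based simulation.
## Centroid of voxel (i, j, l) (0-based) sits at origin + (i + 0.5) * spacing.
## ---------------------------------------------------------------------------

#' Voxelized 3D concentration grid
#'
#' Stores concentrations sampled at voxel centroids together with
#' precomputed per-axis central-difference gradient fields (one-sided at the
#' boundary layers). Queries use trilinear interpolation between the eight
#' surrounding centroids; gradient queries interpolate the precomputed
#' gradient fields so the interpolated gradient is continuous.
#'
#' @param values 3D numeric array of non-negative concentrations at centroids.
#' @param origin Numeric length-3: lower corner of the voxel box (micrometres).
#' @param spacing Voxel edge length in micrometres (> 0, default 5).
#' @return An object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(values, origin = c(0, 0, 0), spacing = 5) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            is.numeric(origin), length(origin) == 3L,
            is.numeric(spacing), length(spacing) == 1L)
  if (spacing <= 0) stop("'spacing' must be positive")
  if (any(values < 0)) stop("grid values must be non-negative")
  g <- structure(list(values = values, origin = as.numeric(origin),
                      spacing = spacing, dim = dim(values)),
                 class = "voxel_grid")
  g$grad <- lapply(1:3, function(ax) .axis_gradient(values, ax, spacing))
  g
}

# central differences along one axis, one-sided at the two boundary layers
.axis_gradient <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  if (n < 2L) return(array(0, d))
  idx <- function(i) {
    args <- list(a)
    args[1 + seq_len(3)] <- lapply(d, seq_len)
    args[[1 + axis]] <- i
    args$drop <- FALSE
    do.call(`[`, args)
  }
  out <- array(0, d)
  assign_slab <- function(i, val) {
    args <- list(out)
    args[1 + seq_len(3)] <- lapply(d, seq_len)
    args[[1 + axis]] <- i
    do.call(`[<-`, c(args, list(value = val)))
  }
  out <- assign_slab(2:(n - 1), (idx(3:n) - idx(1:(n - 2))) / (2 * h))
  out <- assign_slab(1L, (idx(2L) - idx(1L)) / h)
  out <- assign_slab(n, (idx(n) - idx(n - 1L)) / h)
  out
}

#' Discretize a chemokine environment onto voxel grids
#'
#' Samples both chemokine fields at voxel centroids inside \code{bounds}.
#' The 1D environment varies along \code{axis} and is constant in the two
#' transverse directions.
#'
#' @param env A \code{\link{chemokine_env}}.
#' @param bounds 3x2 numeric matrix (rows = axes) of box bounds, micrometres.
#' @param spacing Voxel edge length (default 5 micrometres).
#' @param axis Axis (1, 2 or 3) along which the zones are separated.
#' @return List with voxel grids \code{grid1} (CXCL12) and \code{grid2}
#'   (CXCL13).
#' @export
discretize_env <- function(env, bounds, spacing = 5, axis = 1L) {
  stopifnot(inherits(env, "chemokine_env"),
            is.matrix(bounds), nrow(bounds) == 3L, ncol(bounds) == 2L)
  if (spacing <= 0) stop("'spacing' must be positive")
  if (any(bounds[, 2] <= bounds[, 1])) stop("degenerate bounds")
  lo <- bounds[axis, 1]; hi <- bounds[axis, 2]
  if (-env$k < lo || -env$k > hi || env$k < lo || env$k > hi)
    stop("bounds must contain both field centers along the zone axis")
  n <- pmax(1L, floor((bounds[, 2] - bounds[, 1]) / spacing))
  origin <- bounds[, 1]
  cent <- lapply(1:3, function(a) origin[a] + (seq_len(n[a]) - 0.5) * spacing)
  xs <- cent[[axis]]
  v1 <- field_value(env$f1, xs)
  v2 <- field_value(env$f2, xs)
  expand_axis <- function(vals) {
    a <- array(0, n)
    perm <- c(axis, setdiff(1:3, axis))
    slab <- array(rep(vals, times = prod(n[setdiff(1:3, axis)])),
                  dim = c(n[axis], n[setdiff(1:3, axis)]))
    aperm(slab, order(perm))
  }
  list(grid1 = voxel_grid(expand_axis(v1), origin, spacing),
       grid2 = voxel_grid(expand_axis(v2), origin, spacing))
}

# fractional index coordinates of p in the centroid lattice (0-based)
.grid_coords <- function(grid, p) {
  (p - grid$origin) / grid$spacing - 0.5
}

.trilinear <- function(a, u) {
  d <- dim(a)
  if (any(u < -1e-9) || any(u > d - 1 + 1e-9))
    stop("query point outside the grid's centroid hull")
  i0 <- pmin(pmax(floor(u), 0), d - 2)  # clamp exact-edge queries
  t <- u - i0
  i0 <- as.integer(i0) + 1L  # to 1-based
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) t[1] else 1 - t[1]) *
           (if (dy) t[2] else 1 - t[2]) *
           (if (dz) t[3] else 1 - t[3])
    acc <- acc + wgt * a[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  acc
}

#' Trilinear interpolation on a voxel grid
#'
#' @param grid A \code{\link{voxel_grid}}.
#' @param p Numeric length-3 position (micrometres), strictly inside the
#'   grid's centroid hull.
#' @return Interpolated concentration (scalar) for \code{grid_interpolate};
#'   length-3 gradient vector for \code{grid_interpolate_gradient}.
#' @export
grid_interpolate <- function(grid, p) {
  stopifnot(inherits(grid, "voxel_grid"), length(p) == 3L)
  .trilinear(grid$values, .grid_coords(grid, p))
}

#' @rdname grid_interpolate
#' @export
grid_interpolate_gradient <- function(grid, p) {
  stopifnot(inherits(grid, "voxel_grid"), length(p) == 3L)
  u <- .grid_coords(grid, p)
  vapply(1:3, function(ax) .trilinear(grid$grad[[ax]], u), numeric(1))
}

#' Write / read a voxel grid as plain text with a JSON header
#'
#' The header line (JSON) records origin, spacing and array dimensions; the
#' remaining lines hold the values in column-major order, one per line.
#'
#' @param grid A \code{\link{voxel_grid}}.
#' @param path File path.
#' @return \code{read_voxel_grid} returns a \code{\link{voxel_grid}}.
#' @export
write_voxel_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  hdr <- jsonlite::toJSON(list(origin = grid$origin, spacing = grid$spacing,
                               dim = grid$dim), auto_unbox = FALSE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  writeLines(format(as.vector(grid$values), digits = 17, scientific = TRUE,
                    trim = TRUE), con)
  invisible(path)
}

#' @rdname write_voxel_grid
#' @export
read_voxel_grid <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  vals <- as.numeric(lines[-1])
  voxel_grid(array(vals, dim = hdr$dim), origin = hdr$origin,
             spacing = hdr$spacing)
}
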