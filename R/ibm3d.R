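## 3D individual-based simulation: stochastic chemotaxis over voxelized
## chemokine fields with reflective confinement and optional soft-sphere
## repulsion between cells.

#' Configuration for a 3D individual-based run
#'
#' @param scenario Scenario name or \code{gc_scenario} supplying the
#'   full-model parameters (must be a \code{"full"} scenario).
#' @param override Named parameter overrides passed to
#'   \code{\link{scenario_model}} (e.g. \code{list(k = 44, pi1 = 0.9)}).
#' @param bounds 3x2 matrix of simulation-volume bounds (micrometres); the
#'   default spans the two zones with a transverse cross-section of 100 um.
#' @param spacing Voxel edge length (default 5 um).
#' @param n_cells Number of cells.
#' @param placement \code{"dz"} (uniform in the dark-zone quarter of the
#'   volume), \code{"origin"} (all cells at the volume centre of the
#'   transverse axes with x = 0), or a \code{n_cells x 3} matrix of
#'   positions.
#' @param v0 Initial velocity, length 3 (default (1, 0, 0): unit speed
#'   along the zone axis, as in the 1D reference runs).
#' @param r0 Initial receptor densities, length 2 (default (1, 1)).
#' @param sigma Velocity noise intensity (default 0).
#' @param dt Time step (default 0.01).
#' @param duration Simulated time.
#' @param seed Base RNG seed; cell i uses stream \code{seed + i}.
#' @param sample_every Store every n-th step.
#' @param collisions Enable pairwise soft-sphere repulsion (default FALSE).
#' @param radius Cell radius for collisions (default 5 um).
#' @param k_rep Repulsion spring constant (default 1).
#' @return A list of class \code{ibm_config}.
#' @export
ibm_config <- function(scenario = "fig4_default", override = NULL,
                       bounds = NULL, spacing = 5, n_cells = 1L,
                       placement = "origin", v0 = c(1, 0, 0), r0 = c(1, 1),
                       sigma = 0, dt = 0.01, duration = 1000, seed = 1L,
                       sample_every = 100L, collisions = FALSE,
                       radius = 5, k_rep = 1) {
  sc <- if (is.character(scenario)) load_scenario(scenario) else scenario
  problems <- character(0)
  if (!identical(sc$model, "full"))
    problems <- c(problems, "IBM requires a 'full' model scenario")
  if (spacing <= 0) problems <- c(problems, "spacing must be positive")
  if (dt <= 0) problems <- c(problems, "dt must be positive")
  if (duration <= 0) problems <- c(problems, "duration must be positive")
  if (sigma < 0) problems <- c(problems, "sigma must be non-negative")
  if (n_cells < 1) problems <- c(problems, "n_cells must be at least 1")
  if (is.matrix(placement) &&
      (nrow(placement) != n_cells || ncol(placement) != 3L))
    problems <- c(problems, "placement matrix must be n_cells x 3")
  if (!is.matrix(placement) && !placement %in% c("dz", "origin"))
    problems <- c(problems, "placement must be 'dz', 'origin' or a matrix")
  if (length(problems))
    stop(paste0("invalid IBM config:\n  ", paste(problems, collapse = "\n  ")))
  k <- if (!is.null(override$k)) override$k else sc$parameters$k
  w <- sc$parameters$w
  if (is.null(bounds))
    bounds <- rbind(c(-(k + 3 * w), k + 3 * w), c(-50, 50), c(-50, 50))
  structure(list(scenario = sc, override = override, bounds = bounds,
                 spacing = spacing, n_cells = as.integer(n_cells),
                 placement = placement, v0 = v0, r0 = r0, sigma = sigma,
                 dt = dt, duration = duration, seed = as.integer(seed),
                 sample_every = as.integer(sample_every),
                 collisions = collisions, radius = radius, k_rep = k_rep),
            class = "ibm_config")
}

# parameters needed by the per-step kinetics, extracted once
.ibm_params <- function(sc, override) {
  p <- sc$parameters
  if (!is.null(override)) p[names(override)] <- override
  list(rp1 = receptor_params(p$pi1, p$tau1, p$kappa1, p$delta1),
       rp2 = receptor_params(p$pi2, p$tau2, p$kappa2, p$delta2),
       chi = p$chi, zeta = if (is.null(p$zeta)) 1 else p$zeta,
       gamma = p$gamma,
       epsilon1 = p$epsilon1, epsilon2 = p$epsilon2, k = p$k, w = p$w,
       c = p$c)
}

#' Advance an IBM world by one time step
#'
#' Per cell: interpolate both chemokine concentrations and gradients at the
#' cell position, update receptors by the reduced receptor equation
#' (explicit Euler), relax the velocity towards the chemotactic target
#' velocity plus optional collision forces and additive Gaussian noise,
#' advance the position, and reflect position and normal velocity at the
#' volume boundary.
#'
#' @param world List with elements \code{cells} (n x 8 matrix: x, y, z, vx,
#'   vy, vz, r1, r2), \code{grids} (from \code{\link{discretize_env}}),
#'   \code{bounds}, \code{par} (internal parameter list), \code{radius},
#'   \code{k_rep}, \code{collisions}.
#' @param dt Time step.
#' @param noise Optional n x 3 matrix of standard-normal draws (velocity
#'   noise for this step); NULL for the deterministic step.
#' @param sigma Noise intensity.
#' @return The world with \code{cells} advanced by dt.
#' @export
ibm_step <- function(world, dt, noise = NULL, sigma = 0) {
  cells <- world$cells
  par <- world$par
  n <- nrow(cells)
  rep_force <- matrix(0, n, 3)
  if (world$collisions && n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dvec <- cells[i, 1:3] - cells[j, 1:3]
      dist <- sqrt(sum(dvec^2))
      overlap <- 2 * world$radius - dist
      if (overlap > 0) {
        dir <- if (dist > 0) dvec / dist else c(1, 0, 0)
        f <- world$k_rep * overlap * dir
        rep_force[i, ] <- rep_force[i, ] + f
        rep_force[j, ] <- rep_force[j, ] - f
      }
    }
  }
  sq <- sigma * sqrt(dt)
  for (i in seq_len(n)) {
    pos <- cells[i, 1:3]; vel <- cells[i, 4:6]
    r1 <- cells[i, 7]; r2 <- cells[i, 8]
    f1 <- grid_interpolate(world$grids$grid1, pos)
    f2 <- grid_interpolate(world$grids$grid2, pos)
    g1 <- grid_interpolate_gradient(world$grids$grid1, pos)
    g2 <- grid_interpolate_gradient(world$grids$grid2, pos)
    S <- chemotactic_signal(r1, f1, g1, par$epsilon1) +
      chemotactic_signal(r2, f2, g2, par$epsilon2)
    vel <- vel + dt * (par$gamma * (par$chi * par$zeta * S - vel) +
                         rep_force[i, ])
    if (!is.null(noise)) vel <- vel + sq * noise[i, ]
    r1 <- r1 + dt * receptor_rhs(r1, f1, par$rp1)
    r2 <- r2 + dt * receptor_rhs(r2, f2, par$rp2)
    if (r1 < 0) r1 <- 0
    if (r2 < 0) r2 <- 0
    pos <- pos + dt * vel
    for (ax in 1:3) {
      lo <- world$bounds[ax, 1]; hi <- world$bounds[ax, 2]
      if (pos[ax] < lo) { pos[ax] <- 2 * lo - pos[ax]; vel[ax] <- -vel[ax] }
      if (pos[ax] > hi) { pos[ax] <- 2 * hi - pos[ax]; vel[ax] <- -vel[ax] }
    }
    if (any(!is.finite(c(pos, vel, r1, r2))))
      stop(sprintf("non-finite state for cell %d", i))
    cells[i, ] <- c(pos, vel, r1, r2)
  }
  world$cells <- cells
  world
}

#' Run a 3D individual-based simulation
#'
#' Discretizes the scenario's chemokine environment onto voxel grids
#' (extended one voxel layer beyond the simulation volume so that every
#' confined position has a full interpolation stencil), places the cells,
#' and advances the world with \code{\link{ibm_step}}. Each cell draws its
#' velocity noise from its own RNG stream seeded as \code{seed + cell_id},
#' so results are independent of scheduling order and bitwise reproducible.
#'
#' @param config An \code{\link{ibm_config}}.
#' @return List of class \code{ibm_result}: \code{trajectories} (one
#'   \code{gc_trajectory} per cell with states x, y, z, vx, vy, vz, r1, r2)
#'   and \code{config}.
#' @export
run_ibm <- function(config) {
  stopifnot(inherits(config, "ibm_config"))
  par <- .ibm_params(config$scenario, config$override)
  env <- chemokine_env(c1 = par$c, w1 = par$w, k = par$k)
  pad <- 2 * config$spacing
  gb <- config$bounds + cbind(rep(-pad, 3), rep(pad, 3))
  grids <- discretize_env(env, gb, config$spacing, axis = 1L)
  n <- config$n_cells
  placement_rng <- .cell_rng(config$seed)
  pos0 <- matrix(0, n, 3)
  if (is.matrix(config$placement)) {
    pos0 <- config$placement
  } else if (config$placement == "dz") {
    lo <- config$bounds[, 1]; hi <- config$bounds[, 2]
    u <- matrix(stats::pnorm(placement_rng(3L * n)), n, 3)
    pos0[, 1] <- lo[1] + u[, 1] * 0.25 * (hi[1] - lo[1])
    pos0[, 2] <- lo[2] + u[, 2] * (hi[2] - lo[2])
    pos0[, 3] <- lo[3] + u[, 3] * (hi[3] - lo[3])
  }  # "origin": all zeros
  cells <- cbind(pos0,
                 matrix(rep(config$v0, each = n), n, 3),
                 matrix(rep(config$r0, each = n), n, 2))
  world <- list(cells = cells, grids = grids, bounds = config$bounds,
                par = par, radius = config$radius, k_rep = config$k_rep,
                collisions = config$collisions)
  n_steps <- ceiling(config$duration / config$dt)
  keep <- seq(0L, n_steps, by = config$sample_every)
  times <- keep * config$dt
  store <- lapply(seq_len(n), function(i)
    matrix(NA_real_, length(keep), 8L))
  for (i in seq_len(n)) store[[i]][1, ] <- cells[i, ]
  rngs <- lapply(seq_len(n), function(i) .cell_rng(config$seed + i))
  ki <- 2L
  for (stp in seq_len(n_steps)) {
    noise <- if (config$sigma > 0)
      t(vapply(rngs, function(r) r(3L), numeric(3))) else NULL
    world <- ibm_step(world, config$dt, noise, config$sigma)
    if (ki <= length(keep) && stp == keep[ki]) {
      for (i in seq_len(n)) store[[i]][ki, ] <- world$cells[i, ]
      ki <- ki + 1L
    }
  }
  snames <- c("x", "y", "z", "vx", "vy", "vz", "r1", "r2")
  trajs <- lapply(seq_len(n), function(i)
    .new_trajectory(times, store[[i]],
                    list(model = "ibm3d", state_names = snames,
                         integrator = "euler-maruyama", dt = config$dt,
                         sigma = config$sigma, seed = config$seed,
                         cell_id = i)))
  structure(list(trajectories = trajs, config = config),
            class = "ibm_result")
}

#' @export
print.ibm_result <- function(x, ...) {
  cat(sprintf("<ibm_result> %d cell(s), duration %g, sigma = %g\n",
              length(x$trajectories), x$config$duration, x$config$sigma))
  invisible(x)
}
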