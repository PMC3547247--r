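## Deterministic and stochastic integration of the migration models.

.new_trajectory <- function(times, states, meta) {
  colnames(states) <- meta$state_names
  structure(list(times = times, states = states, meta = meta),
            class = "gc_trajectory")
}

#' Construct a trajectory from raw samples
#'
#' Mostly useful for analysing externally produced series with the
#' classification tools; the integrators build trajectories directly.
#'
#' @param times Strictly increasing sample times.
#' @param states Matrix of states (one row per time) or a numeric vector of
#'   displacements (stored as column \code{x}).
#' @param state_names Column names (default: x, v, r1, r2 prefix).
#' @param model Model name stored in the metadata.
#' @return A \code{gc_trajectory}.
#' @export
trajectory <- function(times, states, state_names = NULL, model = "custom") {
  if (is.null(dim(states))) states <- matrix(states, ncol = 1)
  if (is.null(state_names))
    state_names <- c("x", "v", "r1", "r2")[seq_len(ncol(states))]
  stopifnot(length(times) == nrow(states), all(diff(times) > 0))
  .new_trajectory(times, states,
                  list(model = model, state_names = state_names))
}

#' @export
print.gc_trajectory <- function(x, ...) {
  cat(sprintf("<gc_trajectory> model '%s', %d samples on t in [%g, %g]\n",
              x$meta$model, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.gc_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states)
}

#' Integrate a model deterministically
#'
#' Adaptive-step integration (lsoda via \pkg{deSolve}) of a
#' \code{gc_model}'s right-hand side, sampled at the requested output times.
#'
#' @param model A \code{gc_model}.
#' @param state0 Initial state (x, v, r1, r2).
#' @param times Output times (strictly increasing, starting at t0).
#' @param rtol,atol Relative and absolute tolerances.
#' @return A \code{gc_trajectory}.
#' @examples
#' env <- chemokine_env(20, 15.7, k = 30)
#' m <- toy_model(env, toy_params(0.3, 1, 0.001, 0.001, 1))
#' tr <- integrate_ode(m, c(0, 1, 1, 1), seq(0, 100, by = 1))
#' @export
integrate_ode <- function(model, state0, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "gc_model"), length(state0) == 4L,
            all(is.finite(state0)), all(diff(times) > 0))
  f <- function(t, y, parms) list(model$rhs(y))
  sol <- deSolve::ode(y = as.numeric(state0), times = times, func = f,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (nrow(sol) < length(times) || any(!is.finite(sol)))
    stop(sprintf("integration failed near t = %g", sol[nrow(sol), 1]))
  .new_trajectory(sol[, 1], unname(sol[, -1, drop = FALSE]),
                  list(model = model$name, state_names = model$state_names,
                       integrator = "lsoda", rtol = rtol, atol = atol))
}

#' Integrate the Langevin model (Euler-Maruyama)
#'
#' Fixed-step Euler-Maruyama integration: the deterministic drift step plus
#' additive Wiener noise \eqn{\sigma\sqrt{dt}\,N(0,1)} on the velocity
#' component only (receptors and position remain noise-free). Runs are
#' bitwise reproducible for a given seed.
#'
#' @param model A \code{gc_model}.
#' @param state0 Initial state (x, v, r1, r2).
#' @param t_end Final time (integration starts at 0).
#' @param dt Fixed time step (default 0.01).
#' @param sigma Noise intensity; defaults to the model's own \code{sigma}.
#' @param seed Integer RNG seed (required).
#' @param sample_every Store every n-th step (default 1).
#' @return A \code{gc_trajectory}.
#' @export
integrate_sde <- function(model, state0, t_end, dt = 0.01,
                          sigma = model$sigma, seed, sample_every = 1L) {
  stopifnot(inherits(model, "gc_model"), dt > 0, sigma >= 0,
            length(state0) == 4L)
  if (missing(seed)) stop("'seed' must be supplied for reproducibility")
  n_steps <- ceiling(t_end / dt)
  keep <- seq(0L, n_steps, by = sample_every)
  out <- matrix(NA_real_, length(keep), 4L)
  times <- keep * dt
  rng <- .cell_rng(seed)
  state <- as.numeric(state0)
  out[1, ] <- state
  ki <- 2L
  sq <- sigma * sqrt(dt)
  for (i in seq_len(n_steps)) {
    state <- state + dt * model$rhs(state)
    if (sigma > 0) state[2] <- state[2] + sq * rng()
    if (any(!is.finite(state)))
      stop(sprintf("SDE state non-finite at t = %g (dt too large?)", i * dt))
    if (ki <= length(keep) && i == keep[ki]) {
      out[ki, ] <- state
      ki <- ki + 1L
    }
  }
  .new_trajectory(times, out,
                  list(model = model$name, state_names = model$state_names,
                       integrator = "euler-maruyama", dt = dt,
                       sigma = sigma, seed = seed))
}

# Per-stream standard-normal generator: isolates the package's draws from
# the global RNG state and lets each simulated cell own a stream seeded as
# base_seed + cell_index.
.cell_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  function(n = 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    z <- stats::rnorm(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    z
  }
}

#' Write / read a trajectory as tidy CSV with a JSON sidecar
#'
#' The CSV holds one row per sample (time plus state columns); the sidecar
#' \code{<path>.json} records the model name, integrator settings and seed
#' so a run can be reproduced exactly.
#'
#' @param traj A \code{gc_trajectory}.
#' @param path CSV file path.
#' @return \code{read_trajectory} returns a \code{gc_trajectory}.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "gc_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  jsonlite::write_json(traj$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else
    list(model = "unknown", state_names = colnames(df)[-1])
  meta$state_names <- colnames(df)[-1]
  .new_trajectory(df$time, as.matrix(df[, -1, drop = FALSE]), meta)
}
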