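## Model right-hand sides for chemokine-driven B-cell migration.
##
## State vector throughout: (x, v, r1, r2) — displacement along the
## dark-zone/light-zone axis (um), velocity (um per time unit), and surface
## densities of the two chemokine receptors (CXCR4, CXCR5; arbitrary units).
## Time is in abstract model units chosen so that the bundled scenario
## parameter sets give oscillations with periods on the scale of hours.

#' Toy-model parameters
#'
#' Receptor synthesis rates \code{pi1}, \code{pi2}, constitutive degradation
#' rates \code{delta1}, \code{delta2} and the velocity drag coefficient
#' \code{gamma}. In the toy model the chemokine concentration itself acts as
#' the (mass-action) down-regulation rate of its cognate receptor.
#'
#' @param pi1,pi2 Synthesis rates (>= 0).
#' @param delta1,delta2 Degradation rates (>= 0).
#' @param gamma Drag coefficient (>= 0).
#' @return A list of class \code{toy_params}.
#' @export
toy_params <- function(pi1, pi2, delta1, delta2, gamma) {
  p <- list(pi1 = pi1, pi2 = pi2, delta1 = delta1, delta2 = delta2,
            gamma = gamma)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                         is.finite(v) && v >= 0, logical(1))))
  structure(p, class = "toy_params")
}

#' Receptor trafficking parameters (reduced single-receptor equation)
#'
#' Parameters of the quasi-steady-state receptor equation
#' \deqn{dr/dt = \pi - r\,\tau\,\kappa f/(1+\kappa f) - \delta r,}
#' obtained from mass-action GPCR trafficking by eliminating the fast
#' ligand-binding step: \code{kappa} is a rescaled equilibrium association
#' constant, \code{tau} the removal rate of bound receptor and \code{delta}
#' the constitutive degradation rate.
#'
#' @param pi Synthesis rate (>= 0).
#' @param tau Bound-receptor removal rate (>= 0).
#' @param kappa Rescaled equilibrium association constant (>= 0).
#' @param delta Constitutive degradation rate (>= 0).
#' @return A list of class \code{receptor_params}.
#' @export
receptor_params <- function(pi, tau, kappa, delta) {
  p <- list(pi = pi, tau = tau, kappa = kappa, delta = delta)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                         is.finite(v) && v >= 0, logical(1))))
  structure(p, class = "receptor_params")
}

#' Chemotaxis parameters for the phenomenological model
#'
#' \code{chi} is the chemotactic responsiveness, \code{epsilon1}/\code{epsilon2}
#' the effective equilibrium association constants of the signalling arm
#' (kept distinct from the trafficking constants \code{kappa} to allow
#' differential coupling of bound receptor to signal transduction),
#' \code{zeta} an overall signal scale, \code{gamma} the velocity relaxation
#' rate and \code{sigma} the Langevin noise intensity (0 for the
#' deterministic model).
#'
#' @param chi Chemotactic responsiveness (>= 0).
#' @param epsilon1,epsilon2 Effective association constants (>= 0).
#' @param zeta Signal scaling (default 1).
#' @param gamma Velocity relaxation (drag) rate (>= 0).
#' @param sigma Noise intensity on velocity (>= 0, default 0).
#' @return A list of class \code{chemotaxis_params}.
#' @export
chemotaxis_params <- function(chi, epsilon1, epsilon2, gamma, zeta = 1,
                              sigma = 0) {
  p <- list(chi = chi, epsilon1 = epsilon1, epsilon2 = epsilon2,
            zeta = zeta, gamma = gamma, sigma = sigma)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                         is.finite(v), logical(1))),
            p$chi >= 0, p$gamma >= 0, p$sigma >= 0,
            p$epsilon1 >= 0, p$epsilon2 >= 0)
  structure(p, class = "chemotaxis_params")
}

#' Saturable chemotactic receptor signal
#'
#' The directional signal contributed by one receptor species: the receptor
#' density multiplied by the spatial derivative of the saturable occupancy
#' \eqn{\epsilon f/(1+\epsilon f)}, i.e.
#' \deqn{S = r\,\epsilon f'(x) / (1 + \epsilon f(x))^2.}
#' The signal depends on both the local ligand concentration (through the
#' saturation) and the receptor density (linearly), and vanishes at a field
#' peak. This function is the single swappable definition used by the full
#' model, the Langevin model and the 3D individual-based simulation.
#'
#' @param r Receptor density (scalar or vector).
#' @param f Local chemokine concentration.
#' @param g Local chemokine gradient (scalar, or 3-vector in the IBM).
#' @param epsilon Effective equilibrium association constant.
#' @return Signal with the dimensionality of \code{g}.
#' @export
chemotactic_signal <- function(r, f, g, epsilon) {
  r * epsilon * g / (1 + epsilon * f)^2
}

#' Steady-state receptor density of the toy model
#'
#' At a fixed position with local cognate concentration \code{f_local},
#' receptor synthesis balances chemokine-driven plus constitutive loss at
#' \eqn{r^{SS} = \pi/(\delta + f)}.
#'
#' @param pi Synthesis rate.
#' @param delta Degradation rate.
#' @param f_local Local chemokine concentration.
#' @return Steady-state receptor density.
#' @export
toy_receptor_steady_state <- function(pi, delta, f_local) {
  if (any(delta + f_local <= 0)) stop("delta + f_local must be positive")
  pi / (delta + f_local)
}

#' Reduced receptor equation right-hand side and steady state
#'
#' @param r Receptor density.
#' @param f_local Local cognate chemokine concentration.
#' @param rp A \code{\link{receptor_params}}.
#' @return \code{receptor_rhs}: dr/dt. \code{receptor_steady_state}: the
#'   fixed point \eqn{\pi/(\delta + \tau\kappa f/(1+\kappa f))}.
#' @export
receptor_rhs <- function(r, f_local, rp) {
  rp$pi - r * rp$tau * rp$kappa * f_local / (1 + rp$kappa * f_local) -
    rp$delta * r
}

#' @rdname receptor_rhs
#' @export
receptor_steady_state <- function(f_local, rp) {
  den <- rp$delta + rp$tau * rp$kappa * f_local / (1 + rp$kappa * f_local)
  if (any(den <= 0)) stop("zero removal rate: no finite steady state")
  rp$pi / den
}

## ---------------------------------------------------------------------------
## Mass-action GPCR trafficking (unreduced)
## ---------------------------------------------------------------------------

#' Mass-action GPCR trafficking parameters
#'
#' Unbound receptors (U) bind ligand at rate \code{k_on} and unbind at
#' \code{k_off}; bound receptors (B) are internalized at \code{mu};
#' internalized receptors (I) are degraded at \code{delta} or recycled at
#' \code{beta}; new receptor is synthesized at \code{pi}; unbound receptor
#' is removed at first-order rate \code{tau} (needed so U stays finite
#' without ligand).
#'
#' @param k_on,k_off,mu,beta,delta,pi,tau Non-negative rates.
#' @return A list of class \code{mass_action_params}.
#' @export
mass_action_params <- function(k_on, k_off, mu, beta, delta, pi, tau) {
  p <- list(k_on = k_on, k_off = k_off, mu = mu, beta = beta,
            delta = delta, pi = pi, tau = tau)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                         is.finite(v) && v >= 0, logical(1))))
  structure(p, class = "mass_action_params")
}

#' Mass-action trafficking right-hand side
#'
#' @param state Numeric length-3: (U, B, I), all >= 0.
#' @param L Ligand concentration (>= 0).
#' @param mp A \code{\link{mass_action_params}}.
#' @return d(U, B, I)/dt.
#' @export
mass_action_rhs <- function(state, L, mp) {
  U <- state[1]; B <- state[2]; I <- state[3]
  c(mp$pi - mp$k_on * L * U + mp$k_off * B + mp$beta * I - mp$tau * U,
    mp$k_on * L * U - mp$k_off * B - mp$mu * B,
    mp$mu * B - mp$beta * I - mp$delta * I)
}

#' Quasi-steady-state reduction of the mass-action trafficking scheme
#'
#' When ligand binding and unbinding are fast, the bound fraction
#' equilibrates at \eqn{B/U = \hat\kappa L} with
#' \eqn{\hat\kappa = k_{on}/(k_{off}+\mu)}, and the total surface receptor
#' \eqn{r = U + B} obeys the reduced receptor equation with
#' \code{kappa} = \eqn{\hat\kappa}, \code{delta} = \code{tau} (constitutive
#' loss of unbound receptor) and \code{tau} = \eqn{\mu - \tau} (excess
#' removal of bound receptor). Recycling of the internalized pool is
#' neglected (valid when synthesis dominates, \eqn{\pi \gg \mu B}).
#'
#' @param mp A \code{\link{mass_action_params}}.
#' @return A \code{\link{receptor_params}}.
#' @export
reduce_mass_action <- function(mp) {
  stopifnot(inherits(mp, "mass_action_params"))
  if (mp$mu < mp$tau) stop("reduction requires mu >= tau")
  receptor_params(pi = mp$pi, tau = mp$mu - mp$tau,
                  kappa = mp$k_on / (mp$k_off + mp$mu), delta = mp$tau)
}

## ---------------------------------------------------------------------------
## Model objects
## ---------------------------------------------------------------------------

.new_model <- function(name, env, rhs, nullcline, force, gamma, sigma = 0,
                       active = 1:4) {
  structure(list(name = name, env = env, rhs = rhs, nullcline = nullcline,
                 force = force, gamma = gamma, sigma = sigma,
                 active = active,
                 state_names = c("x", "v", "r1", "r2")),
            class = "gc_model")
}

#' @export
print.gc_model <- function(x, ...) {
  cat(sprintf("<gc_model '%s'> state: (%s); zones at +/-%g um\n",
              x$name, paste(x$state_names, collapse = ", "), x$env$k))
  invisible(x)
}

#' Toy model of receptor regulation and chemotaxis
#'
#' Receptors are synthesized at constant rate, degraded constitutively, and
#' down-regulated at a rate proportional to receptor times local cognate
#' chemokine; velocity accelerates along the receptor-weighted sum of the
#' chemokine gradients against linear drag:
#' \deqn{dr_i/dt = \pi_i - r_i f_i(x) - \delta_i r_i}
#' \deqn{dx/dt = v, \quad dv/dt = r_1 f_1'(x) + r_2 f_2'(x) - \gamma v}
#'
#' @param env A \code{\link{chemokine_env}}.
#' @param tp A \code{\link{toy_params}}.
#' @return A \code{gc_model}.
#' @export
toy_model <- function(env, tp) {
  stopifnot(inherits(env, "chemokine_env"), inherits(tp, "toy_params"))
  rhs <- function(state) {
    x <- state[1]; v <- state[2]; r1 <- state[3]; r2 <- state[4]
    f <- env_values(env, x); g <- env_gradients(env, x)
    c(v,
      r1 * g$g1 + r2 * g$g2 - tp$gamma * v,
      tp$pi1 - r1 * f$f1 - tp$delta1 * r1,
      tp$pi2 - r2 * f$f2 - tp$delta2 * r2)
  }
  nullcline <- function(x) {
    f <- env_values(env, x)
    c(toy_receptor_steady_state(tp$pi1, tp$delta1, f$f1),
      toy_receptor_steady_state(tp$pi2, tp$delta2, f$f2))
  }
  force <- function(x) {  # vectorized over x
    f <- env_values(env, x); g <- env_gradients(env, x)
    toy_receptor_steady_state(tp$pi1, tp$delta1, f$f1) * g$g1 +
      toy_receptor_steady_state(tp$pi2, tp$delta2, f$f2) * g$g2
  }
  .new_model("toy", env, rhs, nullcline, force, tp$gamma)
}

#' Full phenomenological model
#'
#' Couples the reduced (quasi-steady-state) receptor equations for CXCR4 and
#' CXCR5 to a persistent-random-walk chemotaxis model in which the velocity
#' relaxes at rate \eqn{\gamma} towards a chemotactic target velocity set by
#' saturable receptor signals:
#' \deqn{dr_i/dt = \pi_i - r_i\tau_i\kappa_i f_i/(1+\kappa_i f_i) - \delta_i r_i}
#' \deqn{dx/dt = v, \quad
#'   dv/dt = \gamma\left[\chi\zeta\,(S_1 + S_2) - v\right]}
#' with \eqn{S_i} the \code{\link{chemotactic_signal}}. Setting
#' \code{cp$sigma > 0} and integrating with \code{\link{integrate_sde}}
#' yields the Langevin version with additive Wiener noise on velocity.
#'
#' @param env A \code{\link{chemokine_env}}.
#' @param rp1,rp2 \code{\link{receptor_params}} for CXCR4 and CXCR5.
#' @param cp A \code{\link{chemotaxis_params}}.
#' @return A \code{gc_model}.
#' @export
full_model <- function(env, rp1, rp2, cp) {
  stopifnot(inherits(env, "chemokine_env"), inherits(rp1, "receptor_params"),
            inherits(rp2, "receptor_params"), inherits(cp, "chemotaxis_params"))
  signal <- function(x, r1, r2) {
    f <- env_values(env, x); g <- env_gradients(env, x)
    chemotactic_signal(r1, f$f1, g$g1, cp$epsilon1) +
      chemotactic_signal(r2, f$f2, g$g2, cp$epsilon2)
  }
  rhs <- function(state) {
    x <- state[1]; v <- state[2]; r1 <- state[3]; r2 <- state[4]
    f <- env_values(env, x)
    c(v,
      cp$gamma * (cp$chi * cp$zeta * signal(x, r1, r2) - v),
      receptor_rhs(r1, f$f1, rp1),
      receptor_rhs(r2, f$f2, rp2))
  }
  nullcline <- function(x) {
    f <- env_values(env, x)
    c(receptor_steady_state(f$f1, rp1), receptor_steady_state(f$f2, rp2))
  }
  force <- function(x) {  # vectorized over x
    f <- env_values(env, x)
    cp$gamma * cp$chi * cp$zeta *
      signal(x, receptor_steady_state(f$f1, rp1),
             receptor_steady_state(f$f2, rp2))
  }
  .new_model("full", env, rhs, nullcline, force, cp$gamma, cp$sigma)
}

#' Single-receptor variant of the full model
#'
#' Identical to \code{\link{full_model}} except that the CXCR5 density is
#' held fixed at \code{r2_fixed}: only CXCR4 is regulated by its chemokine
#' field. Oscillations still arise in this variant, but over a narrower
#' range of zone separations than with reciprocal regulation of both
#' receptors.
#'
#' @inheritParams full_model
#' @param r2_fixed Frozen CXCR5 density (>= 0).
#' @return A \code{gc_model}.
#' @export
single_receptor_model <- function(env, rp1, rp2, cp, r2_fixed) {
  base <- full_model(env, rp1, rp2, cp)
  rhs <- function(state) {
    d <- base$rhs(c(state[1:3], r2_fixed))
    d[4] <- 0
    d
  }
  nullcline <- function(x) {
    f <- env_values(env, x)
    c(receptor_steady_state(f$f1, rp1), r2_fixed)
  }
  force <- function(x) {
    f <- env_values(env, x); g <- env_gradients(env, x)
    r1 <- receptor_steady_state(f$f1, rp1)
    cp$gamma * cp$chi * cp$zeta *
      (chemotactic_signal(r1, f$f1, g$g1, cp$epsilon1) +
         chemotactic_signal(r2_fixed, f$f2, g$g2, cp$epsilon2))
  }
  # r2 is frozen, so stability lives on the (x, v, r1) subsystem
  m <- .new_model("single_receptor", env, rhs, nullcline, force,
                  cp$gamma, cp$sigma, active = 1:3)
  m$r2_fixed <- r2_fixed
  m
}

#' Reduced undamped velocity model
#'
#' With drag removed and the receptor ratio frozen at \eqn{s = r_1/r_2}, the
#' velocity obeys \eqn{dv/dt = s f_1'(x) + f_2'(x)}. Scanning its roots in
#' \eqn{x} (with stability read from the slope of the right-hand side)
#' reproduces the saddle-node structure by which the dark zone, light zone
#' or both can be equilibria depending only on the receptor ratio.
#'
#' @param x Displacement(s).
#' @param s Receptor density ratio r1/r2 (>= 0).
#' @param env A \code{\link{chemokine_env}}.
#' @return \code{reduced_velocity_rhs}: the acceleration at \code{x}.
#' @export
reduced_velocity_rhs <- function(x, s, env) {
  g <- env_gradients(env, x)
  s * g$g1 + g$g2
}

#' @rdname reduced_velocity_rhs
#' @param xlim Scan interval (default spans both fields).
#' @param n Scan resolution.
#' @return \code{reduced_equilibria}: data frame with columns \code{x} and
#'   \code{stable} (TRUE where the slope of the acceleration is negative).
#' @export
reduced_equilibria <- function(s, env, xlim = NULL, n = 4001L) {
  if (is.null(xlim)) {
    w <- max(env$f1$width, env$f2$width)
    xlim <- c(-env$k - 4 * w, env$k + 4 * w)
  }
  xs <- seq(xlim[1], xlim[2], length.out = n)
  fs <- reduced_velocity_rhs(xs, s, env)
  sc <- which(diff(sign(fs)) != 0)
  if (!length(sc)) return(data.frame(x = numeric(0), stable = logical(0)))
  roots <- vapply(sc, function(i)
    stats::uniroot(function(z) reduced_velocity_rhs(z, s, env),
                   c(xs[i], xs[i + 1]), tol = 1e-12)$root, numeric(1))
  roots <- .dedupe_roots(roots, diff(xlim))
  h <- 1e-6 * (1 + abs(roots))
  slope <- (reduced_velocity_rhs(roots + h, s, env) -
              reduced_velocity_rhs(roots - h, s, env)) / (2 * h)
  data.frame(x = roots, stable = slope < 0)
}

# collapse refined roots that coincide (tangential sign changes are caught
# twice by the grid scan)
.dedupe_roots <- function(roots, span) {
  if (length(roots) < 2L) return(roots)
  roots <- sort(roots)
  keep <- c(TRUE, diff(roots) > 1e-8 * span)
  roots[keep]
}

#' Jacobian of a model right-hand side
#'
#' Central finite differences with step scaled to the state magnitude
#' (1e-6 * (1 + |state|) per component).
#'
#' @param model A \code{gc_model}.
#' @param state State vector at which to differentiate.
#' @return Square Jacobian matrix.
#' @export
model_jacobian <- function(model, state) {
  n <- length(state)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * (1 + abs(state[j]))
    sp <- state; sp[j] <- sp[j] + h
    sm <- state; sm[j] <- sm[j] - h
    J[, j] <- (model$rhs(sp) - model$rhs(sm)) / (2 * h)
  }
  if (any(!is.finite(J))) stop("non-finite Jacobian entries")
  J
}
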