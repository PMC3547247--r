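## Trajectory phenotyping: fixed point, damped, and the taxonomy of
## sustained oscillations (symmetric, asymmetric, intrazonal, nested,
## chaotic), with period and zone-residence estimation.

.post_transient <- function(traj, transient_frac) {
  t <- traj$times
  keep <- t >= t[1] + transient_frac * (t[length(t)] - t[1])
  list(t = t[keep], x = traj$states[keep, "x"])
}

.peak_indices <- function(x) which(diff(sign(diff(x))) == -2) + 1L
.trough_indices <- function(x) which(diff(sign(diff(x))) == 2) + 1L

# local maxima with prominence (drop to the deeper neighbouring trough)
# above prom_tol; suppresses sampling jitter and SDE noise wiggles
.prominent_peaks <- function(x, prom_tol) {
  pk <- .peak_indices(x)
  tr <- .trough_indices(x)
  if (!length(pk)) return(integer(0))
  keep <- vapply(pk, function(i) {
    prev_tr <- tr[tr < i]
    next_tr <- tr[tr > i]
    lo_prev <- if (length(prev_tr)) x[max(prev_tr)] else min(x[seq_len(i)])
    lo_next <- if (length(next_tr)) x[min(next_tr)] else
      min(x[seq(i, length(x))])
    min(x[i] - lo_prev, x[i] - lo_next) > prom_tol
  }, logical(1))
  pk[keep]
}

#' Estimate the oscillation period of a trajectory
#'
#' Median inter-peak interval of the displacement series after transient
#' removal; the median absolute deviation of the intervals is attached as
#' attribute \code{"uncertainty"}.
#'
#' @param traj A \code{gc_trajectory}.
#' @param transient_frac Fraction of the record discarded as transient.
#' @return Period (model time units), with attribute \code{uncertainty}.
#' @export
estimate_period <- function(traj, transient_frac = 0.25) {
  s <- .post_transient(traj, transient_frac)
  pk <- .peak_indices(s$x)
  if (length(pk) < 5L)
    stop("fewer than 5 peaks after transient removal; cannot estimate period")
  iv <- diff(s$t[pk])
  structure(stats::median(iv), uncertainty = stats::mad(iv))
}

#' Fraction of time spent on each side of the inter-zone midline
#'
#' The dark-zone side is \code{x < -dead_band} and the light-zone side
#' \code{x > +dead_band}; time inside the dead band (in transit) counts to
#' neither, so the two fractions sum to at most 1.
#'
#' @param traj A \code{gc_trajectory}.
#' @param dead_band Half-width of the excluded transit band (micrometres).
#' @param transient_frac Fraction of the record discarded as transient.
#' @return Named numeric: \code{dz}, \code{lz}.
#' @export
residence_times <- function(traj, dead_band = 0, transient_frac = 0.25) {
  s <- .post_transient(traj, transient_frac)
  c(dz = mean(s$x < -dead_band), lz = mean(s$x > dead_band))
}

#' Largest Lyapunov exponent by two-trajectory renormalization
#'
#' Integrates a reference and a perturbed trajectory in short segments,
#' accumulating the log separation growth and renormalizing the companion
#' back to the initial separation along the current difference vector.
#' Positive estimates flag sensitive dependence (chaos candidates).
#'
#' @param model A \code{gc_model}.
#' @param state0 Initial state.
#' @param horizon Total time over which to average.
#' @param d0 Initial separation (default 1e-6).
#' @param segment Renormalization interval (default 5 time units).
#' @param transient Time to discard before averaging begins (default
#'   \code{horizon / 4}).
#' @param rtol,atol Integrator tolerances.
#' @return Estimated exponent (per model time unit).
#' @export
lyapunov_estimate <- function(model, state0, horizon, d0 = 1e-6,
                              segment = 5, transient = horizon / 4,
                              rtol = 1e-8, atol = 1e-10) {
  ref <- as.numeric(state0)
  prt <- ref + c(d0, 0, 0, 0)
  acc <- 0; t_acc <- 0; t <- 0
  while (t < transient + horizon) {
    tt <- c(0, segment)
    ref_tr <- integrate_ode(model, ref, tt, rtol, atol)
    prt_tr <- integrate_ode(model, prt, tt, rtol, atol)
    ref <- ref_tr$states[2, ]
    pst <- prt_tr$states[2, ]
    d <- sqrt(sum((pst - ref)^2))
    if (d == 0) d <- .Machine$double.eps
    if (t >= transient) {
      acc <- acc + log(d / d0)
      t_acc <- t_acc + segment
    }
    prt <- ref + (pst - ref) * (d0 / d)
    t <- t + segment
  }
  acc / t_acc
}

#' Classify a trajectory into the oscillation taxonomy
#'
#' Decision tree over the post-transient displacement record:
#' \enumerate{
#'   \item displacement range below \code{amp_tol} -> \code{fixed_point};
#'   \item consistently decaying peak envelope -> \code{damped};
#'   \item otherwise sustained: \code{chaotic} when inter-peak intervals are
#'     irregular (coefficient of variation above \code{cv_chaos}) and a
#'     positive Lyapunov estimate is supplied; \code{nested} when the peak
#'     heights fall into well-separated groups (large and small cycles);
#'     \code{intrazonal} when all extrema lie on one side of the midline;
#'     else \code{periodic_symmetric} when the cycle mean is near zero and
#'     the zone residence fractions agree to within \code{sym_tol},
#'     otherwise \code{periodic_asymmetric}.
#' }
#' The thresholds operationalize qualitative trajectory categories; they
#' are configuration values, not fitted quantities.
#'
#' @param traj A \code{gc_trajectory}.
#' @param dead_band Transit band for residence fractions (default: a
#'   quarter of the zone half-separation when \code{env} is given, else 0).
#' @param env Optional \code{\link{chemokine_env}} (sets the dead band).
#' @param lyapunov Optional largest-Lyapunov estimate for the generating
#'   model (see \code{\link{lyapunov_estimate}}); required to assign
#'   \code{chaotic}.
#' @param transient_frac Transient fraction to discard (default 0.25).
#' @param amp_tol Amplitude below which motion counts as at rest (um).
#' @param cv_chaos Inter-peak-interval CV above which peaks are irregular.
#' @param sym_tol Maximum residence-fraction difference for symmetry.
#' @param lyap_tol Positive-Lyapunov threshold (per time unit).
#' @return A list of class \code{gc_phenotype}: label, period (NA unless
#'   periodic), amplitude, residence fractions and the peak statistics used.
#' @export
classify_trajectory <- function(traj, dead_band = NULL, env = NULL,
                                lyapunov = NULL, transient_frac = 0.25,
                                amp_tol = 1, cv_chaos = 0.2, sym_tol = 0.1,
                                lyap_tol = 0.01) {
  stopifnot(inherits(traj, "gc_trajectory"))
  if (length(traj$times) < 50L) stop("trajectory too short to classify")
  if (is.null(dead_band)) dead_band <- if (!is.null(env)) env$k / 4 else 0
  s <- .post_transient(traj, transient_frac)
  amp <- diff(range(s$x)) / 2
  res <- residence_times(traj, dead_band, transient_frac)
  out <- list(label = NA_character_, period = NA_real_, amplitude = amp,
              residence = res, n_peaks = NA_integer_, peak_cv = NA_real_,
              lyapunov = lyapunov)
  if (diff(range(s$x)) < amp_tol) {
    out$label <- "fixed_point"
    return(structure(out, class = "gc_phenotype"))
  }
  ctr <- stats::median(s$x)
  pk <- .prominent_peaks(s$x, prom_tol = 0.05 * 2 * amp)
  tr <- .trough_indices(s$x)
  heights <- abs(s$x[pk] - ctr)
  out$n_peaks <- length(pk)
  if (length(pk) >= 5L) {
    # damped: envelope shrinks consistently and substantially
    first_q <- stats::median(heights[seq_len(max(2L, length(heights) %/% 4))])
    last_q <- stats::median(heights[seq(length(heights) -
                                          max(1L, length(heights) %/% 4) + 1L,
                                        length(heights))])
    rho <- suppressWarnings(stats::cor(seq_along(heights), heights,
                                       method = "spearman"))
    if (is.finite(rho) && rho < -0.6 && last_q < 0.5 * first_q) {
      out$label <- "damped"
      return(structure(out, class = "gc_phenotype"))
    }
    iv <- diff(s$t[pk])
    out$peak_cv <- stats::sd(iv) / mean(iv)
    out$period <- stats::median(iv)
  } else if (length(pk) >= 2L) {
    out$period <- stats::median(diff(s$t[pk]))
  }
  extrema <- s$x[c(pk, tr)]
  one_sided <- length(extrema) > 0 && (all(extrema > 0) || all(extrema < 0))
  # nested: sub-oscillations ride on the main cycle, so there are many more
  # prominent maxima than full cycles about the record centre, and the
  # maxima reach clearly different heights
  n_cycles <- max(1, sum(diff(sign(s$x - ctr)) != 0) / 2)
  nested <- length(pk) >= 6L &&
    length(pk) > 1.8 * n_cycles &&
    diff(range(heights)) > 0.2 * amp
  chaotic <- !is.na(out$peak_cv) && out$peak_cv > cv_chaos &&
    !is.null(lyapunov) && lyapunov > lyap_tol
  if (chaotic) out$label <- "chaotic"
  else if (nested) out$label <- "nested"
  else if (one_sided) out$label <- "intrazonal"
  else if (abs(mean(s$x)) < 0.1 * amp + 1e-9 &&
           abs(res["dz"] - res["lz"]) <= sym_tol)
    out$label <- "periodic_symmetric"
  else out$label <- "periodic_asymmetric"
  structure(out, class = "gc_phenotype")
}

#' @export
print.gc_phenotype <- function(x, ...) {
  cat(sprintf("<gc_phenotype> %s; amplitude %.1f um", x$label, x$amplitude))
  if (!is.na(x$period)) cat(sprintf("; period %.1f", x$period))
  cat(sprintf("; residence dz %.2f / lz %.2f\n",
              x$residence["dz"], x$residence["lz"]))
  invisible(x)
}
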