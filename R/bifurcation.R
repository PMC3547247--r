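## Equilibrium location, stability and one/two-parameter continuation.
##
## All model variants have equilibria with v = 0 and receptors on their
## closed-form nullclines, so locating every equilibrium at a given
## parameter value reduces to a scalar root scan of the force balance in x.
## Scanning the full root set at each parameter value (rather than following
## a single branch by natural-parameter continuation) keeps every branch in
## view across the folds, where the subcritical Hopf points of these models
## sit.

#' Locate an equilibrium by Newton iteration
#'
#' Polishes a full state-space root of the model right-hand side and
#' returns it with its eigen-decomposition.
#'
#' @param model A \code{gc_model}.
#' @param guess Initial state guess.
#' @param tol Convergence tolerance on the max-norm of the right-hand side.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class \code{gc_equilibrium}: list with \code{state},
#'   \code{eigenvalues}, \code{stable}, \code{residual}.
#' @export
find_equilibrium <- function(model, guess, tol = 1e-10, max_iter = 50L) {
  state <- as.numeric(guess)
  act <- model$active
  for (i in seq_len(max_iter)) {
    f <- model$rhs(state)[act]
    if (max(abs(f)) < tol) break
    J <- model_jacobian(model, state)[act, act, drop = FALSE]
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in Newton iteration")
    state[act] <- state[act] - step
  }
  res <- max(abs(model$rhs(state)[act]))
  if (res >= tol)
    stop(sprintf("Newton did not converge: residual %.3e after %d iterations",
                 res, max_iter))
  J <- model_jacobian(model, state)[act, act, drop = FALSE]
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(state = state, eigenvalues = ev,
                 stable = max(Re(ev)) < 0, residual = res),
            class = "gc_equilibrium")
}

#' @export
print.gc_equilibrium <- function(x, ...) {
  cat(sprintf("<gc_equilibrium> x = %.4f (%s), max Re(lambda) = %+.3e\n",
              x$state[1], if (x$stable) "stable" else "unstable",
              max(Re(x$eigenvalues))))
  invisible(x)
}

.max_re_complex <- function(ev, im_tol = 1e-8) {
  cp <- ev[abs(Im(ev)) > im_tol]
  if (!length(cp)) return(NA_real_)
  max(Re(cp))
}

#' All equilibria of a model at its current parameters
#'
#' Scans the scalar force balance (velocity drift at v = 0 with receptors on
#' their nullclines) for sign changes, refines each root, and classifies
#' stability from the Jacobian eigenvalues of the full system.
#'
#' @param model A \code{gc_model}.
#' @param xlim Scan interval; defaults to the zone span plus four widths.
#' @param n Scan resolution.
#' @return Data frame with one row per equilibrium: \code{x}, \code{r1},
#'   \code{r2}, \code{max_re} (largest eigenvalue real part),
#'   \code{max_re_complex} (largest real part among complex pairs, NA if
#'   all eigenvalues are real) and \code{stable}.
#' @export
equilibria <- function(model, xlim = NULL, n = 4001L) {
  stopifnot(inherits(model, "gc_model"))
  env <- model$env
  if (is.null(xlim)) {
    w <- max(env$f1$width, env$f2$width)
    xlim <- c(-env$k - 4 * w, env$k + 4 * w)
  }
  xs <- seq(xlim[1], xlim[2], length.out = n)
  fs <- model$force(xs)
  sc <- which(diff(sign(fs)) != 0)
  roots <- vapply(sc, function(i)
    stats::uniroot(model$force, c(xs[i], xs[i + 1]), tol = 1e-13)$root,
    numeric(1))
  roots <- .dedupe_roots(roots, diff(xlim))
  rows <- lapply(roots, function(x) {
    r <- model$nullcline(x)
    st <- c(x, 0, r)
    J <- model_jacobian(model, st)[model$active, model$active, drop = FALSE]
    ev <- eigen(J, only.values = TRUE)$values
    data.frame(x = x, r1 = r[1], r2 = r[2], max_re = max(Re(ev)),
               max_re_complex = .max_re_complex(ev),
               stable = max(Re(ev)) < 0)
  })
  if (!length(rows))
    return(data.frame(x = numeric(0), r1 = numeric(0), r2 = numeric(0),
                      max_re = numeric(0), max_re_complex = numeric(0),
                      stable = logical(0)))
  do.call(rbind, rows)
}

# bisect a boundary of the "a stable equilibrium exists" indicator
.bisect_indicator <- function(indicator, lo, hi, tol) {
  flo <- indicator(lo)
  for (i in 1:200) {
    if (hi - lo < tol) break
    mid <- (lo + hi) / 2
    if (indicator(mid) == flo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' One-parameter continuation with Hopf and fold detection
#'
#' Sweeps a scenario parameter (typically the zone half-separation k) over a
#' grid, locating all equilibria and their stability at each value, then
#' refines three kinds of transition by bisection to \code{param_tol}:
#' \itemize{
#'   \item boundaries of the oscillatory window, i.e. the parameter range in
#'     which no stable equilibrium exists (lower boundary labelled H1,
#'     upper H2 -- in these models the subcritical upper Hopf is numerically
#'     coincident with the fold that creates the re-stabilized branch);
#'   \item sign changes of the largest complex-pair real part along a
#'     branch matched by x-continuity (kind \code{"hopf"});
#'   \item changes in the number of equilibria (kind \code{"fold"}).
#' }
#'
#' @param factory Function taking one numeric parameter value and returning
#'   a \code{gc_model}.
#' @param range Length-2 numeric: parameter sweep interval.
#' @param step Grid step (default 0.25).
#' @param param_tol Bisection refinement tolerance (default 1e-3).
#' @param param_name Name used in the output tables (default "k").
#' @return List with \code{branch} (data frame of all equilibria over the
#'   grid), \code{points} (data frame of detected bifurcation points with
#'   columns kind, label, param, x) and \code{windows} (data frame of
#'   oscillatory windows with columns lo, hi).
#' @export
continuation <- function(factory, range, step = 0.25, param_tol = 1e-3,
                         param_name = "k") {
  ks <- seq(range[1], range[2], by = step)
  eqs <- lapply(ks, function(k) equilibria(factory(k)))
  branch <- do.call(rbind, Map(function(k, e) {
    if (nrow(e)) cbind(param = k, e) else NULL
  }, ks, eqs))
  names(branch)[1] <- param_name

  any_stable <- vapply(eqs, function(e) any(e$stable), logical(1))
  n_eq <- vapply(eqs, nrow, integer(1))

  has_stable <- function(k) any(equilibria(factory(k))$stable)
  windows <- NULL
  points <- list()
  runs <- rle(!any_stable)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in seq_along(runs$values)) {
    if (!runs$values[j]) next
    i0 <- starts[j]; i1 <- ends[j]
    lo <- if (i0 > 1L)
      .bisect_indicator(has_stable, ks[i0 - 1L], ks[i0], param_tol) else ks[i0]
    hi <- if (i1 < length(ks))
      .bisect_indicator(has_stable, ks[i1], ks[i1 + 1L], param_tol) else ks[i1]
    windows <- rbind(windows, data.frame(lo = lo, hi = hi))
    if (i0 > 1L)
      points[[length(points) + 1L]] <-
        data.frame(kind = "hopf", label = "H1", param = lo,
                   x = utils::tail(eqs[[i0]]$x, 1))
    if (i1 < length(ks))
      points[[length(points) + 1L]] <-
        data.frame(kind = "hopf", label = "H2", param = hi,
                   x = utils::tail(eqs[[i1]]$x, 1))
  }

  # branch-matched complex-pair crossings between consecutive grid values
  match_tol <- max(2, 10 * step)
  mrc_at <- function(k, x_ref) {
    e <- equilibria(factory(k))
    if (!nrow(e)) return(NA_real_)
    i <- which.min(abs(e$x - x_ref))
    if (abs(e$x[i] - x_ref) > match_tol) return(NA_real_)
    e$max_re_complex[i]
  }
  for (i in seq_len(length(ks) - 1L)) {
    e0 <- eqs[[i]]; e1 <- eqs[[i + 1L]]
    if (!nrow(e0) || !nrow(e1)) next
    for (r in seq_len(nrow(e0))) {
      jm <- which.min(abs(e1$x - e0$x[r]))
      if (abs(e1$x[jm] - e0$x[r]) > match_tol) next
      m0 <- e0$max_re_complex[r]; m1 <- e1$max_re_complex[jm]
      if (is.na(m0) || is.na(m1) || sign(m0) == sign(m1)) next
      x_ref <- e0$x[r]
      kh <- .bisect_indicator(function(k) {
        m <- mrc_at(k, x_ref)
        !is.na(m) && m > 0
      }, ks[i], ks[i + 1L], param_tol)
      points[[length(points) + 1L]] <-
        data.frame(kind = "hopf", label = "H", param = kh, x = x_ref)
    }
    if (nrow(e0) != nrow(e1)) {
      kf <- .bisect_indicator(function(k) nrow(equilibria(factory(k))),
                              ks[i], ks[i + 1L], param_tol)
      points[[length(points) + 1L]] <-
        data.frame(kind = "fold", label = "LP", param = kf,
                   x = mean(range(c(e0$x, e1$x))))
    }
  }

  pts <- if (length(points)) do.call(rbind, points) else
    data.frame(kind = character(0), label = character(0),
               param = numeric(0), x = numeric(0))
  pts <- pts[order(pts$param), , drop = FALSE]
  # number fold labels in parameter order
  if (any(pts$kind == "fold"))
    pts$label[pts$kind == "fold"] <-
      paste0("LP", seq_len(sum(pts$kind == "fold")))
  rownames(pts) <- NULL
  list(branch = branch, points = pts,
       windows = if (is.null(windows))
         data.frame(lo = numeric(0), hi = numeric(0)) else windows)
}

#' Oscillatory window in one parameter
#'
#' Convenience wrapper around \code{\link{continuation}} returning just the
#' parameter interval(s) in which no stable equilibrium exists (between the
#' supercritical H1 and subcritical H2 thresholds).
#'
#' @inheritParams continuation
#' @return Data frame with columns \code{lo}, \code{hi} (possibly 0 rows).
#' @export
oscillation_window <- function(factory, range, step = 0.25,
                               param_tol = 1e-3) {
  continuation(factory, range, step, param_tol)$windows
}

#' Two-parameter Hopf boundary
#'
#' Traces the boundary of the oscillatory region in a parameter plane by
#' running the one-parameter window detection in \code{p1} for each value of
#' \code{p2} on a grid.
#'
#' @param factory2 Function \code{(p1, p2) -> gc_model}.
#' @param p2_values Grid of second-parameter values.
#' @param p1_range Sweep interval for the first parameter.
#' @param step,param_tol Passed to \code{\link{continuation}}.
#' @return Data frame with one row per (p2, window): columns \code{p2},
#'   \code{p1_lo}, \code{p1_hi}. p2 values with no oscillatory window are
#'   absent (gaps in the boundary).
#' @export
trace_hopf_boundary <- function(factory2, p2_values, p1_range,
                                step = 0.25, param_tol = 1e-3) {
  out <- NULL
  for (p2 in p2_values) {
    w <- oscillation_window(function(p1) factory2(p1, p2), p1_range,
                            step, param_tol)
    if (nrow(w))
      out <- rbind(out, data.frame(p2 = p2, p1_lo = w$lo, p1_hi = w$hi))
  }
  if (is.null(out))
    data.frame(p2 = numeric(0), p1_lo = numeric(0), p1_hi = numeric(0))
  else out
}

#' Is a parameter point inside the oscillatory region?
#'
#' A point is oscillatory when the model at those parameters has no stable
#' equilibrium, so every trajectory settles onto a sustained oscillation.
#'
#' @param model A \code{gc_model}.
#' @return Logical.
#' @export
is_oscillatory <- function(model) {
  !any(equilibria(model)$stable)
}
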