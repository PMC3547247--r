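## Named scenario registry: the reference parameter sets used throughout
## the package's examples, tests and acceptance runs. Parameter keys are
## ASCII transliterations of the model symbols (pi1, kappa2, epsilon1, chi,
## zeta, gamma, sigma, c, w, k).

.toy_keys <- c("c", "w", "k", "pi1", "pi2", "delta1", "delta2", "gamma")
.full_keys <- c("c", "w", "k", "pi1", "pi2", "tau1", "tau2",
                "delta1", "delta2", "kappa1", "kappa2",
                "epsilon1", "epsilon2", "chi", "zeta", "gamma")
.opt_keys <- c("sigma")

.fig4_fixed <- list(c = 10, w = 25, pi2 = 0.1, tau1 = 0.06, tau2 = 0.06,
                    delta1 = 0.006, delta2 = 0.006, kappa1 = 1, kappa2 = 0.1,
                    epsilon1 = 0.3, epsilon2 = 0.3, chi = 28, zeta = 1,
                    gamma = 5)

.fig5_top <- list(c = 10, w = 25, tau1 = 0.06, tau2 = 0.06, delta1 = 0.006,
                  delta2 = 0.006, epsilon1 = 0.3, epsilon2 = 0.3, chi = 28,
                  zeta = 1, gamma = 5, k = 50)
.fig5_bottom <- list(c = 5, w = 22, delta1 = 0.001, delta2 = 0.001,
                     zeta = 1, gamma = 0.03, k = 45)

.scenario_registry <- local({
  reg <- list()
  add <- function(name, model, params, provenance) {
    reg[[name]] <<- list(name = name, model = model, parameters = params,
                         provenance = provenance)
  }
  add("fig2_default", "toy",
      list(c = 20, w = 15.7, k = 30, pi1 = 0.3, pi2 = 1,
           delta1 = 0.001, delta2 = 0.001, gamma = 1),
      "toy-model reference set for the one-parameter sweep in k")
  add("fig4_default", "full",
      c(.fig4_fixed, list(pi1 = 0.15, k = 50)),
      "full-model reference set for the one-parameter sweep in k")
  add("fig5_topleft", "full",
      c(.fig5_top, list(pi1 = 0.15, pi2 = 0.15, kappa1 = 0.5, kappa2 = 0.5)),
      "symmetric interzonal oscillation example")
  add("fig5_topcenter", "full",
      c(.fig5_top, list(pi1 = 0.23, pi2 = 0.15, kappa1 = 0.5, kappa2 = 0.5)),
      "asymmetric oscillation example")
  add("fig5_topright", "full",
      c(.fig5_top, list(pi1 = 0.15, pi2 = 0.15, kappa1 = 3.6, kappa2 = 0.5)),
      "single-zone oscillation example")
  add("fig5_bottomleft", "full",
      c(.fig5_bottom, list(pi1 = 0.02, pi2 = 0.004, tau1 = 0.005,
                           tau2 = 0.01, kappa1 = 10, kappa2 = 10,
                           epsilon1 = 3, epsilon2 = 0.2, chi = 26.67)),
      "nested oscillations in both zones example")
  add("fig5_bottomcenter", "full",
      c(.fig5_bottom, list(pi1 = 0.05, pi2 = 0.006, tau1 = 0.04,
                           tau2 = 0.015, kappa1 = 10, kappa2 = 10,
                           epsilon1 = 6, epsilon2 = 0.1, chi = 3.33)),
      "nested oscillations in one zone example")
  add("fig5_bottomright", "full",
      c(.fig5_bottom, list(pi1 = 0.05, pi2 = 0.0056, tau1 = 0.005,
                           tau2 = 0.018, kappa1 = 5.5, kappa2 = 10,
                           epsilon1 = 6, epsilon2 = 0.1, chi = 16.17)),
      "chaotic oscillation example")
  reg
})

# (k, pi1) sample points in the full-model parameter plane, with the
# behaviour each exhibits under the fig4 fixed parameters
.fig7_pair_table <- data.frame(
  color = c("cyan", "black", "green", "magenta", "blue", "red"),
  k = c(43, 44, 50, 44, 50, 50),
  pi1 = c(0.9, 0.75, 0.15, 0.9, 0.25, 0.05),
  behavior = c("oscillatory", "oscillatory", "oscillatory",
               "steady_state", "steady_state", "steady_state"),
  stringsAsFactors = FALSE)

#' Sample (k, pi1) parameter pairs of the full-model phase diagram
#'
#' Six reference points in the (zone half-separation, CXCR4 synthesis rate)
#' plane under the \code{fig4_default} fixed parameters: three inside the
#' oscillatory region and three outside, used for classification checks and
#' for the 1D-vs-3D comparison runs.
#'
#' @return Data frame with columns color, k, pi1, behavior.
#' @export
fig7_pairs <- function() .fig7_pair_table

#' Names of the built-in scenarios
#' @return Character vector.
#' @export
scenario_names <- function() names(.scenario_registry)

#' Load a scenario by name or from a configuration file
#'
#' A scenario bundles a model choice (\code{"toy"} or \code{"full"}) with a
#' complete, validated parameter set. Files may be JSON (always supported)
#' or YAML (if the \pkg{yaml} package is installed) with top-level keys
#' \code{model} and \code{parameters}. Validation reports all problems --
#' missing keys, unknown keys, non-numeric values -- in a single pass.
#'
#' @param name_or_path Registered scenario name, or path to a config file.
#' @return A list of class \code{gc_scenario}: name, model, parameters,
#'   provenance.
#' @examples
#' sc <- load_scenario("fig4_default")
#' sc$parameters$kappa1
#' @export
load_scenario <- function(name_or_path) {
  if (name_or_path %in% names(.scenario_registry)) {
    sc <- .scenario_registry[[name_or_path]]
  } else if (file.exists(name_or_path)) {
    raw <- if (grepl("\\.ya?ml$", name_or_path)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML scenarios requires the 'yaml' package")
      yaml::read_yaml(name_or_path)
    } else {
      jsonlite::fromJSON(name_or_path)
    }
    sc <- list(name = raw$name %||% basename(name_or_path),
               model = raw$model, parameters = as.list(raw$parameters),
               provenance = raw$provenance %||% name_or_path)
  } else {
    stop(sprintf("unknown scenario '%s' (registered: %s)", name_or_path,
                 paste(scenario_names(), collapse = ", ")))
  }
  .validate_scenario(sc)
  structure(sc, class = "gc_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_scenario <- function(sc) {
  problems <- character(0)
  if (is.null(sc$model) || !sc$model %in% c("toy", "full", "single_receptor"))
    problems <- c(problems,
                  "model must be one of: toy, full, single_receptor")
  req <- if (identical(sc$model, "toy")) .toy_keys else .full_keys
  extra_ok <- .opt_keys
  if (identical(sc$model, "single_receptor")) extra_ok <- c(extra_ok, "r2_fixed")
  keys <- names(sc$parameters)
  missing <- setdiff(req, keys)
  unknown <- setdiff(keys, c(req, extra_ok))
  if (length(missing))
    problems <- c(problems, paste("missing parameter keys:",
                                  paste(missing, collapse = ", ")))
  if (length(unknown))
    problems <- c(problems, paste("unknown parameter keys:",
                                  paste(unknown, collapse = ", ")))
  bad <- keys[!vapply(sc$parameters, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad))
    problems <- c(problems, paste("non-numeric parameter values:",
                                  paste(bad, collapse = ", ")))
  if (length(problems))
    stop(paste0("invalid scenario:\n  ", paste(problems, collapse = "\n  ")))
  invisible(sc)
}

#' @export
print.gc_scenario <- function(x, ...) {
  cat(sprintf("<gc_scenario '%s'> model: %s (%s)\n", x$name, x$model,
              x$provenance))
  p <- unlist(x$parameters)
  cat(paste(sprintf("  %s = %g", names(p), p), collapse = "\n"), "\n")
  invisible(x)
}

#' Write a scenario to a JSON configuration file
#'
#' @param sc A \code{gc_scenario}.
#' @param path Output file path.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "gc_scenario"))
  jsonlite::write_json(unclass(sc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build a model from a scenario
#'
#' @param sc A \code{gc_scenario} (or scenario name).
#' @param override Named list of parameter overrides (e.g.
#'   \code{list(k = 44, pi1 = 0.9)}).
#' @param sigma Optional noise intensity override.
#' @return A \code{gc_model}.
#' @examples
#' m <- scenario_model("fig4_default", override = list(k = 44, pi1 = 0.9))
#' @export
scenario_model <- function(sc, override = NULL, sigma = NULL) {
  if (is.character(sc)) sc <- load_scenario(sc)
  stopifnot(inherits(sc, "gc_scenario"))
  p <- sc$parameters
  if (!is.null(override)) {
    unknown <- setdiff(names(override), c(names(p), .opt_keys, "r2_fixed"))
    if (length(unknown))
      stop(paste("unknown override keys:", paste(unknown, collapse = ", ")))
    p[names(override)] <- override
  }
  if (!is.null(sigma)) p$sigma <- sigma
  env <- chemokine_env(c1 = p$c, w1 = p$w, k = p$k)
  if (identical(sc$model, "toy")) {
    return(toy_model(env, toy_params(p$pi1, p$pi2, p$delta1, p$delta2,
                                     p$gamma)))
  }
  rp1 <- receptor_params(p$pi1, p$tau1, p$kappa1, p$delta1)
  rp2 <- receptor_params(p$pi2, p$tau2, p$kappa2, p$delta2)
  cp <- chemotaxis_params(chi = p$chi, epsilon1 = p$epsilon1,
                          epsilon2 = p$epsilon2, gamma = p$gamma,
                          zeta = p$zeta %||% 1, sigma = p$sigma %||% 0)
  if (identical(sc$model, "single_receptor"))
    single_receptor_model(env, rp1, rp2, cp, r2_fixed = p$r2_fixed)
  else
    full_model(env, rp1, rp2, cp)
}
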