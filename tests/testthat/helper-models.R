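# Shared fixtures: small constructors used across the test files.

toy_fig2 <- function(k = 30) {
  scenario_model("fig2_default", override = list(k = k))
}

full_fig4 <- function(k = 50, pi1 = 0.15, ...) {
  scenario_model("fig4_default", override = c(list(k = k, pi1 = pi1),
                                              list(...)))
}

# a symmetric toy model (identical zones)
toy_symmetric <- function(k = 30, gamma = 1) {
  env <- chemokine_env(20, 15.7, k = k)
  toy_model(env, toy_params(0.5, 0.5, 0.001, 0.001, gamma))
}

# standard-normal-shaped fields at -/+1.5 for the reduced velocity model
reduced_env <- function() chemokine_env(1, 1, k = 1.5)

# single-receptor variant sharing the fig4 fixed parameters
single_receptor_fig4 <- function(k, r2_fixed, pi1 = NULL) {
  p <- load_scenario("fig4_default")$parameters
  if (!is.null(pi1)) p$pi1 <- pi1
  env <- chemokine_env(p$c, p$w, k = k)
  single_receptor_model(
    env,
    receptor_params(p$pi1, p$tau1, p$kappa1, p$delta1),
    receptor_params(p$pi2, p$tau2, p$kappa2, p$delta2),
    chemotaxis_params(p$chi, p$epsilon1, p$epsilon2, p$gamma, p$zeta),
    r2_fixed = r2_fixed)
}
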