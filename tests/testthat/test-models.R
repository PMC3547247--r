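test_that("toy right-hand side has the stated limiting behaviour", {
  env <- chemokine_env(20, 15.7, k = 400)  # zones far apart
  tp <- toy_params(0.3, 1, 0.001, 0.001, 1)
  m <- toy_model(env, tp)
  # no receptors, no velocity: only synthesis acts
  d <- m$rhs(c(10, 0, 0, 0))
  expect_equal(d[2], 0)
  expect_equal(d[3:4], c(0.3, 1))
  # at the CXCL12 peak with the other zone negligible: no net force
  d2 <- m$rhs(c(-400, 0, 2, 2))
  expect_lt(abs(d2[2]), 1e-12)
})

test_that("toy receptor steady state is the synthesis/loss balance", {
  expect_equal(toy_receptor_steady_state(0.3, 0.001, 0), 300)
  expect_equal(toy_receptor_steady_state(0.3, 0.001, 20), 0.3 / 20.001)
  fs <- seq(0, 30, by = 0.5)
  expect_true(all(diff(toy_receptor_steady_state(0.3, 0.001, fs)) < 0))
  # the dynamic equation relaxes to it: dr/dt = pi - r f - delta r at fixed x
  sol <- deSolve::ode(c(r = 5), c(0, 2e4),
                      function(t, y, p) list(0.3 - y * 20 - 0.001 * y),
                      NULL, rtol = 1e-10, atol = 1e-12)
  expect_lt(abs(sol[2, "r"] - 0.3 / 20.001), 1e-6)
})

test_that("reduced velocity model reproduces the receptor-ratio equilibria", {
  env <- reduced_env()
  e0 <- reduced_equilibria(0, env)
  expect_equal(nrow(e0[e0$stable, ]), 1L)
  expect_equal(e0$x[e0$stable], 1.5, tolerance = 1e-6)
  e1 <- reduced_equilibria(1, env)
  st <- e1[e1$stable, ]
  expect_equal(nrow(st), 2L)  # bistable
  expect_equal(st$x[1], -st$x[2], tolerance = 1e-8)  # symmetric pair
  e45 <- reduced_equilibria(4.5, env)
  st45 <- e45[e45$stable, ]
  expect_equal(nrow(st45), 1L)
  expect_equal(st45$x, -1.4924, tolerance = 1e-3)
})

test_that("mass-action trafficking respects conservation and the no-ligand limit", {
  mp <- mass_action_params(k_on = 100, k_off = 100, mu = 50, beta = 0.1,
                           delta = 0.05, pi = 1, tau = 0.05)
  # L = 0: B and I never grow, U relaxes to pi/tau
  sol <- deSolve::ode(c(U = 0, B = 0, I = 0), c(0, 500),
                      function(t, y, p) list(mass_action_rhs(y, 0, mp)),
                      NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(sol[2, c("B", "I")]), c(0, 0))
  expect_equal(unname(sol[2, "U"]), 1 / 0.05, tolerance = 1e-6)
  # total receptor flux balance along a trajectory with ligand
  sol2 <- deSolve::ode(c(U = 5, B = 1, I = 0.5), seq(0, 50, by = 5),
                       function(t, y, p) list(mass_action_rhs(y, 2, mp)),
                       NULL, rtol = 1e-12, atol = 1e-14)
  for (i in seq_len(nrow(sol2))) {
    y <- sol2[i, -1]
    d <- mass_action_rhs(y, 2, mp)
    expect_equal(sum(d), mp$pi - mp$tau * y[["U"]] - mp$delta * y[["I"]],
                 tolerance = 1e-9)
  }
})

test_that("quasi-steady-state reduction tracks total surface receptor", {
  mp <- mass_action_params(k_on = 100, k_off = 100, mu = 50, beta = 0,
                           delta = 0.05, pi = 1, tau = 0.05)
  rp <- reduce_mass_action(mp)
  expect_equal(rp$kappa, 100 / 150)
  L <- 2
  tt <- seq(0, 200, by = 1)
  solMA <- deSolve::ode(c(U = 1, B = 0, I = 0), tt,
                        function(t, y, p) list(mass_action_rhs(y, L, mp)),
                        NULL, rtol = 1e-10, atol = 1e-12)
  solR <- deSolve::ode(c(r = 1), tt,
                       function(t, y, p) list(receptor_rhs(y, L, rp)),
                       NULL, rtol = 1e-10, atol = 1e-12)
  surf <- solMA[, "U"] + solMA[, "B"]
  sel <- tt > 20
  expect_lt(max(abs(surf[sel] - solR[sel, "r"]) / solR[sel, "r"]), 0.05)
})

test_that("reduced receptor equation saturates in ligand", {
  rp <- receptor_params(pi = 0.15, tau = 0.06, kappa = 0.5, delta = 0.006)
  expect_equal(receptor_rhs(3, 0, rp), 0.15 - 0.006 * 3)
  # saturation limit: removal rate tends to delta + tau
  expect_equal(receptor_rhs(3, 1e9, rp), 0.15 - (0.06 + 0.006) * 3,
               tolerance = 1e-6)
  expect_equal(receptor_steady_state(10, rp),
               0.15 / (0.006 + 0.06 * 5 / 6), tolerance = 1e-12)
  expect_equal(receptor_steady_state(10, rp), 2.678571, tolerance = 1e-6)
  # long-time integration converges to the closed form
  sol <- deSolve::ode(c(r = 0.2), c(0, 5e3),
                      function(t, y, p) list(receptor_rhs(y, 10, rp)),
                      NULL, rtol = 1e-10, atol = 1e-12)
  expect_lt(abs(sol[2, "r"] - receptor_steady_state(10, rp)), 1e-6)
})

test_that("the full model preserves the odd symmetry of the environment", {
  env <- chemokine_env(10, 25, k = 50)
  rp <- receptor_params(0.15, 0.06, 0.5, 0.006)
  cp <- chemotaxis_params(chi = 28, epsilon1 = 0.3, epsilon2 = 0.3,
                          gamma = 5)
  m <- full_model(env, rp, rp, cp)
  # symmetric state on the symmetry axis: no net force, ever
  d <- m$rhs(c(0, 0, 2.7, 2.7))
  expect_equal(d[1], 0)
  expect_equal(d[2], 0)
  tr <- integrate_ode(m, c(0, 0, 1, 1), seq(0, 500, by = 5))
  expect_lt(max(abs(tr$states[, "x"])), 1e-6)
  expect_equal(tr$states[, "r1"], tr$states[, "r2"], tolerance = 1e-8)
})

test_that("receptor densities stay non-negative along random trajectories", {
  set.seed(23)
  for (rep in 1:8) {
    m <- full_fig4(k = runif(1, 40, 55), pi1 = runif(1, 0.05, 0.9))
    st0 <- c(runif(1, -30, 30), runif(1, -2, 2), runif(1, 0, 3),
             runif(1, 0, 3))
    tr <- integrate_ode(m, st0, seq(0, 800, by = 8))
    expect_true(all(tr$states[, c("r1", "r2")] >= -1e-10))
  }
})

test_that("the frozen-receptor variant shares the full model's equilibria", {
  m <- full_fig4(k = 44, pi1 = 0.9)
  eq <- equilibria(m)
  i <- which(eq$stable)[1]
  ms <- single_receptor_fig4(k = 44, r2_fixed = eq$r2[i], pi1 = 0.9)
  # r2 never moves
  d <- ms$rhs(c(5, 1, 2, eq$r2[i]))
  expect_equal(d[4], 0)
  eqs <- equilibria(ms)
  expect_true(any(abs(eqs$x - eq$x[i]) < 1e-6))
})

test_that("finite-difference Jacobian matches the block-triangular limit", {
  # far from both fields the toy Jacobian decouples:
  # receptors decay at -delta_i; (x, v) block has eigenvalues {0, -gamma}
  env <- chemokine_env(20, 15.7, k = 3000)
  tp <- toy_params(0.3, 1, 0.002, 0.003, 1.7)
  m <- toy_model(env, tp)
  J <- model_jacobian(m, c(0, 0, 5, 5))
  ev <- sort(Re(eigen(J, only.values = TRUE)$values))
  expect_equal(ev, sort(c(-0.002, -0.003, 0, -1.7)), tolerance = 1e-6)
  # symmetric full model: Jacobian at the symmetric equilibrium commutes
  # with the zone relabeling (x,v,r1,r2) -> (-x,-v,r2,r1)
  envf <- chemokine_env(10, 25, k = 50)
  rp <- receptor_params(0.15, 0.06, 0.5, 0.006)
  cp <- chemotaxis_params(28, 0.3, 0.3, gamma = 5)
  mf <- full_model(envf, rp, rp, cp)
  eq <- equilibria(mf)
  i <- which.min(abs(eq$x))
  st <- c(eq$x[i], 0, eq$r1[i], eq$r2[i])
  Jf <- model_jacobian(mf, st)
  P <- matrix(0, 4, 4)
  P[1, 1] <- -1; P[2, 2] <- -1; P[3, 4] <- 1; P[4, 3] <- 1
  expect_equal(P %*% Jf %*% P, Jf, tolerance = 1e-5)
})
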