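test_that("correlated increments hit the target covariance", {
  dt <- 0.01
  n <- noise_params(M1 = 0.5, M2 = 0.05, mu = 0.5)
  set.seed(11)
  W <- correlated_increments(1e5, dt, n)
  target <- 2 * dt * matrix(c(0.5, 0.5 * sqrt(0.025),
                              0.5 * sqrt(0.025), 0.05), 2)
  S <- crossprod(W) / nrow(W)
  # 4 standard errors of a sample (co)variance of 1e5 Gaussian pairs
  se <- 4 * sqrt((target[1, 1] * target[2, 2] + target[1, 2]^2) / 1e5)
  expect_lt(abs(S[1, 2] - target[1, 2]), se)
  expect_lt(abs(S[1, 1] - target[1, 1]), 4 * sqrt(2 / 1e5) * target[1, 1])
  expect_lt(abs(S[2, 2] - target[2, 2]), 4 * sqrt(2 / 1e5) * target[2, 2])
})

test_that("uncorrelated increments are independent; |mu| = 1 is rank one", {
  dt <- 0.01
  set.seed(12)
  W0 <- correlated_increments(1e5, dt, noise_params(M1 = 0.5, M2 = 0.05,
                                                    mu = 0))
  expect_lt(abs(cor(W0[, 1], W0[, 2])), 4 / sqrt(1e5))
  W1 <- correlated_increments(1e4, dt, noise_params(M1 = 0.5, M2 = 0.05,
                                                    mu = 1))
  expect_equal(cor(W1[, 1], W1[, 2]), 1, tolerance = 1e-12)
  expect_equal(W1[, 2], sqrt(0.05 / 0.5) * W1[, 1], tolerance = 1e-12)
  Wm <- correlated_increments(1e4, dt, noise_params(M1 = 0.5, M2 = 0.05,
                                                    mu = -1))
  expect_equal(cor(Wm[, 1], Wm[, 2]), -1, tolerance = 1e-12)
  expect_error(
    correlated_increments(10, dt, noise_params(M1 = 0, M2 = 0.05, mu = 1)),
    "M1 = 0")
})

test_that("noise-free steps hold the deterministic fixed points", {
  p <- ref_params()
  n0 <- noise_params(M1 = 0, M2 = 0, mu = 0)
  z <- cbind(dW1 = 0, dW2 = 0)
  # stable state v = 0.3 with quasistationary depot: drift stays O(dt^2)
  st <- list(x = 0, v = 0.3, e = quasistationary_depot(0.3, ref_params()))
  for (k in 1:100) st <- step_full(st, 0.01, p, n0, z)[c("x", "v", "e")]
  expect_equal(st$v, 0.3, tolerance = 1e-6)
  expect_equal(st$e, 20, tolerance = 1e-4)
  # unstable state v = 0 is exactly preserved (odd drift)
  st0 <- list(x = 0, v = 0, e = 200)
  st0 <- step_full(st0, 0.01, p, n0, z)
  expect_identical(st0$v, 0)
  # reduced variant: both properties
  sr <- list(x = 0, v = 0.3)
  for (k in 1:100) sr <- step_reduced(sr, 0.01, p, n0, z)[c("x", "v")]
  expect_equal(sr$v, 0.3, tolerance = 1e-8)
  expect_identical(step_reduced(list(x = 0, v = 0), 0.01, p, n0, z)$v, 0)
})

test_that("frozen-velocity depot relaxation matches the linear-ODE law", {
  p <- ref_params()
  v <- 0.5; dt <- 0.001; nsteps <- 1000L
  e <- 150
  # Heun on the depot equation alone, velocity held fixed
  for (k in seq_len(nsteps)) {
    k1 <- depot_rhs(e, v, p)
    k2 <- depot_rhs(max(e + k1 * dt, 0), v, p)
    e <- e + 0.5 * (k1 + k2) * dt
  }
  lam <- p$c + p$d2 * v^2
  eqs <- quasistationary_depot(v, p)
  expect_equal(e, eqs + (150 - eqs) * exp(-lam * nsteps * dt),
               tolerance = 1e-4)
})

test_that("ensembles are reproducible and independent of block splitting", {
  p <- ref_params()
  n <- noise_params(M1 = 0.5, M2 = 0.05, mu = 0.3)
  cfg <- quick_cfg(variant = "full")
  e1 <- run_ensemble(cfg, p, n)
  e2 <- run_ensemble(cfg, p, n)
  expect_identical(e1$v, e2$v)
  expect_identical(e1$e, e2$e)
  e3 <- run_ensemble(cfg, p, n, block_size = 7L)
  expect_identical(e1$v, e3$v)
  cfg2 <- quick_cfg(variant = "full", seed = 43L)
  e4 <- run_ensemble(cfg2, p, n)
  expect_true(all(e1$v[, -1] != e4$v[, -1]))
})

test_that("ensemble geometry and depot positivity invariants hold", {
  p <- ref_params()
  n <- noise_params(M1 = 0.5, M2 = 0.05, mu = -0.4)
  cfg <- quick_cfg(variant = "full", n_steps = 1000L, record_every = 5L)
  ens <- run_ensemble(cfg, p, n)
  expect_equal(dim(ens$v), c(20L, 201L))
  expect_equal(dim(ens$x), dim(ens$v))
  expect_equal(ens$times, seq(0, 10, by = 0.05))
  expect_true(all(ens$e >= 0))
  expect_true(all(is.finite(ens$v)))
  # initial conditions inside the configured bounds
  expect_true(all(abs(ens$v[, 1]) <= 1) && all(abs(ens$x[, 1]) <= 1))
  # clamping is rare at reference parameters
  expect_lt(ens$clamp_count / (20 * 1000), 1e-4)
})

test_that("equivalent and reduced variants share a stationary law", {
  # Stratonovich on both sides; ensembles started inside the right well so
  # the comparison probes the within-well law the two forms must share
  p <- ref_params()
  n <- noise_params(M1 = 0.5, M2 = 0.05, mu = 0.5)
  cfgr <- sim_config(n_traj = 60L, n_steps = 4000L, seed = 5,
                     variant = "reduced", convention = "stratonovich",
                     v_bounds = c(0.2, 0.4))
  cfge <- sim_config(n_traj = 60L, n_steps = 4000L, seed = 6,
                     variant = "equivalent", convention = "stratonovich",
                     v_bounds = c(0.2, 0.4))
  vr <- as.vector(run_ensemble(cfgr, p, n)$v[, -(1:800)])
  ve <- as.vector(run_ensemble(cfge, p, n)$v[, -(1:800)])
  # two-sample KS distance on heavily autocorrelated draws: distance only
  d <- suppressWarnings(stats::ks.test(vr, ve)$statistic)
  expect_lt(unname(d), 0.05)
  expect_lt(abs(mean(vr) - mean(ve)), 0.01)
})

test_that("at perfect correlation the equivalent dynamics cannot cross the
           zero-noise velocity from below", {
  p <- ref_params()
  n <- noise_params(M1 = 0.5, M2 = 0.05, mu = 1)
  vroot <- sqrt(0.05 / 0.5)  # G vanishes here
  cfg <- sim_config(n_traj = 40L, n_steps = 5000L, seed = 9,
                    variant = "equivalent", v_bounds = c(-1, 0.25))
  ens <- run_ensemble(cfg, p, n)
  expect_lt(max(ens$v), vroot + 0.02)
})

test_that("integrator convention selects the noise-induced drift", {
  # linear test system: freeze the drag nonlinearity by tiny dt and compare
  # one Stratonovich vs one Ito step built from the same increments
  p <- ref_params()
  n <- noise_params(M1 = 0.5, M2 = 0.05, mu = 0)
  z <- cbind(dW1 = 0.2, dW2 = 0)
  st <- list(x = 0, v = 0.5)
  dt <- 1e-9   # drift contribution negligible, isolates the noise terms
  ito <- step_reduced(st, dt, p, n, z, convention = "ito")
  strat <- step_reduced(st, dt, p, n, z, convention = "stratonovich")
  # Ito noise term: -v dW1; Stratonovich averages the coupling over the
  # predictor, adding -(1/2) dW1 * (predictor shift) = +(1/2) v dW1^2
  expect_equal(ito$v - st$v, -0.5 * 0.2, tolerance = 1e-6)
  expect_equal(strat$v - ito$v, 0.5 * 0.5 * 0.2^2, tolerance = 1e-4)
})

test_that("ensembles persist to CSV with a faithful JSON sidecar", {
  p <- ref_params()
  n <- noise_params(M1 = 0.1, M2 = 0.05, mu = 0.2)
  cfg <- quick_cfg(n_traj = 3L, n_steps = 100L, variant = "full")
  ens <- run_ensemble(cfg, p, n)
  stem <- file.path(withr::local_tempdir(), "ens")
  paths <- write_ensemble(ens, stem)
  expect_true(all(file.exists(paths)))
  df <- read.csv(paths[["csv"]])
  expect_equal(nrow(df), 3 * 101)
  expect_named(df, c("traj", "t", "x", "v", "e"))
  meta <- jsonlite::read_json(paths[["json"]])
  expect_equal(meta$noise$mu, 0.2)
  expect_equal(meta$config$variant, "full")
})
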