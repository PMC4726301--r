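test_that("diffusion function is the cross-correlated quadratic", {
  expect_equal(diffusion_G(0, noise_params(M1 = 1, M2 = 0.05, mu = 0)), 0.05)
  # perfect square at |mu| = 1: (sqrt(M1) v - sqrt(M2))^2
  n1 <- noise_params(M1 = 0.05, M2 = 0.05, mu = 1)
  expect_equal(diffusion_G(1, n1), 0, tolerance = 1e-15)
  expect_equal(diffusion_G(-1, n1), 4 * 0.05)
  # G(v; mu) = G(-v; -mu)
  v <- seq(-2, 2, length.out = 41)
  np <- noise_params(M1 = 0.5, M2 = 0.05, mu = 0.7)
  nm <- noise_params(M1 = 0.5, M2 = 0.05, mu = -0.7)
  expect_equal(diffusion_G(v, np), diffusion_G(-v, nm))
  # strict positivity for |mu| < 1 (negative discriminant)
  for (mu in c(-0.99, -0.5, 0, 0.5, 0.99)) {
    n <- noise_params(M1 = 2, M2 = 0.05, mu = mu)
    expect_true(all(diffusion_G(seq(-5, 5, by = 0.01), n) > 0))
  }
})

test_that("effective drift carries the Stratonovich noise-induced terms", {
  p <- ref_params()
  v <- seq(-1, 1, length.out = 41)
  # mu = 0: only the multiplicative intensity contributes, F - f = M1 v
  n0 <- noise_params(M1 = 0.5, M2 = 0.05, mu = 0)
  expect_equal(drift_F(v, p, n0) - deterministic_force(v, p), 0.5 * v)
  expect_equal(drift_F(0, p, n0), 0)
  # hand evaluation of the cross term at v = 0
  n <- noise_params(M1 = 0.5, M2 = 0.05, mu = 0.5)
  expect_equal(drift_F(0, p, n), -0.5 * sqrt(0.5 * 0.05))
})

test_that("effective potential: normalisation, parity and mirror law", {
  p <- ref_params()
  g <- seq(-1.2, 1.2, length.out = 401)
  n0 <- noise_params(M1 = 0.5, M2 = 0.05, mu = 0)
  U0 <- effective_potential(g, p, n0)
  expect_equal(U0[which(g == 0)], 0)
  expect_equal(U0, rev(U0), tolerance = 1e-8)   # even at mu = 0
  np <- noise_params(M1 = 0.5, M2 = 0.05, mu = 0.5)
  nm <- noise_params(M1 = 0.5, M2 = 0.05, mu = -0.5)
  expect_equal(effective_potential(g, p, np),
               rev(effective_potential(g, p, nm)), tolerance = 1e-8)
  # degenerate noise: grid containing the G-root is rejected
  n1 <- noise_params(M1 = 0.5, M2 = 0.05, mu = 1)
  expect_error(effective_potential(g, p, n1), "degenerate")
})

test_that("cross-correlation tilts the potential toward sign(mu)", {
  p <- ref_params()
  g <- seq(-1.2, 1.2, length.out = 801)
  U <- effective_potential(g, p, noise_params(M1 = 0.5, M2 = 0.05, mu = 0.5))
  expect_lt(min(U[g > 0]), min(U[g < 0]))  # right well deeper for mu > 0
  U2 <- effective_potential(g, p, noise_params(M1 = 0.5, M2 = 0.05,
                                               mu = -0.5))
  expect_lt(min(U2[g < 0]), min(U2[g > 0]))
})

test_that("stationary density is normalised, nonnegative and stationary", {
  p <- ref_params()
  n <- noise_params(M1 = 0.5, M2 = 0.05, mu = 0.5)
  sol <- stationary_distribution(p = p, n = n)
  expect_true(all(sol$Q_st >= 0))
  expect_equal(tz(sol$grid, sol$Q_st), 1, tolerance = 1e-9)
  # zero-flux identity d/dv [G Q] = F Q, via 4th-order central differences
  g <- sol$grid; h <- diff(g)[1]
  GQ <- diffusion_G(g, n) * sol$Q_st
  i <- 3:(length(g) - 2)
  dGQ <- (-GQ[i + 2] + 8 * GQ[i + 1] - 8 * GQ[i - 1] + GQ[i - 2]) / (12 * h)
  FQ <- drift_F(g, p, n) * sol$Q_st
  expect_lt(max(abs(dGQ - FQ[i])) / max(abs(FQ)), 1e-6)
})

test_that("no correlation means no net velocity; weak noise keeps the wells", {
  p <- ref_params()
  sol0 <- stationary_distribution(p = p,
                                  n = noise_params(M1 = 0.5, M2 = 0.05,
                                                   mu = 0))
  expect_equal(sol0$mean_v, 0, tolerance = 1e-10)
  # weak noise: density modes approach the deterministic minima +/- 0.3
  solw <- stationary_distribution(p = p,
                                  n = noise_params(M1 = 0.01, M2 = 0.05,
                                                   mu = 0))
  expect_equal(sort(abs(solw$mode_pair)), c(0.3, 0.3), tolerance = 0.03)
})

test_that("moments: normalisation, zero mean at mu = 0, antisymmetry in mu", {
  p <- ref_params()
  mk <- function(mu) stationary_distribution(
    p = p, n = noise_params(M1 = 0.5, M2 = 0.05, mu = mu))
  s0 <- mk(0); sp <- mk(0.6); sm <- mk(-0.6)
  expect_equal(stationary_moments(s0, 0), 1, tolerance = 1e-9)
  expect_equal(stationary_moments(sp, 0), 1, tolerance = 1e-9)
  expect_equal(stationary_moments(s0, 1), 0, tolerance = 1e-10)
  expect_equal(stationary_moments(sp, 1), -stationary_moments(sm, 1),
               tolerance = 1e-8)
  # second moment is positive and below the grid half-width squared
  expect_gt(stationary_moments(sp, 2), 0)
})

test_that("a grid too narrow for the density is widened automatically", {
  p <- ref_params()
  n <- noise_params(M1 = 2, M2 = 0.2, mu = 0)
  sol <- stationary_distribution(seq(-0.5, 0.5, length.out = 501), p, n)
  expect_gt(max(sol$grid), 0.5)   # widened beyond the requested span
  expect_equal(tz(sol$grid, sol$Q_st), 1, tolerance = 1e-9)
})

test_that("noise parameter validation enforces the correlation bound", {
  expect_error(noise_params(mu = 1.5), "\\[-1, 1\\]")
  expect_error(noise_params(M1 = -1), "M1")
  expect_equal(noise_params(M1 = 0.5, M2 = 0.05, mu = 0.5)$M12,
               0.5 * sqrt(0.025))
  expect_error(stationary_distribution(p = ref_params(),
                                       n = noise_params(M1 = 0, M2 = 0)),
               "no stationary density")
})
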