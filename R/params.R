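#' Physical parameters of the energy-depot model
#'
#' Bundles the four constants of the depot model: the Stokes drag
#' `gamma0`, the energy influx rate `q` into the internal depot, the
#' internal dissipation rate `c` of the depot, and the depot-to-kinetic
#' conversion rate coefficient `d2` (the conversion rate itself is
#' `d2 * v^2`). The defaults are the reference parameter set used
#' throughout the figure experiments.
#'
#' The model is in the *active* (bistable) regime when `d2 * q > gamma0 * c`,
#' i.e. when the energy pumped through the depot overcomes passive friction
#' at small speeds; see [fixed_points()].
#'
#' @param gamma0 Drag coefficient (1/time), > 0.
#' @param q Energy influx rate into the depot (energy/time), >= 0.
#' @param c Depot internal dissipation rate (1/time), > 0.
#' @param d2 Conversion rate coefficient (1/(velocity^2 time)), > 0.
#' @return An object of class `"abp_model"`: a named list with fields
#'   `gamma0`, `q`, `c`, `d2` and an `active_regime` flag.
#' @examples
#' p <- model_params()
#' p$active_regime  # TRUE: d2*q = 2 > gamma0*c = 0.2
#' @export
model_params <- function(gamma0 = 20.0, q = 2.0, c = 0.01, d2 = 1.0) {
  stopifnot(is.numeric(gamma0), length(gamma0) == 1L, is.finite(gamma0),
            is.numeric(q), length(q) == 1L, is.finite(q),
            is.numeric(c), length(c) == 1L, is.finite(c),
            is.numeric(d2), length(d2) == 1L, is.finite(d2))
  if (gamma0 <= 0) stop("'gamma0' must be > 0 (got ", gamma0, ")")
  if (q < 0) stop("'q' must be >= 0 (got ", q, ")")
  if (c <= 0) stop("'c' must be > 0 (got ", c, ")")
  if (d2 <= 0) stop("'d2' must be > 0 (got ", d2, ")")
  structure(
    list(gamma0 = gamma0, q = q, c = c, d2 = d2,
         active_regime = (d2 * q > gamma0 * c)),
    class = "abp_model"
  )
}

#' @export
print.abp_model <- function(x, ...) {
  cat("<abp_model> energy-depot parameters\n")
  cat(sprintf("  gamma0 = %g, q = %g, c = %g, d2 = %g\n",
              x$gamma0, x$q, x$c, x$d2))
  cat(sprintf("  regime: %s (d2*q %s gamma0*c)\n",
              if (x$active_regime) "active/bistable" else "passive",
              if (x$active_regime) ">" else "<="))
  invisible(x)
}

#' Intensities of the correlated noise pair
#'
#' The velocity equation is driven by two zero-mean Gaussian white noises:
#' a multiplicative one (coupling `h1(v) = -v`, random modulation of the
#' drag coefficient) with intensity `M1`, and an additive one (coupling
#' `h2(v) = 1`, internal agitation) with intensity `M2`. Their
#' instantaneous cross-correlation intensity is `mu`, so the cross
#' intensity is `M12 = mu * sqrt(M1 * M2)`; `mu = 0` means independent
#' noises, `|mu| = 1` perfect correlation (the pair is then rank one).
#'
#' @param M1 Multiplicative-noise intensity, >= 0.
#' @param M2 Additive-noise intensity, >= 0.
#' @param mu Cross-correlation intensity in \[-1, 1\].
#' @return An object of class `"abp_noise"` with fields `M1`, `M2`, `mu`
#'   and the derived cross intensity `M12`.
#' @examples
#' noise_params(M1 = 0.5, M2 = 0.05, mu = 0.5)
#' @export
noise_params <- function(M1 = 0.01, M2 = 0.05, mu = 0.0) {
  stopifnot(is.numeric(M1), length(M1) == 1L, is.finite(M1),
            is.numeric(M2), length(M2) == 1L, is.finite(M2),
            is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (M1 < 0) stop("'M1' must be >= 0 (got ", M1, ")")
  if (M2 < 0) stop("'M2' must be >= 0 (got ", M2, ")")
  if (abs(mu) > 1) stop("'mu' must lie in [-1, 1] (got ", mu, ")")
  structure(
    list(M1 = M1, M2 = M2, mu = mu, M12 = mu * sqrt(M1 * M2)),
    class = "abp_noise"
  )
}

#' @export
print.abp_noise <- function(x, ...) {
  cat(sprintf("<abp_noise> M1 = %g, M2 = %g, mu = %g (M12 = %g)\n",
              x$M1, x$M2, x$mu, x$M12))
  invisible(x)
}

#' Integrator and ensemble settings
#'
#' Settings for the stochastic Heun integration of an ensemble of
#' trajectories. The reference numerical protocol uses `dt = 0.01` and
#' 500 trajectories with initial velocity and position drawn uniformly
#' from \[-1, 1\]; the default here is a reduced desk scale
#' (100 trajectories, 2e4 steps) suitable for interactive work.
#'
#' @param dt Time step, > 0.
#' @param n_steps Number of integration steps per trajectory.
#' @param n_traj Ensemble size, >= 1.
#' @param burn_in_steps Steps discarded before stationary averaging;
#'   default 20% of `n_steps`.
#' @param v_bounds,x_bounds Uniform initial-condition bounds for velocity
#'   and position (length-2 numeric).
#' @param depot_init Depot initialisation rule: `"empty"` (default) starts
#'   the depot uncharged, `e(0) = 0`, so every trajectory passes through
#'   the charging transient in which the velocity first collapses under
#'   passive drag and the propulsive instability then switches on;
#'   `"quasistationary"` sets `e(0) = q/(c + d2 v(0)^2)`;
#'   `"reservoir"` sets `e(0) = q/c`.
#' @param convention Stochastic-calculus convention of the integrator:
#'   `"ito"` (default; the noise coefficient is evaluated at the
#'   pre-point, as in a plain second-order stochastic Runge-Kutta) or
#'   `"stratonovich"` (Heun: the noise coefficient is averaged over
#'   predictor and corrector, adding the noise-induced drift
#'   `M1 v - M12`). The analytic Fokker-Planck layer is Stratonovich;
#'   see the methods vignette for why the two conventions behave
#'   qualitatively differently here.
#' @param seed Master RNG seed (integer); per-trajectory substreams are
#'   derived deterministically from it, so results do not depend on the
#'   order in which trajectories are integrated.
#' @param variant Which dynamics to integrate: `"full"` (x, v, e),
#'   `"reduced"` (x, v with the depot adiabatically eliminated), or
#'   `"equivalent"` (x, v driven by a single effective noise).
#' @param record_every Record state every this many steps (thinning for
#'   long runs); observables account for the thinning.
#' @return An object of class `"abp_config"`.
#' @examples
#' sim_config(n_traj = 10, n_steps = 1000, seed = 7)
#' @export
sim_config <- function(dt = 0.01, n_steps = 20000L, n_traj = 100L,
                       burn_in_steps = NULL,
                       v_bounds = c(-1, 1), x_bounds = c(-1, 1),
                       depot_init = c("empty", "quasistationary",
                                      "reservoir"),
                       seed = 1L,
                       variant = c("full", "reduced", "equivalent"),
                       convention = c("ito", "stratonovich"),
                       record_every = 1L) {
  depot_init <- match.arg(depot_init)
  variant <- match.arg(variant)
  convention <- match.arg(convention)
  n_steps <- as.integer(n_steps)
  n_traj <- as.integer(n_traj)
  record_every <- as.integer(record_every)
  if (is.null(burn_in_steps)) burn_in_steps <- as.integer(round(0.2 * n_steps))
  burn_in_steps <- as.integer(burn_in_steps)
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0 (got ", dt, ")")
  if (n_traj < 1L) stop("'n_traj' must be >= 1 (got ", n_traj, ")")
  if (n_steps < 1L) stop("'n_steps' must be >= 1 (got ", n_steps, ")")
  if (burn_in_steps < 0L || burn_in_steps >= n_steps)
    stop("'burn_in_steps' must satisfy 0 <= burn_in_steps < n_steps (got ",
         burn_in_steps, " with n_steps = ", n_steps, ")")
  if (record_every < 1L || record_every > n_steps)
    stop("'record_every' must be in [1, n_steps]")
  stopifnot(length(v_bounds) == 2L, v_bounds[1] <= v_bounds[2],
            length(x_bounds) == 2L, x_bounds[1] <= x_bounds[2])
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  structure(
    list(dt = dt, n_steps = n_steps, n_traj = n_traj,
         burn_in_steps = burn_in_steps,
         v_bounds = as.numeric(v_bounds), x_bounds = as.numeric(x_bounds),
         depot_init = depot_init, seed = seed, variant = variant,
         convention = convention, record_every = record_every),
    class = "abp_config"
  )
}

#' @export
print.abp_config <- function(x, ...) {
  cat(sprintf(
    "<abp_config> variant = %s (%s), dt = %g, n_steps = %d, n_traj = %d\n",
    x$variant, x$convention, x$dt, x$n_steps, x$n_traj))
  cat(sprintf("  burn-in %d steps, record every %d, seed %d\n",
              x$burn_in_steps, x$record_every, x$seed))
  cat(sprintf("  v0 ~ U[%g, %g], x0 ~ U[%g, %g], depot init: %s\n",
              x$v_bounds[1], x$v_bounds[2], x$x_bounds[1], x$x_bounds[2],
              x$depot_init))
  invisible(x)
}

# Deterministic integer substream spawner. Two rounds of a Lehmer-style
# multiplicative step keep every product below 2^53, so the double
# arithmetic is exact; the result is in [1, 2^31 - 2].
spawn_seed <- function(master, k) {
  m <- 2147483647
  s <- master %% m
  s <- (s * 48271) %% m
  s <- (s + (k %% m)) %% m
  s <- (s * 48271) %% m
  as.integer(s %% (m - 1L) + 1)
}
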