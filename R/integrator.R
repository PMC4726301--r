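#' Correlated Wiener increments for the noise pair
#'
#' Draws `n_pairs` increments `(dW1, dW2)` of the two white noises over a
#' step `dt`. With the convention `<eta_i(t) eta_j(t')> = 2 M_ij delta(t-t')`
#' the target covariance is
#' `[[2 M1 dt, 2 M12 dt], [2 M12 dt, 2 M2 dt]]`, `M12 = mu sqrt(M1 M2)`,
#' realised through the lower-triangular square root of the correlation:
#' `dW1 = sqrt(2 M1 dt) z1`, `dW2 = sqrt(2 M2 dt) (mu z1 + sqrt(1-mu^2) z2)`.
#' At `|mu| = 1` the factor is rank one and `dW2` is fully determined by
#' `dW1` (`dW2 = sign(mu) sqrt(M2/M1) dW1`), which requires `M1 > 0`.
#'
#' Uses the current R RNG stream; seed with [set.seed()] (or let
#' [run_ensemble()] manage per-trajectory substreams).
#'
#' @param n_pairs Number of increment pairs.
#' @param dt Time step, > 0.
#' @param n A [noise_params()] object.
#' @return An `n_pairs x 2` matrix with columns `dW1`, `dW2`.
#' @export
correlated_increments <- function(n_pairs, dt, n) {
  stopifnot(inherits(n, "abp_noise"), dt > 0, n_pairs >= 1)
  if (abs(n$mu) == 1 && n$M1 == 0)
    stop("perfect correlation (|mu| = 1) is undefined when M1 = 0: ",
         "the multiplicative noise is null")
  z1 <- stats::rnorm(n_pairs)
  r <- 1 - n$mu^2
  z2 <- if (r > 0) stats::rnorm(n_pairs) else numeric(n_pairs)
  dW1 <- sqrt(2 * n$M1 * dt) * z1
  dW2 <- sqrt(2 * n$M2 * dt) * (n$mu * z1 + sqrt(max(r, 0)) * z2)
  cbind(dW1 = dW1, dW2 = dW2)
}

# ---- vectorised stochastic second-order Runge-Kutta kernels -------------
#
# Predictor and corrector reuse the SAME Wiener increments and the drift
# is averaged over both states (Heun on the drift). The treatment of the
# noise coefficient selects the stochastic calculus: evaluated at the
# pre-point only ("ito"), or averaged over predictor and corrector
# ("stratonovich", which adds the noise-induced drift M1 v - M12).

heun_full <- function(x, v, e, dt, p, n, dW1, dW2, strat) {
  av <- -p$gamma0 * v + p$d2 * e * v
  ae <- p$q - p$c * e - p$d2 * v^2 * e
  vP <- v + av * dt - v * dW1 + dW2
  eP <- pmax(e + ae * dt, 0)
  avP <- -p$gamma0 * vP + p$d2 * eP * vP
  aeP <- p$q - p$c * eP - p$d2 * vP^2 * eP
  noise <- if (strat) -0.5 * (v + vP) * dW1 + dW2 else -v * dW1 + dW2
  vN <- v + 0.5 * (av + avP) * dt + noise
  eN <- e + 0.5 * (ae + aeP) * dt
  clamped <- sum(eN < 0)
  list(x = x + 0.5 * (v + vP) * dt, v = vN, e = pmax(eN, 0),
       clamped = clamped)
}

heun_reduced <- function(x, v, dt, p, n, dW1, dW2, strat) {
  a <- deterministic_force(v, p)
  vP <- v + a * dt - v * dW1 + dW2
  aP <- deterministic_force(vP, p)
  noise <- if (strat) -0.5 * (v + vP) * dW1 + dW2 else -v * dW1 + dW2
  vN <- v + 0.5 * (a + aP) * dt + noise
  list(x = x + 0.5 * (v + vP) * dt, v = vN)
}

heun_equivalent <- function(x, v, dt, p, n, dW, strat) {
  # Single-noise form dv = a dt + sqrt(G(v)) dW whose Fokker-Planck
  # equation has drift F and diffusion G. Under Stratonovich the
  # (1/2) G' correction cancels the noise-induced part of F, so the
  # bare drag f(v) is integrated; under Ito the drift is F itself.
  a <- if (strat) deterministic_force(v, p) else drift_F(v, p, n)
  b <- sqrt(pmax(diffusion_G(v, n), 0))
  vP <- v + a * dt + b * dW
  aP <- if (strat) deterministic_force(vP, p) else drift_F(vP, p, n)
  noise <- if (strat) {
    0.5 * (b + sqrt(pmax(diffusion_G(vP, n), 0))) * dW
  } else b * dW
  vN <- v + 0.5 * (a + aP) * dt + noise
  list(x = x + 0.5 * (v + vP) * dt, v = vN)
}

check_finite <- function(v, step) {
  bad <- which(!is.finite(v))
  if (length(bad))
    stop("integration blew up at step ", step, " (trajectory ",
         bad[1], " of the current block): non-finite state")
}

#' Single stochastic Heun step of the full (x, v, e) system
#'
#' Advances the position-velocity-depot system one step: deterministic
#' drift `dv = (-gamma0 + d2 e) v`, noise terms `-v dW1 + dW2`, depot
#' `de/dt = q - c e - d2 v^2 e` (clamped at 0), `dx = v dt`. Vectorised
#' over trajectories.
#'
#' @param state List with numeric fields `x`, `v`, `e` (equal lengths).
#' @param dt Time step.
#' @param p,n [model_params()] / [noise_params()] objects.
#' @param increments Matrix with columns `dW1`, `dW2` (one row per
#'   trajectory), e.g. from [correlated_increments()].
#' @param convention `"ito"` or `"stratonovich"`; see [sim_config()].
#' @return Updated state list; `$clamped` counts depot clamps this step.
#' @export
step_full <- function(state, dt, p, n, increments,
                      convention = c("ito", "stratonovich")) {
  convention <- match.arg(convention)
  if (any(state$e < 0)) stop("depot energy must be nonnegative")
  s <- heun_full(state$x, state$v, state$e, dt, p, n,
                 as.numeric(increments[, 1L]), as.numeric(increments[, 2L]),
                 strat = convention == "stratonovich")
  check_finite(s$v, step = NA_integer_)
  s
}

#' Single stochastic Heun step of the reduced (x, v) system
#'
#' The depot is adiabatically eliminated: `dv = f(v) dt - v dW1 + dW2`,
#' `dx = v dt`, with `f(v) = -gamma(v) v`.
#'
#' @inheritParams step_full
#' @param state List with numeric fields `x`, `v`.
#' @export
step_reduced <- function(state, dt, p, n, increments,
                         convention = c("ito", "stratonovich")) {
  convention <- match.arg(convention)
  s <- heun_reduced(state$x, state$v, dt, p, n,
                    as.numeric(increments[, 1L]), as.numeric(increments[, 2L]),
                    strat = convention == "stratonovich")
  check_finite(s$v, step = NA_integer_)
  s
}

#' Single stochastic Heun step of the equivalent single-noise system
#'
#' The two correlated noises are replaced by one effective noise with
#' velocity-dependent amplitude `sqrt(G(v))`:
#' `dv = f(v) dt + sqrt(G(v)) o dW` (Stratonovich), whose Fokker-Planck
#' equation has drift `F(v)` and diffusion `G(v)`, identical to the
#' two-noise reduced dynamics.
#'
#' @inheritParams step_full
#' @param state List with numeric fields `x`, `v`.
#' @param increments Numeric vector of unit-intensity Wiener increments
#'   (variance `2 dt`), one per trajectory.
#' @export
step_equivalent <- function(state, dt, p, n, increments,
                            convention = c("ito", "stratonovich")) {
  convention <- match.arg(convention)
  s <- heun_equivalent(state$x, state$v, dt, p, n, as.numeric(increments),
                       strat = convention == "stratonovich")
  check_finite(s$v, step = NA_integer_)
  s
}

#' Integrate an ensemble of trajectories
#'
#' Runs `n_traj` independent trajectories of the chosen variant.
#' Each trajectory has its own RNG substream derived deterministically
#' from the master seed, so the ensemble is bit-reproducible and
#' independent of the order (or blocking) in which trajectories are
#' integrated. Initial velocity and position are uniform on the
#' configured bounds; the depot starts empty by default (see
#' [sim_config()] for the alternatives).
#'
#' @param cfg A [sim_config()] object.
#' @param p A [model_params()] object.
#' @param n A [noise_params()] object.
#' @param block_size Trajectories integrated per vectorised block (memory
#'   knob only; has no effect on results).
#' @param v_sampler Optional function `(n_draws) -> velocities` replacing
#'   the uniform initial-velocity law (used e.g. to start an ensemble in
#'   the analytic stationary distribution); it is called once per
#'   trajectory from that trajectory's RNG substream.
#' @return An `"abp_ensemble"`: `times` (length `n_rec`), matrices `x`,
#'   `v` (and `e` for the full variant) of shape `n_traj x n_rec`,
#'   `clamp_count` (full variant), and `meta` holding the three parameter
#'   objects.
#' @examples
#' ens <- run_ensemble(sim_config(n_traj = 5, n_steps = 500, seed = 2),
#'                     model_params(), noise_params(M1 = 0.5, mu = 0.5))
#' dim(ens$v)
#' @export
run_ensemble <- function(cfg, p, n, block_size = 100L, v_sampler = NULL) {
  stopifnot(inherits(cfg, "abp_config"), inherits(p, "abp_model"),
            inherits(n, "abp_noise"))
  if (abs(n$mu) == 1 && n$M1 == 0)
    stop("perfect correlation (|mu| = 1) is undefined when M1 = 0")
  nt <- cfg$n_traj; ns <- cfg$n_steps; dt <- cfg$dt
  re <- cfg$record_every
  rec_idx <- seq(0L, ns, by = re)          # recorded step numbers
  n_rec <- length(rec_idx)
  times <- rec_idx * dt
  X <- matrix(NA_real_, nt, n_rec)
  V <- matrix(NA_real_, nt, n_rec)
  full <- cfg$variant == "full"
  E <- if (full) matrix(NA_real_, nt, n_rec) else NULL
  clamp_count <- 0L

  blocks <- split(seq_len(nt), ceiling(seq_len(nt) / block_size))
  for (idx in blocks) {
    nb <- length(idx)
    v0 <- numeric(nb); x0 <- numeric(nb)
    Z1 <- matrix(NA_real_, nb, ns)
    Z2 <- if (cfg$variant != "equivalent") matrix(NA_real_, nb, ns) else NULL
    for (j in seq_len(nb)) {
      set.seed(spawn_seed(cfg$seed, idx[j]))
      v0[j] <- if (is.null(v_sampler))
        stats::runif(1, cfg$v_bounds[1], cfg$v_bounds[2]) else v_sampler(1L)
      x0[j] <- stats::runif(1, cfg$x_bounds[1], cfg$x_bounds[2])
      if (cfg$variant == "equivalent") {
        Z1[j, ] <- stats::rnorm(ns)
      } else {
        zz <- matrix(stats::rnorm(2L * ns), nrow = 2L)
        Z1[j, ] <- zz[1L, ]
        Z2[j, ] <- zz[2L, ]
      }
    }
    x <- x0; v <- v0
    if (full) {
      e <- switch(cfg$depot_init,
                  empty = numeric(nb),
                  quasistationary = quasistationary_depot(v0, p),
                  reservoir = rep(p$q / p$c, nb))
    }
    strat <- cfg$convention == "stratonovich"
    s1 <- sqrt(2 * n$M1 * dt)
    s2 <- sqrt(2 * n$M2 * dt)
    r <- sqrt(max(1 - n$mu^2, 0))
    rec_col <- 1L
    X[idx, 1L] <- x; V[idx, 1L] <- v
    if (full) E[idx, 1L] <- e
    for (k in seq_len(ns)) {
      if (cfg$variant == "equivalent") {
        dW <- sqrt(2 * dt) * Z1[, k]
        s <- heun_equivalent(x, v, dt, p, n, dW, strat)
        x <- s$x; v <- s$v
      } else {
        dW1 <- s1 * Z1[, k]
        dW2 <- s2 * (n$mu * Z1[, k] + r * Z2[, k])
        if (full) {
          s <- heun_full(x, v, e, dt, p, n, dW1, dW2, strat)
          x <- s$x; v <- s$v; e <- s$e
          clamp_count <- clamp_count + s$clamped
        } else {
          s <- heun_reduced(x, v, dt, p, n, dW1, dW2, strat)
          x <- s$x; v <- s$v
        }
      }
      if (k %% re == 0L) {
        check_finite(v, k)
        rec_col <- rec_col + 1L
        X[idx, rec_col] <- x
        V[idx, rec_col] <- v
        if (full) E[idx, rec_col] <- e
      }
    }
  }
  structure(
    list(times = times, x = X, v = V, e = E, clamp_count = clamp_count,
         meta = list(params = p, noise = n, config = cfg)),
    class = "abp_ensemble"
  )
}

#' @export
print.abp_ensemble <- function(x, ...) {
  cfg <- x$meta$config
  cat(sprintf(
    "<abp_ensemble> %s variant: %d trajectories x %d recorded states (dt = %g)\n",
    cfg$variant, nrow(x$v), ncol(x$v), cfg$dt))
  if (!is.null(x$e))
    cat(sprintf("  depot clamps: %d of %.3g updates\n", x$clamp_count,
                as.numeric(nrow(x$v)) * cfg$n_steps))
  invisible(x)
}

#' Assemble a trajectory ensemble from raw matrices
#'
#' Constructor for synthetic or externally produced ensembles, mainly
#' useful to exercise the observable estimators on processes with known
#' closed-form behaviour (free diffusion, pure drift).
#'
#' @param times Time grid (strictly increasing, uniform spacing).
#' @param x,v Matrices `n_traj x length(times)`.
#' @param e Optional depot matrix of the same shape.
#' @param p,n,cfg Optional provenance objects; defaults are filled in
#'   with `n_steps`/`dt` consistent with `times`.
#' @return An `"abp_ensemble"` object.
#' @export
trajectory_ensemble <- function(times, x, v, e = NULL,
                                p = model_params(), n = noise_params(),
                                cfg = NULL) {
  stopifnot(is.matrix(x), is.matrix(v), all(dim(x) == dim(v)),
            ncol(x) == length(times), length(times) >= 2L)
  dts <- diff(times)
  if (any(dts <= 0) || diff(range(dts)) > 1e-9 * dts[1])
    stop("'times' must be strictly increasing with uniform spacing")
  if (!is.null(e)) stopifnot(is.matrix(e), all(dim(e) == dim(v)),
                             all(e >= 0))
  if (is.null(cfg))
    cfg <- sim_config(dt = dts[1], n_steps = length(times) - 1L,
                      n_traj = nrow(v),
                      variant = if (is.null(e)) "reduced" else "full")
  structure(
    list(times = times, x = x, v = v, e = e, clamp_count = 0L,
         meta = list(params = p, noise = n, config = cfg)),
    class = "abp_ensemble"
  )
}

#' Persist an ensemble to CSV with a JSON provenance sidecar
#'
#' Writes one long-format CSV row per trajectory and recorded time
#' (columns `traj`, `t`, `x`, `v`, and `e` when present) plus a
#' `<stem>.json` sidecar holding the full parameter set, seed, variant
#' and package version.
#'
#' @param ens An `"abp_ensemble"`.
#' @param stem Output path stem; `<stem>.csv` and `<stem>.json` are
#'   written.
#' @param thin Keep every `thin`-th recorded state in the CSV.
#' @return Invisibly, the two file paths.
#' @export
write_ensemble <- function(ens, stem, thin = 1L) {
  stopifnot(inherits(ens, "abp_ensemble"))
  keep <- seq(1L, length(ens$times), by = as.integer(thin))
  nt <- nrow(ens$v)
  df <- data.frame(
    traj = rep(seq_len(nt), times = length(keep)),
    t = rep(ens$times[keep], each = nt),
    x = as.vector(ens$x[, keep]),
    v = as.vector(ens$v[, keep])
  )
  if (!is.null(ens$e)) df$e <- as.vector(ens$e[, keep])
  csv <- paste0(stem, ".csv"); json <- paste0(stem, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  meta <- ens$meta
  jsonlite::write_json(
    list(params = meta$params[c("gamma0", "q", "c", "d2")],
         noise = meta$noise[c("M1", "M2", "mu")],
         config = meta$config[c("dt", "n_steps", "n_traj", "burn_in_steps",
                                "seed", "variant", "convention",
                                "depot_init", "record_every")],
         clamp_count = ens$clamp_count,
         package_version = as.character(utils::packageVersion("depotABP"))),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}
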