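#' Stationary mean velocity of an ensemble
#'
#' Averages the velocity over the retained (post burn-in) recorded states
#' of every trajectory. The point estimate is the mean of the
#' per-trajectory time averages and the standard error comes from the
#' between-trajectory variance of those averages — trajectories are
#' independent replicates, whereas successive states within one
#' trajectory are strongly autocorrelated.
#'
#' @param ens An `"abp_ensemble"`.
#' @param burn_in Burn-in in *steps* (not recorded columns); defaults to
#'   the value stored in the ensemble's configuration.
#' @return List with `estimate`, `se`, `per_traj` (per-trajectory means,
#'   used e.g. for bootstrap resampling), `n_traj`, `retained_steps`.
#' @export
mean_velocity <- function(ens, burn_in = NULL) {
  stopifnot(inherits(ens, "abp_ensemble"))
  keep <- retained_columns(ens, burn_in)
  per <- rowMeans(ens$v[, keep, drop = FALSE])
  list(estimate = mean(per),
       se = stats::sd(per) / sqrt(length(per)),
       per_traj = per, n_traj = length(per),
       retained_steps = length(keep))
}

#' Ensemble mean position at a given time
#'
#' With a noise-induced drift the mean position grows approximately as
#' `mean_velocity * t`, which is the consistency check used in the test
#' suite.
#'
#' @param ens An `"abp_ensemble"`.
#' @param t_index Column index into the recorded time grid; defaults to
#'   the final time.
#' @return List with `estimate`, `se`, `t`, `per_traj`.
#' @export
mean_position <- function(ens, t_index = NULL) {
  stopifnot(inherits(ens, "abp_ensemble"))
  if (is.null(t_index)) t_index <- ncol(ens$x)
  if (t_index < 1L || t_index > ncol(ens$x)) stop("invalid 't_index'")
  xs <- ens$x[, t_index]
  list(estimate = mean(xs), se = stats::sd(xs) / sqrt(length(xs)),
       t = ens$times[t_index], per_traj = xs)
}

#' Stationary depot observables
#'
#' From a full-variant ensemble, the stationary mean depot energy
#' `<e>` and the mean depot-to-kinetic conversion rate `d2 <e v^2>`.
#' Both are reported: at stationarity they satisfy the energy balance
#' `q = c <e> + d2 <e v^2>` of the depot equation, and either is a
#' natural measure of the "velocity" of the internal energy depot.
#'
#' @inheritParams mean_velocity
#' @return List with `depot_mean_e`, `depot_mean_e_se`,
#'   `depot_conversion_rate`, `depot_conversion_rate_se`,
#'   `balance_residual` (`q - c<e> - d2<e v^2>`) and its `balance_se`.
#' @export
depot_observables <- function(ens, burn_in = NULL) {
  stopifnot(inherits(ens, "abp_ensemble"))
  if (is.null(ens$e))
    stop("depot observables need a full-variant ensemble (no 'e' recorded)")
  keep <- retained_columns(ens, burn_in)
  p <- ens$meta$params
  per_e <- rowMeans(ens$e[, keep, drop = FALSE])
  per_conv <- rowMeans(p$d2 * ens$e[, keep, drop = FALSE] *
                         ens$v[, keep, drop = FALSE]^2)
  nt <- length(per_e)
  per_bal <- p$q - p$c * per_e - per_conv
  list(depot_mean_e = mean(per_e),
       depot_mean_e_se = stats::sd(per_e) / sqrt(nt),
       depot_conversion_rate = mean(per_conv),
       depot_conversion_rate_se = stats::sd(per_conv) / sqrt(nt),
       balance_residual = mean(per_bal),
       balance_se = stats::sd(per_bal) / sqrt(nt))
}

#' Effective diffusion coefficient
#'
#' `D_eff` is half the asymptotic growth rate of the ensemble variance of
#' position *about the mean*: `Var[x(t)] ~ 2 D_eff t`. Using the variance
#' rather than the raw mean-squared displacement removes the coherent
#' drift, so `D_eff` measures only the diffusive spread around the mean
#' motion. The slope is estimated by least squares over a late-time
#' window (default: the final half of the recorded span).
#'
#' @param ens An `"abp_ensemble"`.
#' @param fit_window Integer vector of recorded-column indices to fit
#'   over; default `NULL` uses the final half.
#' @param n_blocks Number of trajectory blocks used for the
#'   replicate-based standard error (`se_block`); the regression SE
#'   (`se`) badly understates the uncertainty because the variance path
#'   is autocorrelated in time, so `se_block` is the error bar to use
#'   when comparing `D_eff` across parameter points.
#' @return List with `D_eff`, `se` (regression slope SE), `se_block`
#'   (between-trajectory-block SE; `NA` when fewer than `2 * n_blocks`
#'   trajectories), `negative` flag (point estimate below zero, possible
#'   at fit-noise level), and the fitted `slope`/`intercept`.
#' @export
effective_diffusion <- function(ens, fit_window = NULL, n_blocks = 8L) {
  stopifnot(inherits(ens, "abp_ensemble"))
  n_rec <- ncol(ens$x)
  if (is.null(fit_window))
    fit_window <- seq.int(max(1L, floor(n_rec / 2)), n_rec)
  if (length(fit_window) < 10L)
    stop("'fit_window' must contain at least 10 recorded times")
  t <- ens$times[fit_window]
  slope_of <- function(rows) {
    vx <- apply(ens$x[rows, fit_window, drop = FALSE], 2L, stats::var)
    stats::lm(vx ~ t)
  }
  fit <- slope_of(seq_len(nrow(ens$x)))
  co <- summary(fit)$coefficients
  D <- unname(co["t", "Estimate"]) / 2
  nt <- nrow(ens$x)
  se_block <- NA_real_
  if (nt >= 2L * n_blocks) {
    blocks <- split(seq_len(nt), cut(seq_len(nt), n_blocks, labels = FALSE))
    Db <- vapply(blocks, function(rows)
      unname(stats::coef(slope_of(rows))[2L]) / 2, numeric(1))
    se_block <- stats::sd(Db) / sqrt(length(Db))
  }
  list(D_eff = D, se = unname(co["t", "Std. Error"]) / 2,
       se_block = se_block,
       negative = D < 0,
       slope = unname(co["t", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]))
}

#' Zero crossing of the mean velocity across a parameter sweep
#'
#' Locates the sign change of `mean_v` as a function of the swept
#' parameter (typically the cross-correlation intensity `mu`) by linear
#' interpolation between the two bracketing sweep points. When
#' per-trajectory means are supplied, a bootstrap over trajectories
#' (resampling within each sweep point) gives a standard error for the
#' crossing location.
#'
#' @param values Swept parameter values (increasing).
#' @param mean_v Mean-velocity estimates at `values`.
#' @param per_traj Optional list (same length as `values`) of
#'   per-trajectory mean velocities, as returned by [mean_velocity()].
#' @param n_boot Bootstrap replicates (used only with `per_traj`).
#' @return List with `crossing`, `se` (`NA` without `per_traj`), and the
#'   bracketing indices.
#' @examples
#' sign_change(c(-0.5, 0, 0.5), c(-0.2, 0.0, 0.2))  # crossing at 0
#' @export
sign_change <- function(values, mean_v, per_traj = NULL, n_boot = 200L) {
  stopifnot(length(values) == length(mean_v), length(values) >= 2L,
            !is.unsorted(values))
  cross <- interp_crossing(values, mean_v)
  se <- NA_real_
  if (!is.null(per_traj)) {
    stopifnot(length(per_traj) == length(values))
    boots <- vapply(seq_len(n_boot), function(b) {
      mv <- vapply(per_traj, function(pt)
        mean(sample(pt, length(pt), replace = TRUE)), numeric(1))
      tryCatch(interp_crossing(values, mv)$crossing,
               error = function(e) NA_real_)
    }, numeric(1))
    se <- stats::sd(boots, na.rm = TRUE)
  }
  list(crossing = cross$crossing, se = se,
       bracket = c(cross$i, cross$i + 1L))
}

# linear-interpolated zero crossing; if several, the one closest to
# parameter value 0 (ties broken toward the first)
interp_crossing <- function(values, mean_v) {
  s <- sign(mean_v)
  idx <- which(s[-length(s)] * s[-1] < 0 | mean_v[-length(mean_v)] == 0)
  if (any(mean_v == 0)) {
    iz <- which(mean_v == 0)
    return(list(crossing = values[iz[which.min(abs(values[iz]))]],
                i = iz[which.min(abs(values[iz]))]))
  }
  if (length(idx) == 0L)
    stop("no sign change of mean_v in the swept range")
  xc <- vapply(idx, function(i) {
    values[i] - mean_v[i] * (values[i + 1] - values[i]) /
      (mean_v[i + 1] - mean_v[i])
  }, numeric(1))
  j <- which.min(abs(xc))
  list(crossing = xc[j], i = idx[j])
}

# recorded columns strictly after the burn-in step
retained_columns <- function(ens, burn_in = NULL) {
  cfg <- ens$meta$config
  if (is.null(burn_in)) burn_in <- cfg$burn_in_steps
  if (burn_in >= cfg$n_steps)
    stop("'burn_in' must be smaller than n_steps (", cfg$n_steps, ")")
  steps <- seq(0L, cfg$n_steps, by = cfg$record_every)
  keep <- which(steps > burn_in)
  if (length(keep) == 0L) stop("no recorded states after burn-in")
  keep
}
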