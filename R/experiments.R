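#' Load a validated parameter configuration from YAML
#'
#' Reads a flat YAML mapping and returns the three validated parameter
#' objects. Omitted keys fall back to the reference defaults of the
#' figure experiments (`gamma0 = 20`, `q = 2`, `d2 = 1`, `c = 0.01`,
#' `M2 = 0.05`, `dt = 0.01`, `n_traj = 500`, `n_steps = 1e5`). Unknown
#' keys and out-of-range values raise an error naming the offending key.
#'
#' Recognised keys: `gamma0`, `q`, `c`, `d2`; `M1`, `M2`, `mu`; `dt`,
#' `n_steps`, `n_traj`, `burn_in_steps`, `seed`, `variant`,
#' `record_every`, `depot_init`, `v_min`, `v_max`, `x_min`, `x_max`.
#'
#' @param path Path to a YAML file (or a file with an empty/absent
#'   mapping, which yields pure defaults).
#' @return List with elements `params` ([model_params()]),
#'   `noise` ([noise_params()]), `config` ([sim_config()]).
#' @seealso [dump_config()]
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  known <- c("gamma0", "q", "c", "d2", "M1", "M2", "mu",
             "dt", "n_steps", "n_traj", "burn_in_steps", "seed", "variant",
             "convention", "record_every", "depot_init",
             "v_min", "v_max", "x_min", "x_max")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; legal keys are: ", paste(known, collapse = ", "))
  gv <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  params <- model_params(gamma0 = gv("gamma0", 20.0), q = gv("q", 2.0),
                         c = gv("c", 0.01), d2 = gv("d2", 1.0))
  noise <- noise_params(M1 = gv("M1", 0.01), M2 = gv("M2", 0.05),
                        mu = gv("mu", 0.0))
  config <- sim_config(
    dt = gv("dt", 0.01), n_steps = gv("n_steps", 100000L),
    n_traj = gv("n_traj", 500L),
    burn_in_steps = raw[["burn_in_steps"]],
    v_bounds = c(gv("v_min", -1), gv("v_max", 1)),
    x_bounds = c(gv("x_min", -1), gv("x_max", 1)),
    depot_init = gv("depot_init", "empty"),
    seed = gv("seed", 1L), variant = gv("variant", "full"),
    convention = gv("convention", "ito"),
    record_every = gv("record_every", 1L))
  list(params = params, noise = noise, config = config)
}

#' Write a configuration back to YAML
#'
#' Inverse of [load_config()]: serialises the three parameter objects to
#' a flat YAML mapping, so `load_config(dump_config(cfg, f))` reproduces
#' `cfg` exactly.
#'
#' @param cfg List with `params`, `noise`, `config` as returned by
#'   [load_config()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
dump_config <- function(cfg, path) {
  p <- cfg$params; n <- cfg$noise; s <- cfg$config
  out <- list(gamma0 = p$gamma0, q = p$q, c = p$c, d2 = p$d2,
              M1 = n$M1, M2 = n$M2, mu = n$mu,
              dt = s$dt, n_steps = s$n_steps, n_traj = s$n_traj,
              burn_in_steps = s$burn_in_steps, seed = s$seed,
              variant = s$variant, convention = s$convention,
              record_every = s$record_every,
              depot_init = s$depot_init,
              v_min = s$v_bounds[1], v_max = s$v_bounds[2],
              x_min = s$x_bounds[1], x_max = s$x_bounds[2])
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Specify a one-parameter sweep experiment
#'
#' A sweep varies one noise parameter (`mu`, `M1` or `M2`) over an
#' explicit list of values, optionally crossed with a second "curve"
#' parameter (one curve per value, so an experiment can overlay several
#' curves). All other parameters are held fixed.
#'
#' @param parameter One of `"mu"`, `"M1"`, `"M2"`.
#' @param values Swept values (nonempty, within the legal range).
#' @param params A [model_params()] object.
#' @param noise A [noise_params()] object holding the non-swept
#'   intensities.
#' @param config A [sim_config()] object (its seed is the master seed of
#'   the whole sweep).
#' @param curve_parameter,curve_values Optional second parameter crossed
#'   with the sweep.
#' @param label Experiment tag carried into the output table.
#' @return An `"abp_sweep_spec"` object.
#' @export
sweep_spec <- function(parameter = c("mu", "M1", "M2"), values,
                       params = model_params(), noise = noise_params(),
                       config = sim_config(),
                       curve_parameter = NULL, curve_values = NULL,
                       label = "sweep") {
  parameter <- match.arg(parameter)
  stopifnot(length(values) >= 1L, is.numeric(values))
  check_noise_range <- function(key, vals) {
    if (key == "mu" && any(abs(vals) > 1))
      stop("swept 'mu' values must lie in [-1, 1]")
    if (key %in% c("M1", "M2") && any(vals < 0))
      stop("swept '", key, "' values must be >= 0")
  }
  check_noise_range(parameter, values)
  if (!is.null(curve_parameter)) {
    curve_parameter <- match.arg(curve_parameter, c("mu", "M1", "M2"))
    if (curve_parameter == parameter)
      stop("'curve_parameter' must differ from the swept parameter")
    stopifnot(length(curve_values) >= 1L)
    check_noise_range(curve_parameter, curve_values)
  }
  structure(
    list(parameter = parameter, values = as.numeric(values),
         params = params, noise = noise, config = config,
         curve_parameter = curve_parameter,
         curve_values = if (is.null(curve_values)) NULL
                        else as.numeric(curve_values),
         label = label),
    class = "abp_sweep_spec"
  )
}

#' Run a sweep experiment
#'
#' For each (curve value, swept value) combination: builds the noise
#' parameters, integrates an ensemble with a deterministic per-point seed
#' derived from the master seed, computes the observables, and emits one
#' results row. One progress line per point goes to `stderr`; timing is
#' deliberately kept out of the results table so that repeated runs with
#' the same seed produce byte-identical CSV output.
#'
#' @param spec An [sweep_spec()] object.
#' @param block_size Passed to [run_ensemble()].
#' @param quiet Suppress progress lines.
#' @return An `"abp_sweep"` object: `$table` (one row per point with all
#'   parameters, seed and observable estimates/SEs) and `$per_traj`
#'   (per-point vectors of per-trajectory mean velocities, for bootstrap
#'   use by [sign_change()]).
#' @export
run_sweep <- function(spec, block_size = 100L, quiet = FALSE) {
  stopifnot(inherits(spec, "abp_sweep_spec"))
  curves <- if (is.null(spec$curve_parameter)) NA_real_ else spec$curve_values
  rows <- list(); per_traj <- list(); k <- 0L
  for (cv in curves) {
    for (val in spec$values) {
      k <- k + 1L
      nse <- spec$noise
      args <- list(M1 = nse$M1, M2 = nse$M2, mu = nse$mu)
      if (!is.null(spec$curve_parameter)) args[[spec$curve_parameter]] <- cv
      args[[spec$parameter]] <- val
      nse <- do.call(noise_params, args)
      cfg <- spec$config
      cfg$seed <- spawn_seed(spec$config$seed, 100000 + k)
      t0 <- proc.time()[["elapsed"]]
      ens <- run_ensemble(cfg, spec$params, nse, block_size = block_size)
      mv <- mean_velocity(ens)
      mx <- mean_position(ens)
      De <- effective_diffusion(ens)
      dep <- if (!is.null(ens$e)) depot_observables(ens) else
        list(depot_mean_e = NA_real_, depot_mean_e_se = NA_real_,
             depot_conversion_rate = NA_real_,
             depot_conversion_rate_se = NA_real_,
             balance_residual = NA_real_, balance_se = NA_real_)
      if (!quiet)
        message(sprintf(
          "[%s] %s=%g%s mean_v=%.4f D_eff=%.4g clamps=%d (%.1fs)",
          spec$label, spec$parameter, val,
          if (is.na(cv)) "" else sprintf(" %s=%g", spec$curve_parameter, cv),
          mv$estimate, De$D_eff, ens$clamp_count,
          proc.time()[["elapsed"]] - t0))
      rows[[k]] <- data.frame(
        label = spec$label,
        gamma0 = spec$params$gamma0, q = spec$params$q,
        c = spec$params$c, d2 = spec$params$d2,
        M1 = nse$M1, M2 = nse$M2, mu = nse$mu,
        variant = cfg$variant, seed = cfg$seed,
        dt = cfg$dt, n_steps = cfg$n_steps, n_traj = cfg$n_traj,
        burn_in_steps = cfg$burn_in_steps,
        mean_v = mv$estimate, mean_v_se = mv$se,
        mean_x_final = mx$estimate, mean_x_final_se = mx$se,
        depot_mean_e = dep$depot_mean_e,
        depot_mean_e_se = dep$depot_mean_e_se,
        depot_conversion_rate = dep$depot_conversion_rate,
        depot_conversion_rate_se = dep$depot_conversion_rate_se,
        D_eff = De$D_eff, D_eff_se = De$se,
        D_eff_se_block = De$se_block,
        clamp_count = ens$clamp_count)
      per_traj[[k]] <- mv$per_traj
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, per_traj = per_traj, spec = spec),
            class = "abp_sweep")
}

#' @export
print.abp_sweep <- function(x, ...) {
  cat(sprintf("<abp_sweep> '%s': %d points sweeping %s\n",
              x$spec$label, nrow(x$table), x$spec$parameter))
  print(utils::head(x$table[, c(x$spec$parameter, "mean_v", "mean_v_se",
                                "D_eff")], 10L))
  invisible(x)
}

#' Write sweep results to CSV with a JSON provenance sidecar
#'
#' @param sweep An `"abp_sweep"` object.
#' @param stem Output path stem (`<stem>.csv`, `<stem>.json`).
#' @return Invisibly, the file paths.
#' @export
write_sweep <- function(sweep, stem) {
  stopifnot(inherits(sweep, "abp_sweep"))
  csv <- paste0(stem, ".csv"); json <- paste0(stem, ".json")
  utils::write.csv(sweep$table, csv, row.names = FALSE)
  sp <- sweep$spec
  jsonlite::write_json(
    list(label = sp$label, parameter = sp$parameter, values = sp$values,
         curve_parameter = sp$curve_parameter,
         curve_values = sp$curve_values,
         params = sp$params[c("gamma0", "q", "c", "d2")],
         noise = sp$noise[c("M1", "M2", "mu")],
         config = sp$config[c("dt", "n_steps", "n_traj", "burn_in_steps",
                              "seed", "variant", "convention", "depot_init",
                              "record_every")],
         package_version = as.character(utils::packageVersion("depotABP"))),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}

#' Tabulate the analytic Fokker-Planck layer
#'
#' Evaluates the effective potential and normalised stationary density on
#' a velocity grid for one or more noise parameter sets, returning a long
#' table of `(v, U_FP, Q_st)` — the analytic counterpart of the
#' effective-potential figures.
#'
#' @param params A [model_params()] object.
#' @param noise_list A [noise_params()] object or a list of them.
#' @param grid Velocity grid.
#' @return `data.frame` with columns `M1`, `M2`, `mu`, `v`, `U_FP`,
#'   `Q_st`.
#' @export
run_fpe <- function(params = model_params(), noise_list,
                    grid = seq(-1.2, 1.2, length.out = 2001L)) {
  if (inherits(noise_list, "abp_noise")) noise_list <- list(noise_list)
  out <- lapply(noise_list, function(nse) {
    sol <- stationary_distribution(grid, params, nse)
    data.frame(M1 = nse$M1, M2 = nse$M2, mu = nse$mu,
               v = sol$grid, U_FP = sol$U_FP, Q_st = sol$Q_st)
  })
  do.call(rbind, out)
}

#' Compare the reduced-SDE stationary law with the Fokker-Planck density
#'
#' Validation harness: integrates a reduced-variant ensemble under the
#' Stratonovich convention (the convention of the analytic layer), pools
#' the retained velocities, and measures the Kolmogorov-Smirnov distance
#' between their empirical CDF and the analytic stationary CDF, together
#' with the first-moment difference and its (between-trajectory) standard
#' error. Retained velocity samples are autocorrelated within a
#' trajectory, so the KS distance is reported as a plain distance, not a
#' test p-value.
#'
#' With `v_init = "stationary"` the initial velocities are drawn from the
#' analytic density by inverse-CDF sampling, so the comparison tests
#' whether the ensemble *stays* distributed as `Q_st` under the dynamics
#' (invariance). This is the meaningful desk-scale check here: the
#' effective-potential barriers at the reference parameters are so high
#' (mean first-passage times of order 1e6 time units) that an ensemble
#' started from a uniform law cannot relax across wells within any
#' feasible horizon, while shape errors in the drift or diffusion would
#' still show up as a drift away from `Q_st` within a well.
#'
#' @param params A [model_params()] object.
#' @param noise A [noise_params()] object; both intensities zero is
#'   rejected (no stationary density exists).
#' @param config A [sim_config()] object; variant is forced to
#'   `"reduced"` and convention to `"stratonovich"`.
#' @param grid Velocity grid for the analytic solution.
#' @param v_init `"stationary"` (default; invariance check) or
#'   `"uniform"` (relaxation from the configured uniform bounds).
#' @return List with `ks`, `mean_sde`, `mean_sde_se`, `mean_fpe`,
#'   `mean_diff`, and the underlying `solution`.
#' @export
compare_sde_fpe <- function(params = model_params(),
                            noise = noise_params(M1 = 0.5, M2 = 0.05,
                                                 mu = 0.5),
                            config = sim_config(variant = "reduced"),
                            grid = seq(-1.2, 1.2, length.out = 2001L),
                            v_init = c("stationary", "uniform")) {
  v_init <- match.arg(v_init)
  if (noise$M1 == 0 && noise$M2 == 0)
    stop("no stationary density: both noise intensities are zero")
  if (abs(noise$mu) >= 1)
    stop("comparison requires |mu| < 1 (non-degenerate diffusion)")
  config$variant <- "reduced"
  config$convention <- "stratonovich"
  sol0 <- stationary_distribution(grid, params, noise)
  sampler <- if (v_init == "stationary") {
    dxg <- diff(sol0$grid)
    cdf0 <- c(0, cumsum((sol0$Q_st[-1] + sol0$Q_st[-length(sol0$Q_st)]) / 2 *
                          dxg))
    cdf0 <- cdf0 / cdf0[length(cdf0)]
    keep0 <- !duplicated(cdf0)
    function(m) stats::approx(cdf0[keep0], sol0$grid[keep0],
                              xout = stats::runif(m), rule = 2)$y
  } else NULL
  ens <- run_ensemble(config, params, noise, v_sampler = sampler)
  keep <- retained_columns(ens)
  samp <- as.vector(ens$v[, keep])
  sol <- sol0
  # analytic CDF by cumulative trapezoid, interpolated at the samples
  dx <- diff(sol$grid)
  cdf <- c(0, cumsum((sol$Q_st[-1] + sol$Q_st[-length(sol$Q_st)]) / 2 * dx))
  cdf <- cdf / cdf[length(cdf)]
  Fs <- stats::approx(sol$grid, cdf, xout = sort(samp), yleft = 0,
                      yright = 1, ties = "ordered")$y
  m <- length(samp)
  ks <- max(abs(seq_len(m) / m - Fs), abs((seq_len(m) - 1) / m - Fs))
  mv <- mean_velocity(ens)
  list(ks = ks, mean_sde = mv$estimate, mean_sde_se = mv$se,
       mean_fpe = sol$mean_v, mean_diff = mv$estimate - sol$mean_v,
       solution = sol)
}

#' Preset experiment specifications for the figure sweeps
#'
#' Named presets for the model's standard figure experiments, with the
#' reference fixed parameters of each. Simulation presets
#' return `list(kind = "sweep", spec = <abp_sweep_spec>)`; analytic ones
#' return `list(kind = "fpe", params = ..., noise_list = ...)`.
#' `scale = "test"` uses a reduced ensemble (100 trajectories, 2e4
#' steps); `scale = "reference"` uses the reference protocol (500
#' trajectories, 1e5 steps), which is substantially slower.
#'
#' @param name One of `"fig1"`, `"fig2"`, `"fig3"`, `"fig4"`, `"fig5"`,
#'   `"fig6a"`, `"fig6b"`, `"fig7"`, `"fig8"`, `"fig9"`, `"fig10a"`,
#'   `"fig10b"`.
#' @param scale `"test"` or `"reference"`.
#' @param seed Master seed for the preset's configuration.
#' @return See Description.
#' @export
preset <- function(name, scale = c("test", "reference"), seed = 1L) {
  scale <- match.arg(scale)
  p <- model_params()           # gamma0 = 20, q = 2, c = 0.01, d2 = 1
  cfg <- function(variant) {
    if (scale == "reference")
      sim_config(dt = 0.01, n_steps = 100000L, n_traj = 500L, seed = seed,
                 variant = variant)
    else
      sim_config(dt = 0.01, n_steps = 20000L, n_traj = 100L, seed = seed,
                 variant = variant)
  }
  mu_grid <- c(-0.9, -0.6, -0.3, 0, 0.3, 0.6, 0.9)
  sweep_of <- function(parameter, values, curve_parameter, curve_values,
                       variant, noise, label)
    list(kind = "sweep",
         spec = sweep_spec(parameter, values, params = p, noise = noise,
                           config = cfg(variant),
                           curve_parameter = curve_parameter,
                           curve_values = curve_values, label = label))
  fpe_of <- function(noise_list)
    list(kind = "fpe", params = p, noise_list = noise_list)
  switch(
    name,
    fig1 = sweep_of("mu", mu_grid, "M1", c(0.01, 2.0), "full",
                    noise_params(M2 = 0.05), "fig1"),
    fig2 = sweep_of("mu", mu_grid, "M1", c(0.01, 2.0), "full",
                    noise_params(M2 = 0.05), "fig2"),
    fig3 = sweep_of("M1", c(0.01, 0.5, 1, 2, 3), "mu",
                    c(-0.9, -0.5, 0, 0.5, 0.9), "full",
                    noise_params(M2 = 0.05), "fig3"),
    fig4 = sweep_of("M2", c(0.05, 0.1, 0.15, 0.2), "mu",
                    c(-0.9, -0.5, 0, 0.5, 0.9), "full",
                    noise_params(M1 = 0.01), "fig4"),
    fig5 = fpe_of(lapply(c(-0.5, 0, 0.5), function(m)
      noise_params(M1 = 0.5, M2 = 0.05, mu = m))),
    fig6a = fpe_of(lapply(c(0.01, 2, 3), function(m1)
      noise_params(M1 = m1, M2 = 0.05, mu = 0.5))),
    fig6b = fpe_of(lapply(c(0.05, 0.1, 0.2), function(m2)
      noise_params(M1 = 2, M2 = m2, mu = 0.5))),
    fig7 = sweep_of("mu", mu_grid, "M1", c(0.01, 1, 2), "full",
                    noise_params(M2 = 0.05), "fig7"),
    fig8 = sweep_of("M1", c(0.01, 0.5, 1, 2, 3), "mu", c(0.1, 0.5, 0.9),
                    "full", noise_params(M2 = 0.05), "fig8"),
    fig9 = sweep_of("M2", c(0.05, 0.1, 0.15, 0.2), "mu", c(0.1, 0.5, 0.9),
                    "full", noise_params(M1 = 0.01), "fig9"),
    fig10a = sweep_of("mu", c(-1, -0.5, 0, 0.5, 1), "M1", c(0.5, 2, 3),
                      "full", noise_params(M2 = 0.05), "fig10a"),
    fig10b = sweep_of("mu", c(-1, -0.5, 0, 0.5, 1), "M2",
                      c(0.05, 0.1, 0.2), "full",
                      noise_params(M1 = 0.5), "fig10b"),
    stop("unknown preset '", name, "'")
  )
}
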