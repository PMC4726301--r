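# Reference parameter set used throughout the figure experiments
ref_params <- function() model_params(gamma0 = 20, q = 2, c = 0.01, d2 = 1)

# Small, fast simulation configuration for unit tests
quick_cfg <- function(..., n_traj = 20L, n_steps = 2000L, seed = 42L) {
  sim_config(n_traj = n_traj, n_steps = n_steps, seed = seed, ...)
}

# trapezoid rule, duplicated here so tests do not rely on package internals
tz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
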