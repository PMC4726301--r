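#' Rate of change of the internal energy depot
#'
#' The depot `e(t)` gains energy from the environment at a constant flux
#' `q`, loses it by internal dissipation at rate `c * e`, and converts it
#' to kinetic energy at rate `d2 * v^2 * e`:
#' `de/dt = q - c*e - d2*v^2*e`.
#'
#' @param e Depot energy (nonnegative). Vectorised over `e` and `v`.
#' @param v Velocity.
#' @param p An [model_params()] object.
#' @return `de/dt`, same length as the recycled inputs.
#' @examples
#' p <- model_params()
#' depot_rhs(0, 0.3, p)      # only the influx term survives: q = 2
#' depot_rhs(200, 0, p)      # quasistationary at v = 0: 0
#' @export
depot_rhs <- function(e, v, p) {
  stopifnot(inherits(p, "abp_model"))
  if (any(e < 0)) stop("depot energy 'e' must be nonnegative")
  p$q - p$c * e - p$d2 * v^2 * e
}

#' Quasistationary depot energy
#'
#' The depot relaxes on the fast timescale `1/(c + d2 v^2)`; setting
#' `de/dt = 0` gives the quasistationary value `e_qs(v) = q / (c + d2 v^2)`,
#' used for the adiabatic elimination of the depot. It is even in `v`,
#' strictly positive for `q > 0`, and decreasing in `|v|`.
#'
#' @inheritParams depot_rhs
#' @return Quasistationary depot energy, vectorised over `v`.
#' @examples
#' p <- model_params()
#' quasistationary_depot(0, p)    # q/c = 200
#' quasistationary_depot(0.3, p)  # 2/0.1 = 20
#' @export
quasistationary_depot <- function(v, p) {
  stopifnot(inherits(p, "abp_model"))
  p$q / (p$c + p$d2 * v^2)
}

#' Effective nonlinear drag coefficient
#'
#' After adiabatic elimination of the depot the velocity feels the drag
#' `gamma(v) = gamma0 - d2*q/(c + d2*v^2)`. In the active regime
#' (`d2*q > gamma0*c`) the drag is negative at small speeds — slow
#' particles are accelerated by the depot — while `gamma(v) -> gamma0`
#' as `|v| -> Inf`.
#'
#' @inheritParams depot_rhs
#' @return Drag coefficient at `v`, vectorised.
#' @examples
#' p <- model_params()
#' drag_coefficient(0, p)    # 20 - 200 = -180: negative drag, active pumping
#' drag_coefficient(10, p)   # ~ 19.98, back to passive friction
#' @export
drag_coefficient <- function(v, p) {
  stopifnot(inherits(p, "abp_model"))
  p$gamma0 - p$d2 * p$q / (p$c + p$d2 * v^2)
}

#' Deterministic drag force of the reduced dynamics
#'
#' `f(v) = -gamma(v) * v`, the drift of the reduced velocity equation.
#' Odd in `v`; its zeros are the fixed points of the noise-free flow.
#'
#' @inheritParams depot_rhs
#' @return Force at `v`, vectorised.
#' @export
deterministic_force <- function(v, p) {
  -drag_coefficient(v, p) * v
}

#' Deterministic velocity potential
#'
#' The potential `U(v)` with `-dU/dv = f(v)`:
#' `U(v) = gamma0 v^2/2 - (q/2) log(c + d2 v^2)`, shifted so `U(0) = 0`
#' (only potential differences are physical). Even in `v`; in the active
#' regime it is a symmetric double well with minima at the stable fixed
#' points and a maximum at `v = 0`.
#'
#' @inheritParams depot_rhs
#' @return Potential values, vectorised over `v`.
#' @export
deterministic_potential <- function(v, p) {
  stopifnot(inherits(p, "abp_model"))
  p$gamma0 * v^2 / 2 - (p$q / 2) * log(p$c + p$d2 * v^2) +
    (p$q / 2) * log(p$c)
}

#' Fixed points of the reduced deterministic dynamics
#'
#' The noise-free reduced flow `dv/dt = f(v)` always has the equilibrium
#' `v = 0`. In the active regime (`d2*q > gamma0*c`) that equilibrium is
#' unstable and two symmetric stable states appear at
#' `v = +/- sqrt(q/gamma0 - c/d2)`; otherwise `v = 0` is the only (stable)
#' equilibrium and `exists_bistable` is `FALSE` — a valid return, not an
#' error, so parameter sweeps may cross the bifurcation.
#'
#' @param p An [model_params()] object.
#' @return A list of class `"abp_fixed_points"` with `v_unstable` (always
#'   0), `v_minus`, `v_plus` (NA when not bistable), and `exists_bistable`.
#' @examples
#' fixed_points(model_params())  # +/- 0.3
#' @export
fixed_points <- function(p) {
  stopifnot(inherits(p, "abp_model"))
  if (p$active_regime) {
    vp <- sqrt(p$q / p$gamma0 - p$c / p$d2)
    out <- list(v_minus = -vp, v_unstable = 0.0, v_plus = vp,
                exists_bistable = TRUE)
  } else {
    out <- list(v_minus = NA_real_, v_unstable = 0.0, v_plus = NA_real_,
                exists_bistable = FALSE)
  }
  structure(out, class = "abp_fixed_points")
}

#' @export
print.abp_fixed_points <- function(x, ...) {
  if (x$exists_bistable) {
    cat(sprintf("<abp_fixed_points> stable %+.6g / %+.6g, unstable %g\n",
                x$v_minus, x$v_plus, x$v_unstable))
  } else {
    cat(sprintf("<abp_fixed_points> single stable state at %g\n",
                x$v_unstable))
  }
  invisible(x)
}
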