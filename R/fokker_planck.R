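#' Velocity-dependent diffusion function of the Fokker-Planck equation
#'
#' For the noise couplings `h1(v) = -v` (multiplicative) and `h2(v) = 1`
#' (additive) with cross intensity `M12 = mu sqrt(M1 M2)`, the diffusion
#' function of the reduced velocity dynamics is the quadratic
#' `G(v) = M1 v^2 - 2 M12 v + M2`. Its discriminant is
#' `4 M1 M2 (mu^2 - 1)`, so G is strictly positive whenever `|mu| < 1`
#' and both intensities are positive; at `|mu| = 1` it degenerates to the
#' perfect square `(sqrt(M1) v - sign(mu) sqrt(M2))^2` with a double root
#' at `v = sign(mu) sqrt(M2/M1)` where the effective noise vanishes.
#'
#' @param v Velocity (vectorised).
#' @param n A [noise_params()] object.
#' @return `G(v)`.
#' @export
diffusion_G <- function(v, n) {
  stopifnot(inherits(n, "abp_noise"))
  n$M1 * v^2 - 2 * n$M12 * v + n$M2
}

#' Effective drift of the Fokker-Planck equation
#'
#' Under the Stratonovich convention the state-dependent noise adds the
#' drift `(1/2) G'(v) = M1 v - M12` to the deterministic drag force, so
#' `F(v) = f(v) + M1 v - mu sqrt(M1 M2)`. At `mu = 0` only the
#' multiplicative intensity contributes (`F = f + M1 v`): uncorrelated
#' additive noise has no effect on the effective drag force, which is the
#' property that pins down the Stratonovich interpretation used
#' throughout this package.
#'
#' @param v Velocity (vectorised).
#' @param p A [model_params()] object.
#' @param n A [noise_params()] object.
#' @return `F(v)`.
#' @export
drift_F <- function(v, p, n) {
  stopifnot(inherits(n, "abp_noise"))
  deterministic_force(v, p) + n$M1 * v - n$M12
}

#' Effective velocity potential of the Fokker-Planck equation
#'
#' `U_FP(v) = log G(v) - integral_0^v F(u)/G(u) du`, shifted so that
#' `U_FP(0) = 0`; the stationary velocity density is proportional to
#' `exp(-U_FP)`. The integral is evaluated by adaptive quadrature
#' ([stats::integrate()]) accumulated between consecutive grid nodes.
#' Cross-correlation (`mu != 0`) tilts the potential: for `mu > 0` the
#' well at positive velocity deepens, which is the origin of the
#' noise-induced net drift.
#'
#' @param grid Velocity grid (finite, strictly increasing).
#' @param p A [model_params()] object.
#' @param n A [noise_params()] object.
#' @return Numeric vector of `U_FP` values on `grid`.
#' @seealso [stationary_distribution()]
#' @export
effective_potential <- function(grid, p, n) {
  stopifnot(inherits(n, "abp_noise"), is.numeric(grid), length(grid) >= 2L)
  if (any(!is.finite(grid)) || any(diff(grid) <= 0))
    stop("'grid' must be finite and strictly increasing")
  G <- diffusion_G(grid, n)
  root_inside <- abs(n$mu) == 1 && n$M1 > 0 &&
    {vr <- sign(n$mu) * sqrt(n$M2 / n$M1); vr >= grid[1] && vr <= grid[length(grid)]}
  if (any(G <= 0) || root_inside)
    stop("degenerate noise: G(v) vanishes on the grid (|mu| = 1 with the ",
         "grid crossing v = sign(mu)*sqrt(M2/M1)); the stationary density ",
         "is only defined piecewise on one side of the root")
  integrand <- function(u) drift_F(u, p, n) / diffusion_G(u, n)
  # cumulative \int_0^v F/G: panel integrals between nodes, anchored at 0
  m <- length(grid)
  panel <- numeric(m - 1L)
  for (i in seq_len(m - 1L)) {
    panel[i] <- stats::integrate(integrand, grid[i], grid[i + 1L],
                                 rel.tol = 1e-10, abs.tol = 1e-12,
                                 subdivisions = 200L)$value
  }
  cum <- c(0, cumsum(panel))          # integral from grid[1]
  # re-anchor at v = 0
  if (grid[1] > 0 || grid[m] < 0) {
    head <- stats::integrate(integrand, 0, grid[1], rel.tol = 1e-10,
                             abs.tol = 1e-12, subdivisions = 200L)$value
  } else {
    i0 <- which.min(abs(grid))
    head <- -cum[i0] + if (grid[i0] != 0) {
      stats::integrate(integrand, 0, grid[i0], rel.tol = 1e-10,
                       abs.tol = 1e-12, subdivisions = 200L)$value
    } else 0
  }
  I <- cum + head
  log(G) - I - log(diffusion_G(0, n))
}

#' Stationary velocity distribution of the reduced dynamics
#'
#' Builds the zero-flux stationary solution of the Fokker-Planck
#' equation, `Q_st(v) = exp(-U_FP(v)) / N`, normalised by trapezoidal
#' quadrature on the grid. The default grid spans \[-1.2, 1.2\] with 2001
#' points, a wide margin around the deterministic wells at the reference
#' parameters; if the density leaves more than `boundary_tol` of its mass
#' in the outermost cells the grid is widened automatically (up to
#' `max_widen` times) and an error is raised if that still fails.
#'
#' @param grid Velocity grid (uniform, symmetric about 0 recommended).
#' @param p A [model_params()] object.
#' @param n A [noise_params()] object.
#' @param boundary_tol Maximum tolerated probability mass in the two
#'   outermost grid cells.
#' @param max_widen Number of automatic 1.5x grid widenings to attempt.
#' @return An `"abp_stationary"` object: `grid`, `U_FP`, `Q_st`,
#'   `log_norm` (log of the normalisation constant of `exp(-U_FP)`),
#'   `mean_v` (first moment), and `mode_pair` (locations of the density
#'   maxima, highest first).
#' @examples
#' sol <- stationary_distribution(p = model_params(),
#'                                n = noise_params(M1 = 0.5, M2 = 0.05, mu = 0.5))
#' sol$mean_v  # positive: mu > 0 tilts the potential toward v > 0
#' @export
stationary_distribution <- function(grid = seq(-1.2, 1.2, length.out = 2001L),
                                    p, n, boundary_tol = 1e-8,
                                    max_widen = 4L) {
  stopifnot(inherits(p, "abp_model"), inherits(n, "abp_noise"))
  if (n$M1 == 0 && n$M2 == 0)
    stop("no stationary density: both noise intensities are zero")
  for (attempt in 0:max_widen) {
    U <- effective_potential(grid, p, n)
    Umin <- min(U)
    w <- exp(-(U - Umin))             # stabilised: max(w) = 1
    dx <- diff(grid)
    Z <- sum((w[-1] + w[-length(w)]) / 2 * dx)
    Q <- w / Z
    mass_edge <- (Q[1] * dx[1] + Q[length(Q)] * dx[length(dx)]) / 2
    if (mass_edge <= boundary_tol) {
      mv <- trapz(grid, grid * Q)
      structure(
        list(grid = grid, U_FP = U, Q_st = Q,
             log_norm = log(Z) - Umin,   # N with the U_FP(0)=0 convention
             mean_v = mv, mode_pair = density_modes(grid, Q),
             params = p, noise = n),
        class = "abp_stationary") -> out
      return(out)
    }
    # widen symmetrically, keep the node spacing comparable
    span <- 1.5 * max(abs(range(grid)))
    grid <- seq(-span, span, length.out = length(grid))
  }
  stop("stationary density does not fit the grid even after widening; ",
       "supply a wider 'grid' (mass at boundary > ", boundary_tol, ")")
}

#' @export
print.abp_stationary <- function(x, ...) {
  cat(sprintf(
    "<abp_stationary> %d-point grid on [%g, %g]\n",
    length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  mean velocity %.6g; modes at %s\n", x$mean_v,
              paste(sprintf("%.4g", x$mode_pair), collapse = ", ")))
  invisible(x)
}

#' Moments of a stationary velocity distribution
#'
#' Trapezoidal moment `integral v^k Q_st(v) dv` of a solution returned by
#' [stationary_distribution()]. The first moment is the analytic
#' counterpart of the simulated ensemble mean velocity.
#'
#' @param sol An `"abp_stationary"` object.
#' @param k Moment order (nonnegative integer).
#' @return The k-th moment.
#' @export
stationary_moments <- function(sol, k) {
  stopifnot(inherits(sol, "abp_stationary"), k >= 0, k == round(k))
  trapz(sol$grid, sol$grid^k * sol$Q_st)
}

# trapezoidal quadrature on a (possibly non-uniform) grid
trapz <- function(x, y) {
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

# locations of the local maxima of a sampled density, highest first
density_modes <- function(grid, Q) {
  m <- length(Q)
  interior <- which(Q[2:(m - 1L)] > Q[1:(m - 2L)] &
                    Q[2:(m - 1L)] >= Q[3:m]) + 1L
  if (length(interior) == 0L) return(grid[which.max(Q)])
  interior <- interior[order(Q[interior], decreasing = TRUE)]
  grid[utils::head(interior, 2L)]
}
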