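#' Spherical shell geometry (reference configuration)
#'
#' @param r0 reference inner radius (mm).
#' @param R0 reference outer radius (mm), `R0 > r0 > 0`.
#' @return object of class `sphere_geometry` with derived fields `h0 = R0 -
#'   r0` and `h0/r0`.
#' @examples
#' sph5 <- sphere_geometry(15, 15.5)   # thin-wall benchmark shell
#' @export
sphere_geometry <- function(r0, R0) {
  stopifnot(is.numeric(r0), is.numeric(R0), r0 > 0, R0 > r0)
  structure(list(r0 = r0, R0 = R0, h0 = R0 - r0, h_over_r = (R0 - r0) / r0),
            class = "sphere_geometry")
}

#' Benchmark shell geometries
#'
#' The three verification shells share the inner radius 15 mm and differ in
#' wall thickness: 0.5 mm (`Sph_5`, thin-wall limit), 2.5 mm (`Sph_25`) and
#' 15 mm (`Sph_150`, thickness-to-radius ratio 1 as found in patient LVs).
#'
#' @return named list of [sphere_geometry()] objects.
#' @export
benchmark_geometries <- function() {
  list(Sph_5   = sphere_geometry(15, 15.5),
       Sph_25  = sphere_geometry(15, 17.5),
       Sph_150 = sphere_geometry(15, 30.0))
}

# In-plane minus radial Cauchy stress difference Delta(xi) for the
# incompressible radial reduction. xi is the reference radial coordinate,
# rho^3 = xi^3 + (r_def^3 - r0^3) the deformed one; lambda = rho/xi the
# in-plane stretch, lambda_r = lambda^-2. Isotropic in-plane active tension
# S_a adds to both in-plane principal stresses.
.sphere_delta <- function(xi, geom, mat, r_def, S_a = 0) {
  if (!inherits(mat, "material_demiray"))
    stop("the radial reduction supports the isotropic Demiray material only")
  c3 <- r_def^3 - geom$r0^3
  rho3 <- xi^3 + c3
  lam2 <- rho3^(2 / 3) / xi^2             # lambda^2
  I1 <- 2 * lam2 + lam2^-2
  mat$a * exp(mat$b * (I1 - 3)) * (lam2 - lam2^-2) + S_a
}

#' Luminal pressure of an incompressible shell at a given deformed radius
#'
#' Solves the radial equilibrium of an incompressible hyperelastic spherical
#' shell in closed quadrature form: with the incompressibility map
#' `rho^3 = xi^3 + (r_def^3 - r0^3)` the equilibrium
#' `d sigma_rr / d rho = 2 (sigma_thetatheta - sigma_rr) / rho`
#' integrates to
#' `p = int_{r0}^{R0} 2 Delta(xi) xi^2 / rho^3 dxi`,
#' where `Delta` is the in-plane minus radial stress difference of the
#' material (plus any isotropic in-plane active tension `S_a`). The outer
#' surface is traction free; the returned `p` is the luminal pressure in kPa.
#'
#' @param geom a [sphere_geometry()].
#' @param mat a [material_demiray()]; the bulk penalty is not used (the
#'   reduction is exactly incompressible).
#' @param r_def deformed inner radius (mm). Passive shells (`S_a = 0`)
#'   require `r_def >= r0` (compression would demand negative luminal
#'   pressure); with active tension the shell may contract below the
#'   reference radius, as the LV does during ejection.
#' @param S_a isotropic in-plane active tension (kPa).
#' @param n_quad Gauss-Legendre nodes over the reference thickness.
#' @param allow_compression permit `r_def < r0` in the purely passive case,
#'   returning the (negative) suction pressure instead of raising the
#'   domain error.
#' @return luminal pressure p (kPa); 0 at `r_def = r0` when `S_a = 0`,
#'   strictly increasing in `r_def`, increasing in `S_a` at fixed radius.
#' @export
pressure_from_inner_radius <- function(geom, mat, r_def, S_a = 0,
                                       n_quad = 200,
                                       allow_compression = FALSE) {
  stopifnot(inherits(geom, "sphere_geometry"))
  if (S_a == 0 && !allow_compression && r_def < geom$r0 * (1 - 1e-12))
    stop("domain error: r_def < r0 requires negative pressure")
  if (r_def <= 0) stop("domain error: r_def must be positive")
  .sphere_pressure(geom, mat, r_def, S_a, n_quad)
}

.sphere_pressure <- function(geom, mat, r_def, S_a, n_quad) {
  gl <- .gauss_nodes(n_quad, geom$r0, geom$R0)
  xi <- gl$x
  rho3 <- xi^3 + (r_def^3 - geom$r0^3)
  sum(gl$w * 2 * .sphere_delta(xi, geom, mat, r_def, S_a) * xi^2 / rho3)
}

#' Full inflation state of a pressurized shell
#'
#' Constructs the complete radial stress profile for a given deformed inner
#' radius and active tension: `sigma_rr` by cumulative quadrature of the
#' equilibrium from the inner boundary (`sigma_rr(r) = -p`,
#' `sigma_rr(R) = 0`), and `sigma_thetatheta = sigma_phiphi = sigma_rr +
#' Delta`. The profile is sampled on `n_profile` reference-coordinate points;
#' cumulative integrals use 5-point Gauss panels per interval so the outer
#' boundary condition is met to near machine precision.
#'
#' @inheritParams pressure_from_inner_radius
#' @param n_profile number of profile sample points through the wall.
#' @return object of class `inflation_state`: fields `p`, `r`, `R` (deformed
#'   radii), `xi`, `rho` (reference/deformed sample radii), `sigma_rr`,
#'   `sigma_tt` (= azimuthal = meridional profile, kPa), `S_a`, `geom`, `mat`.
#' @export
sphere_state <- function(geom, mat, r_def, S_a = 0, n_profile = 801,
                         n_quad = 200) {
  p <- .sphere_pressure(geom, mat, r_def, S_a, n_quad)
  xi <- seq(geom$r0, geom$R0, length.out = n_profile)
  c3 <- r_def^3 - geom$r0^3
  rho <- (xi^3 + c3)^(1 / 3)
  integrand <- function(x) {
    2 * .sphere_delta(x, geom, mat, r_def, S_a) * x^2 / (x^3 + c3)
  }
  cum <- c(0, cumsum(.panel_gauss(integrand, xi)))
  sigma_rr <- -p + cum
  delta <- .sphere_delta(xi, geom, mat, r_def, S_a)
  structure(list(p = p, r = r_def, R = rho[n_profile],
                 xi = xi, rho = rho,
                 sigma_rr = sigma_rr, sigma_tt = sigma_rr + delta,
                 S_a = S_a, geom = geom, mat = mat),
            class = "inflation_state")
}

# 5-point Gauss-Legendre integral over each interval of grid x; returns one
# value per interval.
.panel_gauss <- function(f, x) {
  gl <- .gauss_nodes(5, -1, 1)
  a <- x[-length(x)]; b <- x[-1]
  mid <- (a + b) / 2; half <- (b - a) / 2
  acc <- 0
  for (k in seq_along(gl$x))
    acc <- acc + gl$w[k] * f(mid + half * gl$x[k])
  acc * half
}

#' Inflate a shell to a target pressure
#'
#' Root-finds the deformed inner radius such that
#' [pressure_from_inner_radius()] matches `p_target`, then builds the full
#' [sphere_state()]. The bracket is expanded geometrically until it contains
#' the root; convergence is to `|p - p_target| < 1e-8` kPa.
#'
#' @inheritParams sphere_state
#' @param p_target luminal pressure (kPa), non-negative.
#' @return an `inflation_state` (see [sphere_state()]).
#' @examples
#' st <- inflate(sphere_geometry(15, 17.5), material_demiray(10, 8), 4)
#' mean_stresses(st)
#' @export
inflate <- function(geom, mat, p_target, S_a = 0, n_profile = 801,
                    n_quad = 200) {
  stopifnot(p_target >= 0)
  if (p_target == 0 && S_a == 0)
    return(sphere_state(geom, mat, geom$r0, 0, n_profile, n_quad))
  f <- function(r) pressure_from_inner_radius(geom, mat, r, S_a, n_quad) -
    p_target
  lo <- if (S_a > 0) geom$r0 * 0.999 else geom$r0
  hi <- geom$r0 * 1.05
  # with active tension the equilibrium radius may lie below r0
  it <- 0
  while (S_a > 0 && f(lo) > 0) {
    lo <- lo * 0.9
    it <- it + 1
    if (it > 60) stop("solver error: failed to bracket the inflation radius")
  }
  it <- 0
  while (f(hi) < 0) {
    hi <- hi * 1.5
    it <- it + 1
    if (it > 60) stop("solver error: failed to bracket the inflation radius")
  }
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  st <- sphere_state(geom, mat, r, S_a, n_profile, n_quad)
  if (abs(st$p - p_target) > 1e-8)
    stop("solver error: pressure residual ", st$p - p_target, " kPa")
  st
}

#' Volume-averaged principal stresses of an inflation state
#'
#' Domain averages of the radial, azimuthal and meridional Cauchy stress over
#' the deformed shell. Under incompressibility the deformed volume element
#' `4 pi rho^2 drho` equals the reference one `4 pi xi^2 dxi`, so the average
#' is computed on the stored reference-coordinate profile by trapezoid
#' quadrature. Azimuthal and meridional averages are equal by symmetry.
#'
#' @param state an `inflation_state`.
#' @return named numeric vector `c(sigma_rr, sigma_tt, sigma_pp)` in kPa.
#' @export
mean_stresses <- function(state) {
  stopifnot(inherits(state, "inflation_state"))
  w <- state$xi^2
  vol <- pracma::trapz(state$xi, w)
  s_rr <- pracma::trapz(state$xi, state$sigma_rr * w) / vol
  s_tt <- pracma::trapz(state$xi, state$sigma_tt * w) / vol
  c(sigma_rr = s_rr, sigma_tt = s_tt, sigma_pp = s_tt)
}

#' Cavity volume of an inflation state (ml)
#' @param state an `inflation_state`.
#' @export
cavity_volume <- function(state) 4 * pi / 3 * state$r^3 / 1000

#' Wall volume of an inflation state (ml); constant under incompressibility.
#' @param state an `inflation_state`.
#' @export
wall_volume <- function(state) 4 * pi / 3 * (state$R^3 - state$r^3) / 1000

#' Passive pressure-volume curve (EDPVR)
#'
#' Quasi-static passive inflation along a pressure grid; returns the
#' end-diastolic pressure-volume relation of the shell.
#'
#' @inheritParams inflate
#' @param pressures non-negative, non-decreasing pressure grid (kPa).
#' @return data.frame with columns `p_kPa`, `V_ml`, `r_mm`, `R_mm`.
#' @export
edpvr <- function(geom, mat, pressures, n_quad = 200) {
  stopifnot(all(pressures >= 0), !is.unsorted(pressures))
  states <- inflation_ramp(geom, mat, pressures, n_profile = 3,
                           n_quad = n_quad)
  data.frame(p_kPa = pressures,
             V_ml = vapply(states, cavity_volume, 0),
             r_mm = vapply(states, function(s) s$r, 0),
             R_mm = vapply(states, function(s) s$R, 0))
}

#' Sequence of inflation states along a pressure ramp
#'
#' @inheritParams inflate
#' @param pressures non-decreasing pressure grid (kPa).
#' @return list of `inflation_state` objects.
#' @export
inflation_ramp <- function(geom, mat, pressures, n_profile = 801,
                           n_quad = 200) {
  lapply(pressures, function(p) inflate(geom, mat, p,
                                        n_profile = n_profile,
                                        n_quad = n_quad))
}

#' Internal mechanical work along an inflation ramp
#'
#' Integrates the stress power density `sigma : epsilon_dot` over the
#' deformed shell and over the ramp. For the radial reduction
#' `sigma : epsilon_dot = 2 (sigma_tt - sigma_rr) rho_dot / rho`; increments
#' use midpoint stresses and finite displacement increments between
#' consecutive states, so the result converges to the external work as the
#' ramp is refined (energy conservation).
#'
#' @param states list of `inflation_state` objects ordered by increasing
#'   pressure (all sharing the same geometry and profile grid).
#' @return internal work W_int in J (positive for inflation).
#' @export
internal_work <- function(states) {
  if (length(states) < 2) return(0)
  p <- vapply(states, function(s) s$p, 0)
  if (is.unsorted(p)) stop("ramp states must be ordered by increasing p")
  xi <- states[[1]]$xi
  W <- 0
  for (k in seq_len(length(states) - 1)) {
    s0 <- states[[k]]; s1 <- states[[k + 1]]
    rho_mid <- (s0$rho + s1$rho) / 2
    drho <- s1$rho - s0$rho
    delta_mid <- ((s0$sigma_tt - s0$sigma_rr) +
                    (s1$sigma_tt - s1$sigma_rr)) / 2
    dens <- 2 * delta_mid * drho / rho_mid        # sigma : d(eps), kPa
    W <- W + pracma::trapz(xi, dens * 4 * pi * xi^2)
  }
  W * .J_per_kPa_mm3
}

#' External (pressure-volume) work
#'
#' Trapezoid integral of `p dV_cav`; positive when work is done on the shell
#' during inflation.
#'
#' @param p pressure trace (kPa).
#' @param V cavity volume trace (ml), same length.
#' @return external work W_ext in J.
#' @export
external_work <- function(p, V) {
  if (length(p) != length(V)) stop("length mismatch between p and V traces")
  if (length(p) < 2) return(0)
  pracma::trapz(V, p) * .J_per_kPa_ml
}
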