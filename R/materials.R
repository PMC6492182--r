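#' Constitutive material definitions
#'
#' Two hyperelastic strain-energy functions commonly used for passive
#' myocardium are supported, both with a volumetric penalty
#' `kappa/2 * log(J)^2` enforcing near incompressibility:
#'
#' * the isotropic Demiray (exponential isotropic) model
#'   `Psi = kappa/2 log(J)^2 + a/(2b) (exp(b (tr(Cbar) - 3)) - 1)`,
#' * the transversely isotropic Guccione model
#'   `Psi = kappa/2 log(J)^2 + a/2 (exp(Q) - 1)` with `Q` a quadratic form in
#'   the modified isochoric Green-Lagrange strain expressed in the local
#'   fiber/sheet/sheet-normal frame.
#'
#' `Cbar = J^(-2/3) C` is the modified isochoric right Cauchy-Green tensor.
#'
#' @param a stress-like scale parameter (kPa).
#' @param b exponent (dimensionless), Demiray.
#' @param b_f,b_t,b_fs Guccione exponents (dimensionless).
#' @param kappa bulk modulus penalty (kPa); default 650 kPa.
#' @return an object of class `material_demiray` or `material_guccione`.
#' @examples
#' material_demiray(a = 10, b = 8)
#' @export
material_demiray <- function(a, b, kappa = 650) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(kappa),
            a > 0, b > 0, kappa > 0)
  structure(list(a = a, b = b, kappa = kappa),
            class = c("material_demiray", "material"))
}

#' @rdname material_demiray
#' @export
material_guccione <- function(a, b_f = 18.48, b_t = 3.58, b_fs = 1.627,
                              kappa = 650) {
  stopifnot(a > 0, b_f > 0, b_t > 0, b_fs > 0, kappa > 0)
  structure(list(a = a, b_f = b_f, b_t = b_t, b_fs = b_fs, kappa = kappa),
            class = c("material_guccione", "material"))
}

#' Local fiber coordinate frame
#'
#' A right-handed orthonormal triad of reference-configuration unit vectors:
#' fiber `f0`, sheet `s0` and sheet-normal `n0`. Guccione's energy is
#' anisotropic and requires such a frame; the frame is validated on
#' construction (pairwise orthogonality, unit norms, positive orientation).
#'
#' @param f0,s0,n0 numeric length-3 vectors; `n0` defaults to `f0 x s0`.
#' @param tol orthonormality tolerance.
#' @return object of class `fiber_frame`.
#' @export
fiber_frame <- function(f0 = c(1, 0, 0), s0 = c(0, 1, 0),
                        n0 = cross3(f0, s0), tol = 1e-10) {
  f0 <- as.numeric(f0); s0 <- as.numeric(s0); n0 <- as.numeric(n0)
  stopifnot(length(f0) == 3, length(s0) == 3, length(n0) == 3)
  M <- cbind(f0, s0, n0)
  if (max(abs(crossprod(M) - diag(3))) > tol)
    stop("fiber frame is not orthonormal")
  if (det(M) < 0)
    stop("fiber frame is not right-handed")
  structure(list(f0 = f0, s0 = s0, n0 = n0), class = "fiber_frame")
}

#' @rdname fiber_frame
#' @param a,b length-3 vectors.
#' @export
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Deformation state at a material point
#'
#' Bundles a deformation gradient `F` (3x3, det F > 0) with the local fiber
#' frame. All stress evaluations start from this object.
#'
#' @param F 3x3 deformation gradient.
#' @param frame a [fiber_frame()]; defaults to the Cartesian triad.
#' @return object of class `deformation_state`.
#' @export
deformation_state <- function(F, frame = fiber_frame()) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)))
  if (!is.finite(det(F)) || det(F) <= 0)
    stop("invalid deformation: det F must be positive")
  structure(list(F = F, frame = frame), class = "deformation_state")
}

#' Active stress transient parameters
#'
#' Parameters of the phenomenological active-tension transient: a product of
#' squared hyperbolic-tangent upstroke and downstroke factors scaled by the
#' peak isometric tension and a length-dependence factor `phi(lambda)`.
#' The functional form of the length dependence is injectable; the default is
#' the constant 1 (no length dependence).
#'
#' @param S_peak peak isometric tension (kPa).
#' @param tau_c upstroke time constant (ms).
#' @param tau_r downstroke time constant (ms).
#' @param t_dur transient duration (ms); tension is zero outside (0, t_dur).
#' @param phi function of fiber stretch lambda returning a scalar factor.
#' @return object of class `active_params`.
#' @export
active_params <- function(S_peak, tau_c = 80, tau_r = 30, t_dur = 300,
                          phi = function(lambda) 1) {
  stopifnot(S_peak >= 0, tau_c > 0, tau_r > 0, t_dur > 0, is.function(phi))
  structure(list(S_peak = S_peak, tau_c = tau_c, tau_r = tau_r,
                 t_dur = t_dur, phi = phi), class = "active_params")
}
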