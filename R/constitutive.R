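#' Strain-energy density
#'
#' Evaluates the hyperelastic strain-energy density (kPa) of a
#' [material_demiray()] or [material_guccione()] material at a
#' [deformation_state()]. The energy is zero at the undeformed reference
#' (`C = I`) and positive otherwise.
#'
#' @param def a [deformation_state()].
#' @param mat a material object.
#' @return scalar energy density in kPa.
#' @export
strain_energy <- function(def, mat) UseMethod("strain_energy", mat)

#' @export
strain_energy.material_demiray <- function(def, mat) {
  F <- def$F
  J <- det(F)
  if (J <= 0) stop("invalid deformation: det F <= 0")
  C <- crossprod(F)
  I1bar <- J^(-2 / 3) * sum(diag(C))
  mat$kappa / 2 * log(J)^2 +
    mat$a / (2 * mat$b) * (exp(mat$b * (I1bar - 3)) - 1)
}

#' @export
strain_energy.material_guccione <- function(def, mat) {
  F <- def$F
  J <- det(F)
  if (J <= 0) stop("invalid deformation: det F <= 0")
  C <- crossprod(F)
  Ebar <- 0.5 * (J^(-2 / 3) * C - diag(3))
  Q <- .guccione_Q(Ebar, def$frame, mat)
  mat$kappa / 2 * log(J)^2 + mat$a / 2 * (exp(Q) - 1)
}

# quadratic exponent of the Guccione energy in the local frame
.guccione_Q <- function(Ebar, frame, mat) {
  f <- frame$f0; s <- frame$s0; n <- frame$n0
  Eff <- drop(f %*% Ebar %*% f)
  Ess <- drop(s %*% Ebar %*% s)
  Enn <- drop(n %*% Ebar %*% n)
  Esn <- drop(s %*% Ebar %*% n)
  Efs <- drop(f %*% Ebar %*% s)
  Efn <- drop(f %*% Ebar %*% n)
  mat$b_f * Eff^2 +
    mat$b_t * (Ess^2 + Enn^2 + 2 * Esn^2) +
    2 * mat$b_fs * (Efs^2 + Efn^2)
}

#' Passive Cauchy stress
#'
#' Analytic evaluation of `sigma_pas = J^-1 F (2 dPsi/dC) F^T` for the
#' supported materials. The implementation is closed form per material; the
#' test suite checks it against central finite differences of
#' [strain_energy()] on random deformations.
#'
#' @inheritParams strain_energy
#' @return a [cauchy_stress()] in the Cartesian basis (kPa).
#' @export
passive_stress <- function(def, mat) UseMethod("passive_stress", mat)

#' @export
passive_stress.material_demiray <- function(def, mat) {
  F <- def$F
  J <- det(F)
  if (J <= 0) stop("invalid deformation: det F <= 0")
  B <- tcrossprod(F)                      # F F^T
  I1 <- sum(diag(B))
  I1bar <- J^(-2 / 3) * I1
  gamma <- mat$a * exp(mat$b * (I1bar - 3))
  sig <- (mat$kappa * log(J) / J) * diag(3) +
    (gamma * J^(-5 / 3)) * (B - I1 / 3 * diag(3))
  cauchy_stress(sig)
}

#' @export
passive_stress.material_guccione <- function(def, mat) {
  F <- def$F
  J <- det(F)
  if (J <= 0) stop("invalid deformation: det F <= 0")
  C <- crossprod(F)
  Ebar <- 0.5 * (J^(-2 / 3) * C - diag(3))
  fr <- def$frame
  f <- fr$f0; s <- fr$s0; n <- fr$n0
  Eff <- drop(f %*% Ebar %*% f); Ess <- drop(s %*% Ebar %*% s)
  Enn <- drop(n %*% Ebar %*% n); Esn <- drop(s %*% Ebar %*% n)
  Efs <- drop(f %*% Ebar %*% s); Efn <- drop(f %*% Ebar %*% n)
  sym2 <- function(u, v) tcrossprod(u, v) + tcrossprod(v, u)
  # D = dQ/dEbar (symmetric)
  D <- 2 * mat$b_f * Eff * tcrossprod(f) +
    2 * mat$b_t * (Ess * tcrossprod(s) + Enn * tcrossprod(n) +
                     Esn * sym2(s, n)) +
    2 * mat$b_fs * (Efs * sym2(f, s) + Efn * sym2(f, n))
  Q <- .guccione_Q(Ebar, fr, mat)
  DC <- sum(D * C)
  FD <- F %*% D %*% t(F)
  sig <- (mat$kappa * log(J) / J) * diag(3) +
    (mat$a / 2) * exp(Q) * J^(-5 / 3) * (FD - DC / 3 * diag(3))
  cauchy_stress(sig)
}

#' Active tension transient
#'
#' Scalar active tension (kPa) developed a time `t_s` after local activation
#' onset:
#' `S_a = S_peak * phi(lambda) * tanh^2(t_s/tau_c) * tanh^2((t_dur-t_s)/tau_r)`
#' for `0 < t_s < t_dur` and zero outside that support. Vectorized over `t_s`.
#'
#' @param t_s time since activation onset (ms); may be a vector.
#' @param p an [active_params()] object.
#' @param lambda fiber stretch (dimensionless), passed to `p$phi`.
#' @return active tension S_a (kPa), same length as `t_s`.
#' @export
active_tension <- function(t_s, p, lambda = 1) {
  stopifnot(inherits(p, "active_params"))
  inside <- t_s > 0 & t_s < p$t_dur
  out <- numeric(length(t_s))
  ts <- t_s[inside]
  out[inside] <- p$S_peak * p$phi(lambda) *
    tanh(ts / p$tau_c)^2 * tanh((p$t_dur - ts) / p$tau_r)^2
  out
}

#' Active Cauchy stress tensor
#'
#' Rank-1 active stress acting along the deformed fiber direction:
#' `sigma_act = J^-1 S_a (f0 . C f0)^-1 (F f0) (F f0)^T`.
#' For `F = I` this reduces to `S_a f0 f0^T`; for incompressible deformations
#' its nonzero eigenvalue equals `S_a` exactly.
#'
#' @param def a [deformation_state()].
#' @param S_a active tension (kPa), non-negative.
#' @return a [cauchy_stress()] (Cartesian basis).
#' @export
active_stress_tensor <- function(def, S_a) {
  stopifnot(S_a >= 0)
  F <- def$F
  J <- det(F)
  if (J <= 0) stop("invalid deformation: det F <= 0")
  f0 <- def$frame$f0
  Ff <- drop(F %*% f0)
  lam2 <- sum(Ff^2)                       # f0 . C f0
  cauchy_stress(S_a / (J * lam2) * tcrossprod(Ff))
}

#' Cauchy stress tensor container
#'
#' A symmetric 3x3 stress tensor (kPa) tagged with the basis it is expressed
#' in (`"cartesian"`, `"spherical"` or `"ellipsoidal"`). Symmetry is enforced
#' to floating tolerance on construction.
#'
#' @param sigma 3x3 numeric matrix.
#' @param basis basis tag.
#' @param tol symmetry tolerance relative to the largest entry.
#' @return object of class `cauchy_stress` (a matrix with a `basis` attribute).
#' @export
cauchy_stress <- function(sigma, basis = "cartesian", tol = 1e-8) {
  sigma <- as.matrix(sigma)
  stopifnot(all(dim(sigma) == c(3, 3)))
  scale <- max(abs(sigma), 1e-12)
  if (max(abs(sigma - t(sigma))) > tol * scale)
    stop("stress tensor is not symmetric")
  sigma <- (sigma + t(sigma)) / 2
  structure(sigma, basis = basis, class = c("cauchy_stress", "matrix"))
}

#' Project a Cauchy stress onto the local spherical basis
#'
#' Builds the orthonormal spherical triad `(e_r, e_phi, e_theta)` at position
#' `x` relative to `center` and returns `P^T sigma P`, i.e. the components
#' `sigma_rr`, `sigma_phiphi`, `sigma_thetatheta` (and shears) of the same
#' tensor. The change of basis is orthogonal, so eigenvalues and trace are
#' preserved and the round trip recovers the input.
#'
#' @param sig a [cauchy_stress()] in the Cartesian basis.
#' @param x position (length 3, mm).
#' @param center sphere center (length 3, mm).
#' @param pole polar axis used to define the azimuth; default z.
#' @return a [cauchy_stress()] with basis `"spherical"`, ordered (r, phi,
#'   theta).
#' @export
project_stress <- function(sig, x, center = c(0, 0, 0), pole = c(0, 0, 1)) {
  d <- as.numeric(x) - as.numeric(center)
  nr <- sqrt(sum(d^2))
  if (nr < 1e-12) stop("undefined basis: position coincides with center")
  e_r <- d / nr
  e_phi <- cross3(pole, e_r)
  nphi <- sqrt(sum(e_phi^2))
  if (nphi < 1e-12) {                      # at the pole: pick any tangent
    e_phi <- cross3(c(1, 0, 0), e_r)
    nphi <- sqrt(sum(e_phi^2))
  }
  e_phi <- e_phi / nphi
  e_theta <- cross3(e_phi, e_r)
  P <- cbind(e_r, e_phi, e_theta)
  cauchy_stress(t(P) %*% unclass(sig) %*% P, basis = "spherical")
}

#' Volume average of a radial field over a spherical shell
#'
#' For radially symmetric fields on the shell `rho in [r, R]` the domain
#' average reduces to `int g(rho) rho^2 drho / int rho^2 drho` (the 4*pi
#' factors cancel). Computed by Gauss-Legendre quadrature.
#'
#' @param g function of the radius, vectorized.
#' @param r,R inner and outer radii (mm), `0 < r < R`.
#' @param n number of quadrature nodes.
#' @return the scalar average, guaranteed inside `[min g, max g]` up to
#'   quadrature error.
#' @export
volume_average <- function(g, r, R, n = 200) {
  if (!(r > 0 && R > r)) stop("zero-volume or invalid shell domain")
  gl <- .gauss_nodes(n, r, R)
  sum(gl$w * g(gl$x) * gl$x^2) / sum(gl$w * gl$x^2)
}

# cached Gauss-Legendre nodes on [a, b]
.gl_cache <- new.env(parent = emptyenv())
.gauss_nodes <- function(n, a, b) {
  key <- as.character(n)
  ref <- .gl_cache[[key]]
  if (is.null(ref)) {
    ref <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- ref
  }
  list(x = (a + b) / 2 + (b - a) / 2 * ref$x, w = (b - a) / 2 * ref$w)
}
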