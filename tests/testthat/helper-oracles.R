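# Independent oracles used across the suite.

# Finite-difference Cauchy stress: sigma = J^-1 P F^T with the first
# Piola-Kirchhoff tensor P = dPsi/dF obtained by central differences over the
# nine components of F. Independent of the analytic stress path.
fd_cauchy_stress <- function(def, mat, h = 1e-6) {
  F <- def$F
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (strain_energy(deformation_state(Fp, def$frame), mat) -
                  strain_energy(deformation_state(Fm, def$frame), mat)) /
      (2 * h)
  }
  P %*% t(F) / det(F)
}

# random deformation gradient with det F > 0, bounded away from singular
random_F <- function(spread = 0.15) {
  repeat {
    F <- diag(3) + matrix(runif(9, -spread, spread), 3)
    if (det(F) > 0.4) return(F)
  }
}

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# closed-form in-plane radius of an axis-aligned ellipsoid with semi-axes
# (a, a, c) at axial offset z from its center
ellipsoid_inplane_radius <- function(a, c_ax, z) {
  ifelse(abs(z) < c_ax, a * sqrt(1 - (z / c_ax)^2), NA_real_)
}

# shared fixtures for the verification experiments
demiray_benchmark <- function() material_demiray(a = 10, b = 8)

patient_a_windkessel <- function() {
  wkt <- windkessel_records()[1, ]
  windkessel_params(wkt$Z_v, wkt$Z_a, wkt$R_art, wkt$C_art)
}
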