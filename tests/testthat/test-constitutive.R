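test_that("strain energy vanishes at the reference and matches closed forms", {
  dem <- material_demiray(10, 8)
  guc <- material_guccione(0.5)
  id <- deformation_state(diag(3))
  expect_equal(strain_energy(id, dem), 0)
  expect_equal(strain_energy(id, guc), 0)

  # isochoric uniaxial stretch: independent scalar evaluation of the
  # exponential isotropic energy with J = 1
  lam <- 1.2
  F <- diag(c(lam, lam^(-1 / 2), lam^(-1 / 2)))
  trC <- lam^2 + 2 / lam
  expect_equal(strain_energy(deformation_state(F), dem),
               10 / 16 * (exp(8 * (trC - 3)) - 1), tolerance = 1e-12)

  # pure dilatation: volumetric term only, isochoric invariant is
  # dilatation-invariant
  g <- 1.07
  expect_equal(strain_energy(deformation_state(g * diag(3)), dem),
               dem$kappa / 2 * (3 * log(g))^2, tolerance = 1e-12)
  expect_equal(strain_energy(deformation_state(g * diag(3)), guc),
               guc$kappa / 2 * (3 * log(g))^2, tolerance = 1e-12)
})

test_that("invalid deformations are rejected", {
  expect_error(deformation_state(diag(c(1, 1, -1))), "det F")
  expect_error(deformation_state(diag(c(1, 1, 0))), "det F")
  expect_error(fiber_frame(c(1, 0, 0), c(1, 0, 0)), "orthonormal")
})

test_that("analytic passive stress agrees with the energy finite-difference oracle", {
  dem <- material_demiray(10, 8)
  guc <- material_guccione(0.5)
  expect_equal(unclass(passive_stress(deformation_state(diag(3)), dem)),
               matrix(0, 3, 3), ignore_attr = TRUE)

  # pure dilatation, isotropic material: sigma = kappa log(J)/J * I
  g <- 1.1
  sig <- passive_stress(deformation_state(g * diag(3)), dem)
  expect_equal(unclass(sig), dem$kappa * log(g^3) / g^3 * diag(3),
               tolerance = 1e-10, ignore_attr = TRUE)

  set.seed(42)
  frame <- fiber_frame()
  for (k in 1:100) {
    def <- deformation_state(random_F(), frame)
    mat <- if (k %% 2 == 0) dem else guc
    sig <- passive_stress(def, mat)
    orc <- fd_cauchy_stress(def, mat)
    expect_lt(max(abs(unclass(sig) - orc)) / max(abs(orc), 1e-8), 1e-5)
  }
})

test_that("active tension transient has the stated support and magnitude", {
  p <- active_params(S_peak = 69, tau_c = 80, tau_r = 25, t_dur = 300)
  expect_equal(active_tension(0, p), 0)
  expect_equal(active_tension(300, p), 0)
  expect_equal(active_tension(-10, p), 0)
  expect_equal(active_tension(500, p), 0)
  # independent scalar evaluation at mid-transient
  expect_equal(active_tension(150, p),
               69 * tanh(150 / 80)^2 * tanh(150 / 25)^2, tolerance = 1e-12)
  ts <- seq(0, 300, by = 1)
  sa <- active_tension(ts, p)
  expect_true(all(sa >= 0 & sa <= 69))
})

test_that("active stress tensor is rank one along the deformed fiber", {
  fr <- fiber_frame()
  id <- deformation_state(diag(3), fr)
  expect_equal(unclass(active_stress_tensor(id, 0)), matrix(0, 3, 3),
               ignore_attr = TRUE)
  expect_equal(unclass(active_stress_tensor(id, 12)),
               12 * tcrossprod(c(1, 0, 0)), ignore_attr = TRUE)
  lam <- 1.3
  sig <- active_stress_tensor(deformation_state(diag(c(lam, 1, 1)), fr), 10)
  expect_equal(unclass(sig), 10 / lam * tcrossprod(c(1, 0, 0)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # symmetric rank-1: one nonzero eigenvalue
  ev <- eigen(unclass(sig), symmetric = TRUE)$values
  expect_equal(sort(abs(ev))[1:2], c(0, 0))
})

test_that("spherical projection is an orthogonal change of basis", {
  set.seed(7)
  x <- c(3, -2, 5)
  A <- matrix(rnorm(9), 3); sig <- cauchy_stress((A + t(A)) / 2)
  proj <- project_stress(sig, x)
  expect_equal(sum(diag(proj)), sum(diag(sig)))
  expect_equal(eigen(unclass(proj))$values, eigen(unclass(sig))$values,
               tolerance = 1e-12)
  # isotropic tensor is basis-independent
  iso <- cauchy_stress(3.5 * diag(3))
  expect_equal(unclass(project_stress(iso, x)), 3.5 * diag(3),
               tolerance = 1e-12, ignore_attr = TRUE)
  # pure radial dyad: only sigma_rr nonzero
  er <- x / sqrt(sum(x^2))
  rad <- cauchy_stress(2.2 * tcrossprod(er))
  pr <- unclass(project_stress(rad, x))
  expect_equal(pr[1, 1], 2.2, tolerance = 1e-12)
  expect_lt(max(abs(pr[-1, -1])), 1e-12)
  expect_error(project_stress(sig, c(0, 0, 0)), "center")
})

test_that("shell volume average reduces to the closed-form radial integral", {
  expect_equal(volume_average(function(x) rep(3, length(x)), 1, 2), 3)
  # g(rho) = rho on [1, 2]: (int rho^3) / (int rho^2) = (15/4)/(7/3)
  expect_equal(volume_average(identity, 1, 2), 45 / 28, tolerance = 1e-12)
  g1 <- function(x) sin(x); g2 <- function(x) x^2
  expect_equal(volume_average(function(x) g1(x) + g2(x), 1, 2),
               volume_average(g1, 1, 2) + volume_average(g2, 1, 2),
               tolerance = 1e-12)
  expect_error(volume_average(identity, 2, 2), "domain")
})

test_that("energy is convex along dilatational rays and truly anisotropic", {
  dem <- material_demiray(10, 8)
  gam <- seq(0.8, 1.2, length.out = 41)
  psi <- vapply(gam, function(g)
    strain_energy(deformation_state(g * diag(3)), dem), 0)
  expect_true(all(diff(diff(psi)) > 0))

  # swapping fiber against sheet changes the Guccione energy unless b_f = b_t
  F <- diag(c(1.15, 0.95, 0.92))
  guc <- material_guccione(0.5)
  f1 <- fiber_frame(c(1, 0, 0), c(0, 1, 0))
  e1 <- strain_energy(deformation_state(F, f1), guc)
  e2 <- strain_energy(deformation_state(F, fiber_frame(
    c(0, 1, 0), c(1, 0, 0), cross3(c(0, 1, 0), c(1, 0, 0)))), guc)
  expect_gt(abs(e1 - e2), 1e-6)
  iso <- material_guccione(0.5, b_f = 3.58, b_t = 3.58, b_fs = 3.58)
  e1i <- strain_energy(deformation_state(F, f1), iso)
  e2i <- strain_energy(deformation_state(F, fiber_frame(
    c(0, 1, 0), c(1, 0, 0), cross3(c(0, 1, 0), c(1, 0, 0)))), iso)
  expect_equal(e1i, e2i, tolerance = 1e-12)
})
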