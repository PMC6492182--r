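#' Clinical input records for four aortic-stenosis patients
#'
#' Pretreatment hemodynamic characteristics (MRI volumes, cuff pressures,
#' equatorial wall thickness, transvalvular pressure drop) used to
#' parameterize patient-like synthetic cycles.
#'
#' @return data.frame with one row per patient (A-D): `EDV`, `ESV` (ml),
#'   `SV` (ml), `EF` (%), `HR` (1/min), `p_dia`, `p_sys`, `MAP` (mmHg),
#'   `h_septum`, `h_lateral` (mm), `delta_p` (mmHg).
#' @export
patient_records <- function() {
  data.frame(
    id = c("A", "B", "C", "D"),
    EDV = c(112.0, 121.0, 118.2, 172.0),
    ESV = c(46.0, 54.7, 42.2, 103.0),
    SV = c(66.00, 66.32, 76.14, 69.00),
    EF = c(58.93, 54.81, 64.42, 40.12),
    HR = c(53, 81, 75, 68),
    p_dia = c(74, 75, 71, 79),
    p_sys = c(126, 134, 141, 144),
    MAP = c(91.33, 94.67, 94.33, 100.67),
    h_septum = c(12.0, 11.2, 16.0, 14.0),
    h_lateral = c(12.5, 13.8, 18.2, 15.2),
    delta_p = c(95, 62, 79, 59))
}

#' Fitted afterload and active-stress parameters per patient
#'
#' Three-element Windkessel parameters (valve impedance `Z_v`, aortic
#' characteristic impedance `Z_a`, peripheral resistance `R_art`, compliance
#' `C_art`) together with the fitted active-stress scale `S_peak` and
#' upstroke time constant `tau_c`.
#'
#' @return data.frame, one row per patient A-D; impedances in kPa ms/ml,
#'   compliance in ml/kPa, `S_peak` in kPa, `tau_c` in ms.
#' @export
windkessel_records <- function() {
  data.frame(
    id = c("A", "B", "C", "D"),
    Z_v = c(35.82, 16.08, 15.93, 22.34),
    Z_a = c(26.00, 11.03, 12.78, 11.09),
    R_art = c(187.74, 72.65, 77.34, 62.73),
    C_art = c(15.23, 26.62, 25.50, 30.93),
    S_peak = c(69, 85, 63, 98),
    tau_c = c(80, 35, 40, 58))
}

#' Three-element Windkessel parameter set
#'
#' @param Z_v aortic valve impedance (kPa ms/ml).
#' @param Z_a aortic characteristic impedance (kPa ms/ml).
#' @param R_art peripheral arterial resistance (kPa ms/ml).
#' @param C_art arterial compliance (ml/kPa).
#' @return object of class `windkessel_params`.
#' @export
windkessel_params <- function(Z_v, Z_a, R_art, C_art) {
  stopifnot(Z_v > 0, Z_a > 0, R_art > 0, C_art > 0)
  structure(list(Z_v = Z_v, Z_a = Z_a, R_art = R_art, C_art = C_art),
            class = "windkessel_params")
}

#' One implicit step of the arterial compartment
#'
#' Backward-Euler update of the compliance pressure
#' `C_art dp_c/dt = q - p_c / R_art`; the aortic root pressure follows as
#' `p_ao = p_c + Z_a q`. With zero flow `p_c` decays exponentially with time
#' constant `R_art * C_art`.
#'
#' @param p_c compliance (arterial) pressure state (kPa).
#' @param q flow into the aorta (ml/ms).
#' @param dt time step (ms), positive.
#' @param wk a [windkessel_params()].
#' @return list with updated `p_c` and `p_ao` (kPa).
#' @export
windkessel_step <- function(p_c, q, dt, wk) {
  stopifnot(dt > 0)
  p_c_new <- (p_c + dt * q / wk$C_art) / (1 + dt / (wk$R_art * wk$C_art))
  list(p_c = p_c_new, p_ao = p_c_new + wk$Z_a * q)
}

#' Cycle simulator configuration
#'
#' @param geometry a [sphere_geometry()] (reference radii of the lumped LV).
#' @param passive a [material_demiray()] for the passive wall.
#' @param active an [active_params()] transient.
#' @param wk a [windkessel_params()] afterload.
#' @param edp end-diastolic pressure (kPa).
#' @param period heart period (ms).
#' @param dt time step (ms), at most 1 ms.
#' @param p_ao0 initial aortic (compliance) pressure (kPa).
#' @param noise_sd optional measurement noise s.d. added to the emitted
#'   radii traces (mm); 0 disables.
#' @param seed integer seed for the noise injection.
#' @param n_quad quadrature nodes for the sphere equilibrium solves.
#' @return object of class `cycle_config`.
#' @export
cycle_config <- function(geometry, passive, active, wk, edp = 1.5,
                         period = 60000 / 53, dt = 1,
                         p_ao0 = mmHg_to_kPa(74), noise_sd = 0, seed = 1L,
                         n_quad = 64) {
  stopifnot(inherits(geometry, "sphere_geometry"),
            inherits(passive, "material_demiray"),
            inherits(active, "active_params"),
            inherits(wk, "windkessel_params"),
            edp > 0, period > 0, dt > 0, dt <= 1)
  if (period <= active$t_dur)
    warning("heart period is not longer than the active transient duration")
  structure(list(geometry = geometry, passive = passive, active = active,
                 wk = wk, edp = edp, period = period, dt = dt,
                 p_ao0 = p_ao0, noise_sd = noise_sd, seed = as.integer(seed),
                 n_quad = n_quad),
            class = "cycle_config")
}

#' Derived clinical record fields
#'
#' Exact arithmetic on the primary record entries: stroke volume
#' `SV = EDV - ESV` (ml), ejection fraction `EF = 100 SV / EDV` (%), mean
#' arterial pressure `MAP = p_dia + (p_sys - p_dia)/3` (mmHg) and cardiac
#' output `CO = SV * HR` (ml/min).
#'
#' @param EDV,ESV end-diastolic and end-systolic volume (ml), `EDV > ESV >=
#'   0`.
#' @param HR heart rate (1/min).
#' @param p_dia,p_sys cuff pressures (mmHg).
#' @return list with `SV`, `EF`, `MAP`, `CO`.
#' @export
derive_record_fields <- function(EDV, ESV, HR, p_dia, p_sys) {
  if (EDV <= 0) stop("EDV must be positive")
  if (ESV < 0 || ESV >= EDV) stop("require EDV > ESV >= 0")
  SV <- EDV - ESV
  list(SV = SV, EF = 100 * SV / EDV,
       MAP = map_from_cuff(p_dia, p_sys), CO = SV * HR)
}

#' Simulate one LV cycle of the lumped active sphere
#'
#' The LV is a thick incompressible spherical shell with the passive Demiray
#' response and a spatially uniform active tension added to both in-plane
#' principal stresses. The cycle starts at end diastole (shell inflated to
#' `edp`) and proceeds through
#'
#' 1. isovolumetric contraction (IVC): radius fixed while the active
#'    transient raises the luminal pressure to the aortic pressure;
#' 2. ejection against the three-element Windkessel: at every step the
#'    deformed radius solves the implicit balance `p_sphere(r, S_a) = p_ao +
#'    Z_v q` with `q = -dV_cav/dt`; the valve closes when the flow falls to
#'    zero;
#' 3. isovolumetric relaxation (IVR): radius fixed while the transient
#'    decays;
#' 4. filling: a quasi-static pressure ramp back to `edp`, ending the cycle
#'    at the end-diastolic state.
#'
#' @param cfg a [cycle_config()].
#' @return object of class `hemo_trace`: a data.frame with columns `t_ms`,
#'   `p_lv_kPa`, `p_ao_kPa`, `V_cav_ml`, `q_ml_per_ms` (outflow, positive
#'   during ejection), `r_mm`, `R_mm`, `S_a_kPa`, `phase`; attributes
#'   `events` (named times `t_0ej`, `t_ES`, `t_phat`, `T_sct`), `config`.
#' @export
simulate_cycle <- function(cfg) {
  stopifnot(inherits(cfg, "cycle_config"))
  geom <- cfg$geometry; mat <- cfg$passive; act <- cfg$active
  wk <- cfg$wk; dt <- cfg$dt; nq <- cfg$n_quad
  p_of <- function(r, Sa) pressure_from_inner_radius(geom, mat, r, Sa, nq,
                                                     allow_compression = TRUE)
  V_of <- function(r) 4 * pi / 3 * r^3 / 1000
  ed <- inflate(geom, mat, cfg$edp, n_profile = 3, n_quad = nq)
  r_ed <- ed$r
  nt <- floor(cfg$period / dt) + 1L
  t <- (seq_len(nt) - 1) * dt
  p_lv <- p_ao <- r <- q <- Sa <- numeric(nt)
  phase <- character(nt)
  p_c <- cfg$p_ao0
  r[1] <- r_ed
  Sa[1] <- 0
  p_lv[1] <- cfg$edp
  p_ao[1] <- p_c
  phase[1] <- "IVC"
  mode <- "IVC"
  t_0ej <- t_ES <- NA_real_
  r_es <- NA_real_
  fill_from_p <- NA_real_; fill_from_t <- NA_real_
  for (k in 2:nt) {
    Sa[k] <- active_tension(t[k], act)
    if (mode == "IVC") {
      r[k] <- r_ed
      p_lv[k] <- p_of(r_ed, Sa[k])
      st <- windkessel_step(p_c, 0, dt, wk)
      p_c <- st$p_c; p_ao[k] <- st$p_ao
      q[k] <- 0
      phase[k] <- "IVC"
      if (p_lv[k] >= p_ao[k]) {
        # valve opens; ejection dynamics start at the next step
        mode <- "ejection"
        if (is.na(t_0ej)) t_0ej <- t[k]
      }
      next
    }
    if (mode == "ejection") {
      r_prev <- r[k - 1]
      resid <- function(rn) {
        qn <- -(V_of(rn) - V_of(r_prev)) / dt
        st <- windkessel_step(p_c, qn, dt, wk)
        p_of(rn, Sa[k]) - (st$p_ao + wk$Z_v * qn)
      }
      # no-flow residual decides whether ejection continues
      if (resid(r_prev) <= 0) {
        mode <- "IVR"
        t_ES <- t[k]
        r_es <- r_prev
      } else {
        lo <- r_prev * 0.97
        it <- 0
        while (resid(lo) > 0 && it < 40) { lo <- lo * 0.99; it <- it + 1 }
        rn <- stats::uniroot(resid, c(lo, r_prev), tol = 1e-11)$root
        qn <- -(V_of(rn) - V_of(r_prev)) / dt
        st <- windkessel_step(p_c, qn, dt, wk)
        p_c <- st$p_c
        r[k] <- rn
        q[k] <- qn
        p_ao[k] <- st$p_ao
        p_lv[k] <- p_ao[k] + wk$Z_v * qn
        phase[k] <- "ejection"
        next
      }
    }
    if (mode == "IVR") {
      r[k] <- r_es
      p_lv[k] <- p_of(r_es, Sa[k])
      st <- windkessel_step(p_c, 0, dt, wk)
      p_c <- st$p_c; p_ao[k] <- st$p_ao
      q[k] <- 0
      phase[k] <- "IVR"
      if (Sa[k] <= 0 && t[k] >= act$t_dur) {
        mode <- "filling"
        fill_from_p <- p_lv[k]
        fill_from_t <- t[k]
      }
      next
    }
    # filling: linear pressure ramp back to EDP, quasi-static inflation;
    # the ramp ends exactly at the last sample so the cycle closes at ED
    frac <- (t[k] - fill_from_t) / max(t[nt] - fill_from_t, dt)
    p_tgt <- fill_from_p + (cfg$edp - fill_from_p) * min(frac, 1)
    f <- function(rr) p_of(rr, 0) - p_tgt
    lo <- r[k - 1] * 0.999; hi <- r_ed * 1.001
    r[k] <- if (f(lo) >= 0) lo else stats::uniroot(f, c(lo, hi),
                                                   tol = 1e-11)$root
    p_lv[k] <- p_tgt
    st <- windkessel_step(p_c, 0, dt, wk)
    p_c <- st$p_c; p_ao[k] <- st$p_ao
    q[k] <- 0
    phase[k] <- "filling"
  }
  R <- (geom$R0^3 + r^3 - geom$r0^3)^(1 / 3)
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed)
    r_obs <- r + stats::rnorm(nt, 0, cfg$noise_sd)
    R_obs <- R + stats::rnorm(nt, 0, cfg$noise_sd)
  } else {
    r_obs <- r; R_obs <- R
  }
  tr <- data.frame(t_ms = t, p_lv_kPa = p_lv, p_ao_kPa = p_ao,
                   V_cav_ml = 4 * pi / 3 * r^3 / 1000,
                   q_ml_per_ms = q, r_mm = r_obs, R_mm = R_obs,
                   S_a_kPa = Sa, phase = phase)
  t_phat <- t[which.max(p_lv)]
  events <- c(t_0ej = t_0ej, t_ES = t_ES, t_phat = t_phat,
              T_sct = t_phat)  # ED is t = 0, so T_sct = t_phat
  structure(tr, events = events, config = cfg,
            class = c("hemo_trace", "data.frame"))
}

#' Build a cycle configuration from a clinical record
#'
#' Maps a patient record to the lumped model. The measured end-diastolic
#' volume fixes the end-diastolic inner radius
#' `r_ED = (3 EDV / 4 pi)^(1/3)`; the wall thickness at ED is the mean of
#' the septal and lateral measurements, and the wall volume is conserved.
#' Because EDV is a *loaded* volume, the stress-free reference radius `r0`
#' is then unloaded: it is root-found so that passive inflation of the
#' reference shell to `edp` reproduces exactly `r_ED` (and hence EDV). The
#' heart period comes from the heart rate and the initial aortic pressure
#' from the diastolic cuff pressure. Finally the peak active tension
#' `S_peak` is fitted by bisection so that the simulated ejection fraction
#' matches the record's EF within `ef_tol` percentage points.
#'
#' @param rec one-row data.frame as in [patient_records()].
#' @param wk a [windkessel_params()].
#' @param passive passive material; default Demiray a = 10 kPa, b = 8.
#' @param tau_c,t_dur,tau_r active transient time constants (ms).
#' @param edp end-diastolic pressure (kPa).
#' @param ef_tol absolute EF tolerance (percentage points) for the bisection.
#' @param s_max upper bisection bound for `S_peak` (kPa).
#' @param ... further arguments passed to [cycle_config()].
#' @return a [cycle_config()] whose simulated EF matches the record; the
#'   fitted `S_peak` and achieved EF are attached as attributes `S_peak` and
#'   `EF_achieved`.
#' @export
config_from_patient <- function(rec, wk, passive = material_demiray(1.5, 3),
                                tau_c = 80, t_dur = 300, tau_r = 30,
                                edp = 1.5, ef_tol = 0.5, s_max = 400, ...) {
  r_ed <- (3 * rec$EDV * 1000 / (4 * pi))^(1 / 3)
  h_ed <- mean(c(rec$h_septum, rec$h_lateral))
  wall <- (r_ed + h_ed)^3 - r_ed^3         # conserved, mm^3 * 3/(4 pi)
  geom_of <- function(r0) sphere_geometry(r0, (r0^3 + wall)^(1 / 3))
  unload <- function(r0) {
    inflate(geom_of(r0), passive, edp, n_profile = 3, n_quad = 64)$r - r_ed
  }
  r0 <- stats::uniroot(unload, c(r_ed * 0.4, r_ed * (1 - 1e-9)),
                       tol = 1e-9)$root
  geom <- geom_of(r0)
  make_cfg <- function(S_peak) {
    cycle_config(geometry = geom, passive = passive,
                 active = active_params(S_peak, tau_c, tau_r, t_dur),
                 wk = wk, edp = edp, period = 60000 / rec$HR,
                 p_ao0 = mmHg_to_kPa(rec$p_dia), ...)
  }
  ef_of <- function(S_peak) {
    if (S_peak == 0) return(0)
    simulated_ef(simulate_cycle(make_cfg(S_peak)))
  }
  target <- rec$EF
  if (target <= 0) {
    cfg <- make_cfg(0)
    attr(cfg, "S_peak") <- 0
    attr(cfg, "EF_achieved") <- 0
    return(cfg)
  }
  lo <- 0; hi <- s_max
  ef_hi <- ef_of(hi)
  if (ef_hi < target - ef_tol)
    stop("infeasible EF target: ", target, "% unreachable below S_peak = ",
         s_max, " kPa (achieved ", round(ef_hi, 2), "%)")
  ef_mid <- NA
  S <- hi
  for (it in 1:40) {
    S <- (lo + hi) / 2
    ef_mid <- ef_of(S)
    if (abs(ef_mid - target) <= ef_tol) break
    if (ef_mid < target) lo <- S else hi <- S
  }
  cfg <- make_cfg(S)
  attr(cfg, "S_peak") <- S
  attr(cfg, "EF_achieved") <- ef_mid
  cfg
}

#' Ejection fraction of a simulated trace
#'
#' `EF = 100 (V_ED - V_ES) / V_ED` with `V_ED` the maximum and `V_ES` the
#' minimum cavity volume of the trace (%).
#'
#' @param trace a `hemo_trace`.
#' @export
simulated_ef <- function(trace) {
  V <- trace$V_cav_ml
  100 * (max(V) - min(V)) / max(V)
}

#' Emit endo/epicardial surfaces for a trace sample
#'
#' Generates triangulated surfaces consistent with the cavity-volume trace of
#' the lumped simulation. Shape `"sphere"` emits concentric icospheres at the
#' deformed radii. Shape `"prolate"` (default) maps the sphere to a
#' volume-matched prolate ellipsoid with long/short axis ratio `aspect`
#' (endocardial semi-axes `(a, a, c)` with `c = aspect * a` and `a^2 c =
#' r^3`); the epicardial offset is solved so the wall volume matches the
#' incompressible shell's, making the emitted anatomy nonspherical the way an
#' LV is while preserving both volumes.
#'
#' @param r,R deformed inner/outer sphere radii (mm).
#' @param shape `"prolate"` or `"sphere"`.
#' @param aspect prolate long-axis to short-axis ratio.
#' @param subdiv icosphere subdivision level.
#' @param label time stamp (ms).
#' @return a [surface_pair()].
#' @export
emit_surfaces <- function(r, R, shape = c("prolate", "sphere"),
                          aspect = 1.8, subdiv = 3, label = NA_real_) {
  shape <- match.arg(shape)
  if (shape == "sphere") {
    return(surface_pair(icosphere(subdiv, r), icosphere(subdiv, R), label))
  }
  a <- (r^3 / aspect)^(1 / 3)
  cc <- aspect * a
  wall <- R^3 - r^3                        # mm^3 * 3/(4 pi)
  f <- function(h) (a + h)^2 * (cc + h) - a^2 * cc - wall
  h <- stats::uniroot(f, c(1e-9, R), tol = 1e-12)$root
  surface_pair(icosphere(subdiv, c(a, a, cc)),
               icosphere(subdiv, c(a + h, a + h, cc + h)), label)
}
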