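#' Relative deviation in percent
#'
#' `(estimate / truth - 1) * 100`.
#'
#' @param truth reference value, nonzero.
#' @param estimate estimated value.
#' @export
relative_deviation <- function(truth, estimate) {
  if (any(truth == 0)) stop("zero truth in relative deviation")
  (estimate / truth - 1) * 100
}

#' Sphere verification experiment
#'
#' Inflates the benchmark shells to `p_target`, computes the exact
#' volume-averaged stresses, the three Laplace estimates on the deformed
#' geometry, internal and external work along a pressure ramp, and the
#' Laplace work estimates. The deviation report uses the mean in-plane
#' stress `sigma_circ_bar = (sigma_tt_bar + sigma_pp_bar) / 2` as the truth.
#'
#' @param geoms named list of [sphere_geometry()] objects; defaults to
#'   [benchmark_geometries()].
#' @param mat passive material; default Demiray a = 10 kPa, b = 8.
#' @param p_target evaluation pressure (kPa), default 4.
#' @param ramp_steps number of pressure steps for the work integrals.
#' @param n_profile,n_quad discretization controls.
#' @return list with `table` (one row per shell: mean stresses, Laplace
#'   stresses, works) and `deviations` (percent deviations of each Laplace
#'   stress from `sigma_circ_bar` and the radial-to-circumferential ratio).
#' @export
run_sphere_verification <- function(geoms = benchmark_geometries(),
                                    mat = material_demiray(10, 8),
                                    p_target = 4, ramp_steps = 40,
                                    n_profile = 801, n_quad = 200) {
  rows <- lapply(names(geoms), function(nm) {
    g <- geoms[[nm]]
    ramp_p <- seq(0, p_target, length.out = ramp_steps + 1)
    states <- inflation_ramp(g, mat, ramp_p, n_profile, n_quad)
    st <- states[[length(states)]]
    ms <- mean_stresses(st)
    h <- st$R - st$r
    Vc <- cavity_volume(st); Vm <- wall_volume(st)
    W_int <- internal_work(states)
    pV <- data.frame(p = ramp_p,
                     V = vapply(states, cavity_volume, 0))
    W_ext <- external_work(pV$p, pV$V)
    # Laplace work on the ramp: pseudo-time is the step index
    tt <- seq_along(states)
    r_tr <- vapply(states, function(s) s$r, 0)
    R_tr <- vapply(states, function(s) s$R, 0)
    h_tr <- R_tr - r_tr
    sL_h <- sigma_thin(ramp_p, r_tr, h_tr)
    sL_H <- sigma_thick(ramp_p, r_tr, h_tr)
    P_h <- laplace_power(tt, sL_h, r_tr, R_tr, Vm)
    P_H <- laplace_power(tt, sL_H, r_tr, R_tr, Vm)
    W_h <- work_from_power(tt, P_h) * 1e3   # pseudo-time: W.ms scale cancels
    W_H <- work_from_power(tt, P_H) * 1e3
    data.frame(model = nm,
               sigma_rr_bar = ms[["sigma_rr"]],
               sigma_tt_bar = ms[["sigma_tt"]],
               sigma_pp_bar = ms[["sigma_pp"]],
               sigma_L_h = sigma_thin(p_target, st$r, h),
               sigma_L_H = sigma_thick(p_target, st$r, h),
               sigma_L_V = sigma_volume(p_target, Vc, Vm),
               W_int_J = W_int, W_ext_J = W_ext,
               W_int_h_J = W_h[length(W_h)] * .J_per_kPa_ml,
               W_int_H_J = W_H[length(W_H)] * .J_per_kPa_ml)
  })
  tab <- do.call(rbind, rows)
  circ <- (tab$sigma_tt_bar + tab$sigma_pp_bar) / 2
  dev <- data.frame(model = tab$model,
                    dev_L_h = relative_deviation(circ, tab$sigma_L_h),
                    dev_L_H = relative_deviation(circ, tab$sigma_L_H),
                    dev_L_V = relative_deviation(circ, tab$sigma_L_V),
                    rr_over_circ = abs(tab$sigma_rr_bar) / circ * 100,
                    W_dev = relative_deviation(tab$W_ext_J, tab$W_int_J))
  list(table = tab, deviations = dev)
}

#' Ground-truth stress and power series of a simulated cycle
#'
#' Recomputes, at every trace sample, the exact radial stress profile of the
#' lumped shell (passive plus active) and its volume averages, the internal
#' power by integrating `sigma : epsilon_dot` over the deformed wall
#' (midpoint stresses, finite displacement increments), and the hydrodynamic
#' power `p dV/dt`.
#'
#' @param trace a `hemo_trace` from [simulate_cycle()].
#' @param n_profile profile resolution.
#' @return data.frame with `t_ms`, `sigma_rr_bar`, `sigma_tt_bar`,
#'   `sigma_pp_bar`, `sigma_circ_bar` (kPa), `P_int_W`, `P_ext_W`.
#' @export
truth_series <- function(trace, n_profile = 401) {
  cfg <- attr(trace, "config")
  geom <- cfg$geometry; mat <- cfg$passive
  nt <- nrow(trace)
  xi <- seq(geom$r0, geom$R0, length.out = n_profile)
  w <- xi^2
  vol <- pracma::trapz(xi, w)
  prof <- function(k) {
    # exact radius (noise-free) from the cavity volume trace
    r_def <- (trace$V_cav_ml[k] * 1000 * 3 / (4 * pi))^(1 / 3)
    sphere_state(geom, mat, r_def, trace$S_a_kPa[k], n_profile, cfg$n_quad)
  }
  states <- lapply(seq_len(nt), prof)
  s_rr <- vapply(states, function(s)
    pracma::trapz(xi, s$sigma_rr * w) / vol, 0)
  s_tt <- vapply(states, function(s)
    pracma::trapz(xi, s$sigma_tt * w) / vol, 0)
  # internal power between consecutive samples, assigned to midpoints and
  # interpolated back to the sample grid
  P_mid <- numeric(nt - 1)
  for (k in seq_len(nt - 1)) {
    s0 <- states[[k]]; s1 <- states[[k + 1]]
    dtk <- trace$t_ms[k + 1] - trace$t_ms[k]
    rho_mid <- (s0$rho + s1$rho) / 2
    rate <- (s1$rho - s0$rho) / dtk / rho_mid
    delta_mid <- ((s0$sigma_tt - s0$sigma_rr) +
                    (s1$sigma_tt - s1$sigma_rr)) / 2
    P_mid[k] <- pracma::trapz(xi, 2 * delta_mid * rate * 4 * pi * xi^2) * 1e-3
  }
  P_int <- numeric(nt)
  P_int[1] <- P_mid[1]; P_int[nt] <- P_mid[nt - 1]
  if (nt > 2) P_int[2:(nt - 1)] <- (P_mid[-1] + P_mid[-(nt - 1)]) / 2
  P_ext <- hydrodynamic_power(trace$t_ms, trace$p_lv_kPa,
                              V = trace$V_cav_ml)
  # the valve constraint enforces dV = 0 exactly during the isovolumetric
  # phases; remove finite-difference leakage across phase boundaries
  P_ext[trace$phase %in% c("IVC", "IVR")] <- 0
  data.frame(t_ms = trace$t_ms,
             sigma_rr_bar = s_rr, sigma_tt_bar = s_tt, sigma_pp_bar = s_tt,
             sigma_circ_bar = s_tt,
             P_int_W = P_int, P_ext_W = P_ext)
}

#' Cycle comparison experiment
#'
#' Runs the full evaluation of the Laplace estimators on one simulated
#' cycle: surfaces are emitted at a coarse imaging-like sampling interval,
#' sliced for mean radius and wall width, and the three Laplace stress and
#' power series are computed from those mesh-derived inputs. The result
#' bundles the ground-truth series, the Laplace series, and a peak-power
#' summary (peak internal and external power, their values at the instant of
#' peak pressure, the product of peak pressure and peak flow, IHP, EHP and
#' the two efficiency measures).
#'
#' @param cfg a [cycle_config()].
#' @param mesh_every surface emission interval (ms); default 20 ms,
#'   comparable to short-axis imaging frame times.
#' @param shape,aspect,subdiv see [emit_surfaces()].
#' @param slice_width,dphi see [slice_and_sample()].
#' @param ihp_variant which Laplace stress feeds IHW/IHP.
#' @param out_dir optional directory; when given, the emitted surfaces are
#'   written as numbered PLY pairs and the series as CSV.
#' @return list of class `cycle_comparison`: `trace`, `truth`, `laplace`
#'   (frame-grid series with slice-derived geometry, stresses, powers),
#'   `summary` (named list of peak-power metrics, paper-style sign
#'   convention: generated power negative in `paper_convention`, positive in
#'   the main fields), `events`.
#' @export
run_cycle_comparison <- function(cfg, mesh_every = 20,
                                 shape = c("prolate", "sphere"),
                                 aspect = 1.8, subdiv = 3,
                                 slice_width = 8, dphi = 9,
                                 ihp_variant = c("h", "H", "V"),
                                 out_dir = NULL) {
  shape <- match.arg(shape)
  ihp_variant <- match.arg(ihp_variant)
  trace <- simulate_cycle(cfg)
  truth <- truth_series(trace)
  # frame grid for the imaging-like geometric analysis
  idx <- seq(1, nrow(trace), by = max(1L, round(mesh_every / cfg$dt)))
  frames <- trace[idx, ]
  geo <- lapply(seq_len(nrow(frames)), function(i) {
    pair <- emit_surfaces(frames$r_mm[i], frames$R_mm[i], shape, aspect,
                          subdiv, label = frames$t_ms[i])
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_ply(pair$endo, file.path(out_dir,
        sprintf("endo_%04d.ply", as.integer(frames$t_ms[i]))))
      write_ply(pair$epi, file.path(out_dir,
        sprintf("epi_%04d.ply", as.integer(frames$t_ms[i]))))
    }
    ss <- slice_and_sample(pair, slice_width, dphi)
    sm <- slice_means(ss)
    c(r_bar = sm[["r_bar"]], h_bar = sm[["h_bar"]],
      V_cav = mesh_volume(pair$endo),
      V_myo = mesh_volume(pair$epi) - mesh_volume(pair$endo))
  })
  geo <- as.data.frame(do.call(rbind, geo))
  lap <- data.frame(t_ms = frames$t_ms, p_lv_kPa = frames$p_lv_kPa,
                    r_bar = geo$r_bar, h_bar = geo$h_bar,
                    R_bar = geo$r_bar + geo$h_bar,
                    V_cav_ml = geo$V_cav, V_myo_ml = geo$V_myo)
  lap$sigma_L_h <- sigma_thin(lap$p_lv_kPa, lap$r_bar, lap$h_bar)
  lap$sigma_L_H <- sigma_thick(lap$p_lv_kPa, lap$r_bar, lap$h_bar)
  lap$sigma_L_V <- sigma_volume(lap$p_lv_kPa, lap$V_cav_ml, lap$V_myo_ml)
  for (v in c("h", "H", "V")) {
    lap[[paste0("P_int_", v)]] <- laplace_power(
      lap$t_ms, lap[[paste0("sigma_L_", v)]], lap$r_bar, lap$R_bar,
      lap$V_myo_ml)
    lap[[paste0("W_int_", v)]] <- work_from_power(
      lap$t_ms, lap[[paste0("P_int_", v)]])
  }
  ev <- attr(trace, "events")
  t_phat <- ev[["t_phat"]]
  at_phat <- function(t, x) stats::approx(t, x, xout = t_phat, rule = 2)$y
  # ejection window for EHP
  ej <- c(ev[["t_0ej"]], ev[["t_ES"]])
  EHP <- ehp(trace$t_ms, trace$p_ao_kPa, trace$q_ml_per_ms, ej)
  sL <- lap[[paste0("sigma_L_", ihp_variant)]]
  T_sct <- lap$t_ms[which.max(sL)]         # ED onset is t = 0
  ih <- ihw_ihp(at_phat(lap$t_ms, lap$V_myo_ml), max(sL), T_sct)
  P_int_peak <- max(abs(truth$P_int_W))
  P_ext_peak <- max(abs(truth$P_ext_W))
  q_peak <- max(trace$q_ml_per_ms)
  p_peak <- max(trace$p_lv_kPa)
  summary <- list(
    P_int_peak_W = P_int_peak,
    P_int_at_phat_W = abs(at_phat(truth$t_ms, truth$P_int_W)),
    P_ext_peak_W = P_ext_peak,
    P_ext_at_phat_W = abs(at_phat(truth$t_ms, truth$P_ext_W)),
    p_peak_q_peak_W = p_peak * q_peak,
    P_int_h_at_phat_W = abs(at_phat(lap$t_ms, lap$P_int_h)),
    P_int_H_at_phat_W = abs(at_phat(lap$t_ms, lap$P_int_H)),
    P_int_V_at_phat_W = abs(at_phat(lap$t_ms, lap$P_int_V)),
    IHW_J = ih$IHW, IHP_W = ih$IHP, EHP_W = EHP,
    # clinical MAP * CO from the simulated trace: cycle-averaged aortic
    # power, smaller than the systole-averaged EHP by about T_sys / T
    EHP_map_co_W = mean(trace$p_ao_kPa) *
      (max(trace$V_cav_ml) - min(trace$V_cav_ml)) / cfg$period,
    P_eff = power_efficiency(EHP, P_int_peak),
    P_eff_clin = power_efficiency(EHP, ih$IHP),
    t_phat_ms = t_phat,
    t_power_peak_ms = truth$t_ms[which.max(abs(truth$P_int_W))],
    paper_convention = c(P_int_peak_W = -P_int_peak,
                         P_ext_peak_W = -P_ext_peak))
  res <- list(trace = trace, truth = truth, laplace = lap,
              summary = summary, events = ev)
  if (!is.null(out_dir)) {
    utils::write.csv(trace, file.path(out_dir, "cycle_series.csv"),
                     row.names = FALSE)
    utils::write.csv(lap, file.path(out_dir, "laplace_series.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary[names(summary) != "paper_convention"],
                         file.path(out_dir, "power_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(res, class = "cycle_comparison")
}
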