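#' Laplace wall-stress estimators
#'
#' The three clinically used Laplace estimates of circumferential (hoop) wall
#' stress in a pressurized spherical shell:
#'
#' * `sigma_thin`: thin-wall law `p r / (2 h)`;
#' * `sigma_thick`: thick-wall correction `p r / (2 h) / (1 + h / (2 r))`,
#'   algebraically equal to `p r^2 / ((r + h)^2 - r^2)`;
#' * `sigma_volume`: volume-based form
#'   `p / (((V_cav + V_myo) / V_cav)^(2/3) - 1)`, which coincides with
#'   `sigma_thick` on an exact sphere but differs on nonspherical inputs.
#'
#' All arguments are vectorized; geometry must be positive.
#'
#' @param p luminal pressure (kPa).
#' @param r mean inner radius (mm).
#' @param h mean wall width (mm).
#' @param V_cav cavity volume (ml).
#' @param V_myo wall (myocardial) volume (ml).
#' @return hoop stress estimate (kPa).
#' @examples
#' sigma_thin(4, 15, 0.5)    # 60 kPa
#' sigma_thick(4, 15, 15)    # 4/3 kPa
#' @name laplace_stress
NULL

#' @rdname laplace_stress
#' @export
sigma_thin <- function(p, r, h) {
  if (any(r <= 0) || any(h <= 0)) stop("nonpositive geometry")
  p * r / (2 * h)
}

#' @rdname laplace_stress
#' @export
sigma_thick <- function(p, r, h) {
  if (any(r <= 0) || any(h <= 0)) stop("nonpositive geometry")
  p * r / (2 * h) / (1 + h / (2 * r))
}

#' @rdname laplace_stress
#' @export
sigma_volume <- function(p, V_cav, V_myo) {
  if (any(V_cav <= 0) || any(V_myo <= 0)) stop("nonpositive volumes")
  p / (((V_cav + V_myo) / V_cav)^(2 / 3) - 1)
}

#' Central finite differences of a sampled trace
#'
#' Interior points use central differences, endpoints one-sided ones.
#'
#' @param t sample times (ms), strictly increasing.
#' @param x sampled values.
#' @return derivative dx/dt, same length.
#' @export
fd_derivative <- function(t, x) {
  n <- length(t)
  stopifnot(length(x) == n, n >= 2)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

#' Laplace-based internal power trace
#'
#' Estimates the internal mechanical power from a Laplace stress series and
#' the wall-motion bracket
#' `P_int,* (t) = V_myo(t) sigma_L,*(t) (r_dot/r0 + R_dot/R0)`,
#' where the bracket approximates the circumferential strain rate summed over
#' the two in-plane directions; `r0`, `R0` are the radii at the reference
#' (first) sample. Radii derivatives are computed by [fd_derivative()]. The
#' `half_bracket` flag replaces the sum by its mean for sensitivity analysis.
#'
#' @param t time (ms).
#' @param sigma Laplace stress trace (kPa), any of the three variants.
#' @param r,R inner/outer radius traces (mm).
#' @param V_myo wall volume (ml), scalar or trace.
#' @param r0,R0 reference radii (mm); default the first samples of `r`, `R`.
#' @param half_bracket if TRUE use the mean of the two rate terms.
#' @return power trace in W (positive while inflating, negative during
#'   ejection).
#' @export
laplace_power <- function(t, sigma, r, R, V_myo, r0 = r[1], R0 = R[1],
                          half_bracket = FALSE) {
  if (is.null(r0) || is.null(R0) || !is.finite(r0) || !is.finite(R0))
    stop("missing reference radii")
  br <- fd_derivative(t, r) / r0 + fd_derivative(t, R) / R0
  if (half_bracket) br <- br / 2
  V_myo * sigma * br * .W_per_kPa_ml_ms
}

#' Cumulative work from a power trace
#'
#' `W(t) = int_{t0}^{t} P dt`, cumulative trapezoid; `W(t0) = 0`.
#'
#' @param t time (ms).
#' @param P power trace (W).
#' @return work trace (J).
#' @export
work_from_power <- function(t, P) {
  stopifnot(length(t) == length(P))
  drop(pracma::cumtrapz(t, P)) * 1e-3      # W * ms -> J
}

#' Internal heart work and power (IHW / IHP)
#'
#' The relative indicators `IHW = V_myo * sigma_L` (J) and
#' `IHP = IHW / T_sct` (W), where `T_sct` is the systolic contraction time
#' from the onset of isovolumetric contraction to the instant of peak stress.
#'
#' @param V_myo wall volume (ml).
#' @param sigma Laplace stress (kPa), conventionally at its trace maximum.
#' @param T_sct contraction time (ms), positive.
#' @return list with `IHW` (J) and `IHP` (W).
#' @export
ihw_ihp <- function(V_myo, sigma, T_sct) {
  stopifnot(T_sct > 0)
  IHW <- V_myo * sigma * .J_per_kPa_ml
  list(IHW = IHW, IHP = IHW / (T_sct * 1e-3))
}

#' Hydrodynamic power trace
#'
#' `P_ext = p q = p dV_cav/dt`; zero during isovolumetric segments. The flow
#' is differentiated from the volume trace unless given.
#'
#' @param t time (ms).
#' @param p LV pressure (kPa).
#' @param V cavity volume trace (ml); ignored when `q` is supplied.
#' @param q optional flow `dV_cav/dt` (ml/ms).
#' @return power trace (W); negative during ejection (volume decreasing).
#' @export
hydrodynamic_power <- function(t, p, V = NULL, q = NULL) {
  if (is.null(q)) {
    if (is.null(V)) stop("either V or q must be supplied")
    if (length(V) != length(p)) stop("length mismatch")
    q <- fd_derivative(t, V)
  }
  if (length(q) != length(p)) stop("length mismatch")
  p * q * .W_per_kPa_ml_ms
}

#' External heart power (EHP)
#'
#' Time-averaged hydrodynamic power delivered to the aorta over systole:
#' `EHP = 1/T_sys int_{t_ED}^{t_ES} p_ao q dt`, approximated clinically by
#' `MAP * CO`.
#'
#' @param t time (ms).
#' @param p_ao aortic pressure (kPa).
#' @param q outflow (ml/ms, positive out of the LV).
#' @param window length-2 numeric, systolic window `(t_ED, t_ES)` in ms.
#' @return EHP in W.
#' @export
ehp <- function(t, p_ao, q, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  i <- t >= window[1] & t <= window[2]
  if (sum(i) < 2) stop("empty systolic window")
  pracma::trapz(t[i], p_ao[i] * q[i]) / (window[2] - window[1])
}

#' EHP from cuff pressures and cardiac output
#'
#' The clinical approximation `EHP ~ MAP * CO` with `MAP` in mmHg and `CO` in
#' ml/min, returned in W.
#'
#' @param MAP mean arterial pressure (mmHg).
#' @param CO cardiac output (ml/min).
#' @export
ehp_map_co <- function(MAP, CO) {
  mmHg_to_kPa(MAP) * (CO / 60000) * 1e3    # kPa * ml/ms -> W
}

#' Cardiac power efficiency
#'
#' `P_eff = EHP / |P_peak|` where `P_peak` is the peak internal (physical
#' mode) or the IHP indicator (clinical mode). Magnitudes are used so the
#' efficiency is positive regardless of the sign convention of the power
#' traces.
#'
#' @param EHP external heart power (W).
#' @param P_peak peak power or IHP (W), nonzero.
#' @return dimensionless efficiency.
#' @export
power_efficiency <- function(EHP, P_peak) {
  if (P_peak == 0) stop("zero denominator in power efficiency")
  abs(EHP) / abs(P_peak)
}

#' Mean arterial pressure from cuff pressures
#'
#' `MAP = p_dia + (p_sys - p_dia) / 3` (mmHg).
#'
#' @param p_dia,p_sys diastolic and systolic cuff pressures (mmHg).
#' @export
map_from_cuff <- function(p_dia, p_sys) p_dia + (p_sys - p_dia) / 3
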