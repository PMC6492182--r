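#' Unit conventions and conversions
#'
#' All internal computations use a consistent unit system: pressure and stress
#' in kPa, length in mm, time in ms, volume in ml. In this system
#' 1 kPa * ml / ms = 1 W and 1 kPa * ml = 1e-3 J, so power traces come out in
#' watts with a single scale factor. Clinical pressures in mmHg are converted
#' at the I/O boundary only.
#'
#' @param x numeric vector of pressures.
#' @return converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
mmHg_to_kPa <- function(x) x * 0.133322

#' @rdname units
#' @export
kPa_to_mmHg <- function(x) x / 0.133322

# kPa * mm^3 -> J
.J_per_kPa_mm3 <- 1e-6
# kPa * ml -> J
.J_per_kPa_ml <- 1e-3
# kPa * ml / ms -> W (exactly 1, kept for readability)
.W_per_kPa_ml_ms <- 1
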