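#' @keywords internal
"_PACKAGE"

#' Recognised incident polarization states
#'
#' Vertical (V), +45 degree linear (P), right circular (R), horizontal (H),
#' -45 degree linear (M) and left circular (L).
#'
#' @export
polarization_states <- c("V", "P", "R", "H", "M", "L")

stop_field <- function(field, msg) {
  stop(sprintf("%s: %s", field, msg), call. = FALSE)
}

check_scalar_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_field(field, "must be a single positive finite number")
  as.numeric(x)
}

check_scalar_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_field(field, "must be a single non-negative finite number")
  as.numeric(x)
}

#' Photoacoustic time series
#'
#' One sampled PA pressure trace with its acquisition metadata. Sample `i`
#' (1-based) is taken at time `time_offset + (i - 1) / sampling_rate` after
#' the laser trigger.
#'
#' @param samples numeric vector of pressure values (arbitrary units).
#' @param sampling_rate samples per second (positive).
#' @param time_offset delay from laser trigger to the first sample, seconds.
#' @param pulse_energy laser pulse energy in joules (positive).
#' @param wavelength optical wavelength in nanometres (positive).
#' @param polarization one of [polarization_states].
#' @param replicate_id free-form replicate label.
#' @param meta named list of additional annotations.
#'
#' @return An object of class `pa_timeseries`.
#' @export
pa_timeseries <- function(samples, sampling_rate, time_offset = 0,
                          pulse_energy = 1e-3, wavelength = 1560,
                          polarization = "V", replicate_id = "",
                          meta = list()) {
  if (length(samples) == 0L) stop_field("samples", "must be non-empty")
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples)))
    stop_field("samples", "must be finite numeric values")
  x <- structure(
    list(samples = as.numeric(samples),
         sampling_rate = check_scalar_positive(sampling_rate, "sampling_rate"),
         time_offset = check_scalar_nonneg(time_offset, "time_offset"),
         pulse_energy = check_scalar_positive(pulse_energy, "pulse_energy"),
         wavelength = check_scalar_positive(wavelength, "wavelength"),
         polarization = match.arg(polarization, polarization_states),
         replicate_id = as.character(replicate_id)[1L],
         meta = as.list(meta)),
    class = "pa_timeseries")
  x
}

#' Sample times of a PA trace
#'
#' @param x a [pa_timeseries].
#' @return numeric vector of times in seconds relative to the laser trigger.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "pa_timeseries"))
  x$time_offset + (seq_along(x$samples) - 1) / x$sampling_rate
}

#' @export
print.pa_timeseries <- function(x, ...) {
  cat(sprintf(
    "<pa_timeseries> %d samples @ %.3g S/s, %.4g ns window\n",
    length(x$samples), x$sampling_rate,
    1e9 * length(x$samples) / x$sampling_rate))
  cat(sprintf("  wavelength %g nm, polarization %s, pulse energy %.3g J\n",
              x$wavelength, x$polarization, x$pulse_energy))
  invisible(x)
}

#' Transducer impulse response
#'
#' @param samples numeric vector with non-zero L2 norm.
#' @param sampling_rate samples per second.
#' @param center_frequency centre frequency in Hz; must respect Nyquist.
#' @param fractional_bandwidth -6 dB fractional bandwidth, in (0, 2).
#'
#' @return An object of class `transducer_ir`.
#' @export
transducer_ir <- function(samples, sampling_rate, center_frequency,
                          fractional_bandwidth) {
  if (length(samples) == 0L) stop_field("samples", "must be non-empty")
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop_field("samples", "must be finite numeric values")
  if (sum(samples^2) <= 0)
    stop_field("samples", "impulse response must have non-zero L2 norm")
  sampling_rate <- check_scalar_positive(sampling_rate, "sampling_rate")
  center_frequency <- check_scalar_positive(center_frequency, "center_frequency")
  if (center_frequency >= sampling_rate / 2)
    stop_field("center_frequency",
               "must lie below the Nyquist frequency sampling_rate/2")
  if (!is.numeric(fractional_bandwidth) || length(fractional_bandwidth) != 1L ||
      fractional_bandwidth <= 0 || fractional_bandwidth >= 2)
    stop_field("fractional_bandwidth", "must lie in (0, 2)")
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         center_frequency = center_frequency,
         fractional_bandwidth = as.numeric(fractional_bandwidth)),
    class = "transducer_ir")
}

#' @export
print.transducer_ir <- function(x, ...) {
  cat(sprintf("<transducer_ir> %d taps, fc = %.3g MHz, %.0f%% bandwidth\n",
              length(x$samples), x$center_frequency / 1e6,
              100 * x$fractional_bandwidth))
  invisible(x)
}

#' Acquisition geometry
#'
#' Speed of sound, source-detector separation and the depth at which the
#' reference amplitude P0 is read.
#'
#' @param sos speed of sound in m/s.
#' @param known_path_length illumination-point to transducer distance, metres.
#' @param p0_depth depth of the P0 reference amplitude, metres.
#' @param sos_sweep length-2 numeric: the calibration sweep interval in m/s.
#' @param sos_step sweep step in m/s.
#'
#' @return An object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(sos = 1500, known_path_length = 0.04,
                                 p0_depth = 1.8e-5,
                                 sos_sweep = c(1400, 1550), sos_step = 5) {
  sos <- check_scalar_positive(sos, "sos")
  known_path_length <- check_scalar_positive(known_path_length,
                                             "known_path_length")
  p0_depth <- check_scalar_nonneg(p0_depth, "p0_depth")
  if (p0_depth >= known_path_length)
    stop_field("p0_depth", "must be smaller than known_path_length")
  if (length(sos_sweep) != 2L || any(sos_sweep <= 0) ||
      sos_sweep[1] >= sos_sweep[2])
    stop_field("sos_sweep", "must be an increasing pair of positive values")
  sos_step <- check_scalar_positive(sos_step, "sos_step")
  structure(
    list(sos = sos, known_path_length = known_path_length,
         p0_depth = p0_depth, sos_sweep = as.numeric(sos_sweep),
         sos_step = sos_step),
    class = "acquisition_geometry")
}

#' Fluence-depth profile
#'
#' Envelope amplitude against physical depth, the object the Malus-law
#' inversion reads its P and P0 amplitudes from.
#'
#' @param depth strictly increasing non-negative depths in metres.
#' @param amplitude non-negative envelope amplitudes (arbitrary units).
#' @param sos_used speed of sound used for the time-to-depth mapping, m/s.
#'
#' @return An object of class `fluence_depth_profile`.
#' @export
fluence_depth_profile <- function(depth, amplitude, sos_used) {
  depth <- as.numeric(depth); amplitude <- as.numeric(amplitude)
  if (length(depth) == 0L || length(depth) != length(amplitude))
    stop_field("depth", "depth and amplitude must be non-empty, equal length")
  if (any(depth < 0)) stop_field("depth", "must be non-negative")
  if (is.unsorted(depth, strictly = TRUE))
    stop_field("depth", "must be strictly increasing")
  if (any(amplitude < 0))
    stop_field("amplitude", "envelope amplitudes must be non-negative")
  structure(list(depth = depth, amplitude = amplitude,
                 sos_used = check_scalar_positive(sos_used, "sos_used")),
            class = "fluence_depth_profile")
}

#' Specific rotation parameters
#'
#' The intrinsic per-concentration, per-path-length rotation of a chiral
#' substance at a given wavelength and temperature.
#'
#' @param specific_rotation non-zero specific rotation, in units consistent
#'   with the concentration and path length it will be used with.
#' @param wavelength wavelength in nm.
#' @param temperature temperature in degrees Celsius.
#' @export
specific_rotation_params <- function(specific_rotation, wavelength = 1560,
                                     temperature = 25) {
  if (!is.numeric(specific_rotation) || length(specific_rotation) != 1L ||
      !is.finite(specific_rotation) || specific_rotation == 0)
    stop_field("specific_rotation", "must be a single non-zero finite number")
  structure(list(specific_rotation = as.numeric(specific_rotation),
                 wavelength = check_scalar_positive(wavelength, "wavelength"),
                 temperature = as.numeric(temperature)[1L]),
            class = "specific_rotation_params")
}

#' Simulator configuration
#'
#' Parameters of the one-dimensional ballistic forward model: the local PA
#' source amplitude at depth z is
#' `amplitude * exp(-mu_a * z) * cos(rotation_per_depth * z)^2`, where the
#' overall scale `amplitude` defaults to `grueneisen * mu_a * phi0` (pressure
#' proportional to the Grueneisen parameter, the absorption coefficient and
#' the surface fluence). Supplying `amplitude` explicitly decouples the
#' overall scale from `mu_a`, which permits attenuation-free studies
#' (`mu_a = 0`) with a non-zero signal.
#'
#' @param grueneisen dimensionless Grueneisen parameter (held constant).
#' @param mu_a absorption coefficient in 1/m.
#' @param phi0 surface fluence, arbitrary units.
#' @param rotation_per_depth optical rotation accrued per metre of path,
#'   rad/m (specific rotation times concentration in consistent units).
#' @param noise_sd standard deviation of additive Gaussian sample noise.
#' @param energy_jitter_cv coefficient of variation of the multiplicative
#'   pulse-energy jitter (truncated normal, truncated at +-3 CV).
#' @param seed integer seed fixing all stochastic draws, or `NULL`.
#' @param carrier_frequency acoustic carrier frequency in Hz imprinted on the
#'   simulated trace so that the fluence profile rides in the transducer band.
#' @param amplitude optional explicit overall scale overriding
#'   `grueneisen * mu_a * phi0`.
#' @param pulse_energy nominal pulse energy in joules.
#' @param wavelength optical wavelength in nm.
#' @param polarization incident polarization label.
#'
#' @return An object of class `simulator_config`.
#' @export
simulator_config <- function(grueneisen = 1, mu_a = 1000, phi0 = 1,
                             rotation_per_depth = 0, noise_sd = 0,
                             energy_jitter_cv = 0, seed = NULL,
                             carrier_frequency = 5e6, amplitude = NULL,
                             pulse_energy = 2.5e-3, wavelength = 1560,
                             polarization = "V") {
  cfg <- structure(
    list(grueneisen = check_scalar_positive(grueneisen, "grueneisen"),
         mu_a = check_scalar_nonneg(mu_a, "mu_a"),
         phi0 = check_scalar_positive(phi0, "phi0"),
         rotation_per_depth = as.numeric(rotation_per_depth)[1L],
         noise_sd = check_scalar_nonneg(noise_sd, "noise_sd"),
         energy_jitter_cv = check_scalar_nonneg(energy_jitter_cv,
                                                "energy_jitter_cv"),
         seed = if (!is.null(seed)) as.integer(seed),
         carrier_frequency = check_scalar_positive(carrier_frequency,
                                                   "carrier_frequency"),
         amplitude = if (!is.null(amplitude))
           check_scalar_positive(amplitude, "amplitude"),
         pulse_energy = check_scalar_positive(pulse_energy, "pulse_energy"),
         wavelength = check_scalar_positive(wavelength, "wavelength"),
         polarization = match.arg(polarization, polarization_states)),
    class = "simulator_config")
  cfg
}

fluence_scale <- function(config) {
  if (!is.null(config$amplitude)) config$amplitude
  else config$grueneisen * config$mu_a * config$phi0
}

#' Piecewise quadratic concentration model
#'
#' Two independent quadratics in the observed rotation, switched at the
#' rotation threshold `theta_T`:
#' `Cp = a1*theta^2 + b1*theta + k1` for `theta <= theta_T` and
#' `Cp = a2*theta^2 + b2*theta + k2` for `theta > theta_T`.
#'
#' @param a1,b1,k1 coefficients of the lower-rotation branch.
#' @param a2,b2,k2 coefficients of the upper-rotation branch.
#' @param theta_T rotation threshold in radians (positive).
#' @param units_out concentration unit label, `"mg/dl"` or `"mg/ml"`.
#' @return An object of class `piecewise_quad_model`.
#' @export
piecewise_quad_model <- function(a1, b1, k1, a2, b2, k2, theta_T,
                                 units_out = c("mg/dl", "mg/ml")) {
  co <- c(a1 = a1, b1 = b1, k1 = k1, a2 = a2, b2 = b2, k2 = k2)
  if (!is.numeric(co) || anyNA(co) || any(!is.finite(co)))
    stop_field("coefficients", "all six coefficients must be finite numbers")
  structure(list(a1 = as.numeric(a1), b1 = as.numeric(b1), k1 = as.numeric(k1),
                 a2 = as.numeric(a2), b2 = as.numeric(b2), k2 = as.numeric(k2),
                 theta_T = check_scalar_positive(theta_T, "theta_T"),
                 units_out = match.arg(units_out)),
            class = "piecewise_quad_model")
}

#' @export
print.piecewise_quad_model <- function(x, ...) {
  cat(sprintf("<piecewise_quad_model> theta_T = %.4g rad (%s)\n",
              x$theta_T, x$units_out))
  cat(sprintf("  theta <= theta_T: %.4g t^2 + %.4g t + %.4g\n",
              x$a1, x$b1, x$k1))
  cat(sprintf("  theta >  theta_T: %.4g t^2 + %.4g t + %.4g\n",
              x$a2, x$b2, x$k2))
  invisible(x)
}

#' Linear rotation-concentration model
#'
#' @param slope,intercept coefficients of `c = slope * theta + intercept`.
#' @param r_squared coefficient of determination of the fit, in `[0, 1]`.
#' @return An object of class `pa_linear_model`.
#' @export
pa_linear_model <- function(slope, intercept, r_squared = NA_real_) {
  if (!is.finite(slope) || !is.finite(intercept))
    stop_field("coefficients", "slope and intercept must be finite")
  if (!is.na(r_squared) && (r_squared < -1e-12 || r_squared > 1 + 1e-12))
    stop_field("r_squared", "must lie in [0, 1]")
  structure(list(slope = as.numeric(slope), intercept = as.numeric(intercept),
                 r_squared = as.numeric(r_squared)),
            class = "pa_linear_model")
}

#' @export
print.pa_linear_model <- function(x, ...) {
  cat(sprintf("<pa_linear_model> c = %.4g * theta + %.4g (R^2 = %.4g)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}
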