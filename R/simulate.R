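# Forward model: 1-D ballistic Beer-Lambert fluence decay with a Malus-law
# cos^2 rotation factor, mapped to acoustic arrival time, convolved with a
# band-limited transducer pulse, plus additive noise and pulse-energy jitter.

#' Ground truth for a simulated measurement
#'
#' Bundles a concentration with the analytic rotation and fluence curves the
#' simulator used, so parameter recovery can be scored exactly.
#'
#' @param concentration reference concentration (non-negative).
#' @param config a [simulator_config]; `rotation_per_depth` encodes
#'   specific rotation times concentration in rad/m.
#' @return An object of class `ground_truth` with functions `theta_at(l)`
#'   (radians at path length `l` metres) and `fluence_at(l)`.
#' @export
ground_truth <- function(concentration, config) {
  stopifnot(inherits(config, "simulator_config"))
  concentration <- check_scalar_nonneg(concentration, "concentration")
  rot <- config$rotation_per_depth
  mua <- config$mu_a
  scale <- fluence_scale(config)
  structure(
    list(concentration = concentration,
         theta_at = function(l) rot * l,
         fluence_at = function(l) scale * exp(-mua * l),
         config = config),
    class = "ground_truth")
}

#' Simulated noiseless PA source profile
#'
#' Evaluates `amplitude * exp(-mu_a * z) * cos(rotation_per_depth * z)^2`
#' on a depth grid, where `amplitude` defaults to
#' `grueneisen * mu_a * phi0` (see [simulator_config()]).
#'
#' @param config a [simulator_config].
#' @param depth_grid increasing non-negative depths in metres.
#' @return Numeric vector of non-negative source amplitudes.
#' @export
simulate_fluence <- function(config, depth_grid) {
  stopifnot(inherits(config, "simulator_config"))
  depth_grid <- as.numeric(depth_grid)
  if (any(depth_grid < 0)) stop("depth grid must be non-negative",
                                call. = FALSE)
  if (length(depth_grid) > 1L && is.unsorted(depth_grid))
    stop("depth grid must be increasing", call. = FALSE)
  fluence_scale(config) * exp(-config$mu_a * depth_grid) *
    cos(config$rotation_per_depth * depth_grid)^2
}

#' Gaussian-modulated transducer impulse response
#'
#' A Gaussian-envelope sinusoid whose -6 dB spectral width divided by the
#' centre frequency equals the requested fractional bandwidth. Truncated
#' where the envelope falls below `trunc_db`, and normalized to unit L2 norm.
#'
#' @param center_frequency centre frequency in Hz.
#' @param fractional_bandwidth -6 dB fractional bandwidth (e.g. 0.6).
#' @param sampling_rate samples per second; must exceed twice the centre
#'   frequency.
#' @param trunc_db envelope truncation level in dB below peak.
#' @return A [transducer_ir] with an odd number of taps, centred at the
#'   middle tap.
#' @export
make_transducer_ir <- function(center_frequency = 7.5e6,
                               fractional_bandwidth = 0.6,
                               sampling_rate = 1e9, trunc_db = 60) {
  if (center_frequency >= sampling_rate / 2)
    stop("center_frequency must be below the Nyquist frequency",
         call. = FALSE)
  # envelope exp(-a t^2); -6 dB amplitude points at +- bw * fc / 2
  a <- (pi * center_frequency * fractional_bandwidth / 2)^2 /
    log(10^(6 / 20))
  t_cut <- sqrt(trunc_db / 20 * log(10) / a)
  m <- ceiling(t_cut * sampling_rate)
  t <- (-m:m) / sampling_rate
  h <- exp(-a * t^2) * cos(2 * pi * center_frequency * t)
  h <- h / sqrt(sum(h^2))
  transducer_ir(h, sampling_rate, center_frequency, fractional_bandwidth)
}

#' Simulate one PA time series
#'
#' The source profile of `truth` is evaluated at depths
#' `geometry$sos * (time_offset + i / sampling_rate)`, multiplied by a
#' sinusoidal acoustic carrier (see [simulator_config()]), convolved with the
#' transducer impulse response under mirror boundary conditions, then
#' degraded by additive Gaussian noise (`noise_sd`) and multiplicative
#' pulse-energy jitter (`energy_jitter_cv`). The jitter factor scales both
#' the trace and the recorded `pulse_energy`, so energy normalization can
#' undo it. The same seed always yields the identical trace.
#'
#' @param truth a [ground_truth].
#' @param geometry an [acquisition_geometry].
#' @param ir a [transducer_ir] at the same sampling rate.
#' @param sampling_rate samples per second.
#' @param n_samples number of samples in the trace.
#' @param time_offset trigger-to-first-sample delay in seconds.
#' @param seed integer seed overriding `truth$config$seed`, or `NULL`.
#' @return A [pa_timeseries]; the noiseless trace is stored in
#'   `meta$clean_rms` as its root-mean-square for SNR accounting.
#' @export
simulate_pa_signal <- function(truth, geometry, ir,
                               sampling_rate = 1e9, n_samples = 2048,
                               time_offset = 0, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(geometry, "acquisition_geometry"),
            inherits(ir, "transducer_ir"))
  if (!isTRUE(all.equal(ir$sampling_rate, sampling_rate)))
    stop("impulse response and trace sampling rates differ", call. = FALSE)
  cfg <- truth$config
  if (is.null(seed)) seed <- cfg$seed
  tm <- time_offset + (seq_len(n_samples) - 1) / sampling_rate
  z <- geometry$sos * tm
  if (max(z) < geometry$p0_depth)
    stop(sprintf(paste0("n_samples = %d spans only %.3g m of depth, too ",
                        "small to contain the mapped profile (p0_depth = ",
                        "%.3g m)"), n_samples, max(z), geometry$p0_depth),
         call. = FALSE)
  profile <- simulate_fluence(cfg, z)
  x <- profile * cos(2 * pi * cfg$carrier_frequency * tm)
  clean <- conv_same_mirror(x, ir$samples)
  with_seed(seed, {
    noise <- if (cfg$noise_sd > 0) stats::rnorm(n_samples, 0, cfg$noise_sd)
             else numeric(n_samples)
    jit <- 1
    if (cfg$energy_jitter_cv > 0) {
      repeat {  # truncated normal, +-3 CV, keeps the factor positive
        jit <- 1 + stats::rnorm(1, 0, cfg$energy_jitter_cv)
        if (abs(jit - 1) <= 3 * cfg$energy_jitter_cv && jit > 0) break
      }
    }
    pa_timeseries(samples = (clean + noise) * jit,
                  sampling_rate = sampling_rate,
                  time_offset = time_offset,
                  pulse_energy = cfg$pulse_energy * jit,
                  wavelength = cfg$wavelength,
                  polarization = cfg$polarization,
                  meta = list(clean_rms = rms(clean),
                              nominal_energy = cfg$pulse_energy))
  })
}

#' Noise level for a target signal-to-noise ratio
#'
#' `SNR = 20 log10(rms_signal / rms_noise)`.
#'
#' @param clean_rms root-mean-square of the noiseless trace.
#' @param snr_db target SNR in dB.
#' @return The Gaussian noise standard deviation attaining the target.
#' @export
noise_sd_for_snr <- function(clean_rms, snr_db) {
  check_scalar_nonneg(clean_rms, "clean_rms") / 10^(snr_db / 20)
}

#' Simulate a calibration dataset
#'
#' Generates `length(concentrations) * replicates` traces. The rotation rate
#' scales linearly with concentration: `rotation_per_depth =
#' rotation_coeff * concentration`. Per-replicate seeds are derived
#' deterministically from the master seed, so any record can be regenerated
#' in isolation.
#'
#' @param concentrations non-negative reference concentrations (mg/dl).
#' @param replicates replicates per concentration (>= 1).
#' @param base_config a [simulator_config]; its `rotation_per_depth` is
#'   overwritten per record.
#' @param geometry an [acquisition_geometry].
#' @param ir a [transducer_ir]; default matches the 7.5 MHz, 60% bandwidth
#'   detector.
#' @param rotation_coeff rad per metre of path per unit concentration;
#'   the default 1.75 maps 90--400 mg/dl onto roughly 0.3--1.4 rad at a 2 mm
#'   path, inside the invertible Malus branch.
#' @param target_snr_db if non-`NULL`, sets the per-trace noise level so the
#'   realized SNR equals this value.
#' @param sampling_rate,n_samples,time_offset trace layout; see
#'   [simulate_pa_signal()].
#' @param seed master seed.
#' @return A list of records, each `list(signal = <pa_timeseries>,
#'   truth = <ground_truth>)`.
#' @export
simulate_dataset <- function(concentrations, replicates = 3,
                             base_config = simulator_config(),
                             geometry = acquisition_geometry(sos = 1420),
                             ir = make_transducer_ir(sampling_rate =
                                                       sampling_rate),
                             rotation_coeff = 1.75,
                             target_snr_db = NULL,
                             sampling_rate = 1e9, n_samples = 2048,
                             time_offset = 0, seed = 1L) {
  if (length(concentrations) == 0L)
    stop("concentration list must be non-empty", call. = FALSE)
  if (any(concentrations < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  out <- vector("list", length(concentrations) * replicates)
  idx <- 0L
  for (ci in seq_along(concentrations)) {
    conc <- concentrations[ci]
    for (ri in seq_len(replicates)) {
      idx <- idx + 1L
      cfg <- base_config
      cfg$rotation_per_depth <- rotation_coeff * conc
      cfg$seed <- derive_seed(seed, idx)
      if (!is.null(target_snr_db)) {
        # one noiseless pass to size the noise for the requested SNR
        cfg0 <- cfg; cfg0$noise_sd <- 0; cfg0$energy_jitter_cv <- 0
        clean <- simulate_pa_signal(ground_truth(conc, cfg0), geometry, ir,
                                    sampling_rate, n_samples, time_offset)
        cfg$noise_sd <- noise_sd_for_snr(clean$meta$clean_rms, target_snr_db)
      }
      truth <- ground_truth(conc, cfg)
      sig <- simulate_pa_signal(truth, geometry, ir, sampling_rate,
                                n_samples, time_offset)
      sig$replicate_id <- sprintf("c%03d_r%02d", ci, ri)
      out[[idx]] <- list(signal = sig, truth = truth)
    }
  }
  out
}
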