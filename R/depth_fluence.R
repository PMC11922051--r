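# From filtered trace to fluence-depth profile: transducer deconvolution,
# analytic-signal envelope, speed-of-sound calibration, time-to-depth mapping.

#' Wiener deconvolution of the transducer response
#'
#' Frequency-domain deconvolution of the centred transducer kernel. With
#' `nsr > 0` the classical Wiener regularization
#' `conj(H) / (|H|^2 + nsr * max|H|^2)` is used; with `nsr = 0` a
#' pseudo-inverse is applied instead, inverting exactly wherever the kernel
#' magnitude exceeds 1e-3 of its peak (-60 dB) and zeroing the rest, so a
#' noiseless forward convolution is undone without amplifying numerically
#' empty bands. The trace is mirror-padded and the outer half of the padding
#' is Hann-tapered before the FFT so that window truncation does not leak
#' into the inversion.
#'
#' @param x a [pa_timeseries].
#' @param ir a [transducer_ir] at the same sampling rate, taken as centred
#'   on its middle tap.
#' @param nsr noise-to-signal power ratio (non-negative; default `1e-3`).
#' @return The deconvolved [pa_timeseries], same length as the input.
#' @export
deconvolve <- function(x, ir, nsr = 1e-3) {
  stopifnot(inherits(x, "pa_timeseries"), inherits(ir, "transducer_ir"))
  if (!isTRUE(all.equal(x$sampling_rate, ir$sampling_rate)))
    stop("signal and impulse response sampling rates differ", call. = FALSE)
  nsr <- check_scalar_nonneg(nsr, "nsr")
  h <- ir$samples
  n <- length(x$samples)
  m <- (length(h) - 1L) %/% 2L
  mp <- mirror_pad(x$samples, 2L * length(h))
  yp <- mp$x
  np <- length(yp)
  tw <- mp$pad %/% 2L
  if (tw > 0L) {
    w <- 0.5 * (1 - cos(pi * seq_len(tw) / tw))
    yp[seq_len(tw)] <- yp[seq_len(tw)] * w
    yp[(np - tw + 1L):np] <- yp[(np - tw + 1L):np] * rev(w)
  }
  N <- stats::nextn(np + length(h), c(2, 3))
  Hf <- stats::fft(c(h, numeric(N - length(h))))
  Hf <- Hf * exp(2i * pi * (0:(N - 1)) * m / N)  # undo kernel delay
  Yf <- stats::fft(c(yp, numeric(N - np)))
  Hmax2 <- max(Mod(Hf))^2
  G <- if (nsr > 0) {
    Conj(Hf) / (Mod(Hf)^2 + nsr * Hmax2)
  } else {
    out <- complex(length.out = N)
    keep <- Mod(Hf)^2 >= 1e-6 * Hmax2
    out[keep] <- 1 / Hf[keep]
    out
  }
  xh <- Re(stats::fft(Yf * G, inverse = TRUE)) / N
  x$samples <- xh[(mp$pad + 1L):(mp$pad + n)]
  x
}

#' Analytic-signal envelope
#'
#' Magnitude of the analytic signal (FFT Hilbert transform), computed under
#' mirror boundary conditions. The result is non-negative and bounds the
#' absolute trace pointwise, turning the bipolar deconvolved trace into the
#' non-negative light-attenuation profile that amplitudes are read from.
#'
#' @param x a [pa_timeseries].
#' @return A [pa_timeseries] holding the envelope.
#' @export
envelope <- function(x) {
  stopifnot(inherits(x, "pa_timeseries"))
  x$samples <- analytic_envelope(x$samples)
  x
}

#' Calibrate the speed of sound against a known path length
#'
#' Sweeps candidate speed-of-sound values over `geometry$sos_sweep` (default
#' 1400--1550 m/s in 5 m/s steps) and returns the value whose product with
#' the landmark arrival time best matches `geometry$known_path_length`.
#' Ties break toward the lower speed.
#'
#' @param x a [pa_timeseries] containing the landmark.
#' @param geometry an [acquisition_geometry].
#' @param landmark `"peak"` (envelope maximum, default) or `"onset"` (first
#'   crossing of 10% of the envelope peak).
#' @param noise_floor envelope level the landmark must exceed.
#' @return The calibrated speed of sound in m/s.
#' @export
calibrate_sos <- function(x, geometry, landmark = c("peak", "onset"),
                          noise_floor = 0) {
  stopifnot(inherits(x, "pa_timeseries"),
            inherits(geometry, "acquisition_geometry"))
  landmark <- match.arg(landmark)
  env <- analytic_envelope(x$samples)
  pk <- max(env)
  if (pk <= noise_floor || pk <= 0)
    stop("no signal: envelope peak does not exceed the noise floor",
         call. = FALSE)
  i <- if (landmark == "peak") which.max(env)
       else which(env >= 0.1 * pk)[1L]
  t_land <- x$time_offset + (i - 1) / x$sampling_rate
  v <- seq(geometry$sos_sweep[1], geometry$sos_sweep[2],
           by = geometry$sos_step)
  v[which.min(abs(v * t_land - geometry$known_path_length))]
}

#' Map a trace to a fluence-depth profile
#'
#' Converts sample times to depth via
#' `depth_i = sos * (time_offset + (i - 1) / sampling_rate - illumination_time)`.
#'
#' @param x a [pa_timeseries]; expected to be an envelope (non-negative).
#'   Small numerically negative values are clamped to zero.
#' @param sos speed of sound in m/s.
#' @param illumination_time time of the illumination instant relative to the
#'   trigger, seconds (default 0).
#' @return A [fluence_depth_profile].
#' @export
to_depth_profile <- function(x, sos, illumination_time = 0) {
  stopifnot(inherits(x, "pa_timeseries"))
  sos <- check_scalar_positive(sos, "sos")
  depth <- sos * (signal_times(x) - illumination_time)
  if (depth[1] < 0)
    stop("mapping yields negative depths; adjust time_offset or ",
         "illumination_time so the window starts at or after illumination",
         call. = FALSE)
  amp <- x$samples
  tol <- 1e-9 * max(abs(amp), 1e-300)
  if (any(amp < -tol))
    stop("trace has substantially negative samples; apply envelope() first",
         call. = FALSE)
  fluence_depth_profile(depth, pmax(amp, 0), sos_used = sos)
}
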