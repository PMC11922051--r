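# Shared fixtures, built in code.

default_ir <- function(fs = 1e9) {
  make_transducer_ir(7.5e6, 0.6, sampling_rate = fs)
}

tone_signal <- function(freq, fs = 1e9, n = 20000, amplitude = 1, ...) {
  t <- (0:(n - 1)) / fs
  pa_timeseries(amplitude * sin(2 * pi * freq * t), sampling_rate = fs, ...)
}

# Trace whose envelope peaks at the arrival time of a landmark placed
# `distance` metres away at the true speed of sound.
landmark_trace <- function(distance, true_sos, fs = 1e8, n = 4000) {
  t_arr <- distance / true_sos
  t <- (0:(n - 1)) / fs
  pulse <- exp(-((t - t_arr) / 2e-7)^2) * cos(2 * pi * 7.5e6 * (t - t_arr))
  pa_timeseries(pulse, sampling_rate = fs)
}

# Amplitude of a tone in a trace, measured from the FFT bin nearest `freq`.
fft_tone_amplitude <- function(samples, fs, freq) {
  n <- length(samples)
  sp <- Mod(stats::fft(samples)) / n * 2
  bin <- round(freq * n / fs) + 1
  max(sp[max(2, bin - 1):min(n %/% 2, bin + 1)])
}
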