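# Shared DSP primitives.
#
# All stages treat the acquisition window with mirror (even-reflection)
# boundary conditions: the trace is extended symmetrically about its first
# and last sample before any FFT or IIR pass, and the extension is cropped
# afterwards. This keeps filtering, convolution, deconvolution and the
# analytic-signal envelope consistent near the window edges, where the P0
# reference amplitude is read.

mirror_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad <= 0L) return(list(x = x, pad = 0L))
  list(x = c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)]), pad = pad)
}

# Linear convolution with a centred kernel under mirror boundary conditions;
# output has the length and alignment of x.
conv_same_mirror <- function(x, h) {
  m <- (length(h) - 1L) %/% 2L
  mp <- mirror_pad(x, 2L * length(h))
  y <- stats::convolve(mp$x, rev(h), type = "open")
  y[(mp$pad + m + 1L):(mp$pad + m + length(x))]
}

# Magnitude of the analytic signal (FFT Hilbert transform), mirror-padded.
analytic_envelope <- function(x) {
  mp <- mirror_pad(x, min(length(x) - 1L, 4096L))
  xp <- mp$x
  N <- length(xp)
  X <- stats::fft(xp)
  w <- numeric(N)
  if (N %% 2L == 0L) {
    w[1L] <- 1; w[N / 2L + 1L] <- 1; w[2L:(N / 2L)] <- 2
  } else {
    w[1L] <- 1; if (N > 1L) w[2L:((N + 1L) / 2L)] <- 2
  }
  env <- Mod(stats::fft(X * w, inverse = TRUE) / N)
  env[(mp$pad + 1L):(mp$pad + length(x))]
}

rms <- function(x) sqrt(mean(x^2))

# Deterministic per-record seed derivation (Lehmer-style, exact in doubles).
derive_seed <- function(master, index) {
  m <- 2147483647
  as.integer((((as.numeric(master) %% m) * 48271) + as.numeric(index)) %% m)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
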