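test_that("simulate_fluence matches its closed form", {
  z <- seq(0, 0.01, length.out = 101)
  # no absorber, no rotation: tau * mu_a * phi0 = 0 at all depths
  cfg0 <- simulator_config(mu_a = 0, rotation_per_depth = 0)
  expect_equal(simulate_fluence(cfg0, z), rep(0, length(z)))

  # pure Beer-Lambert: ratio p(z)/p(0) = exp(-mu_a z)
  cfg <- simulator_config(mu_a = 100, rotation_per_depth = 0)
  p <- simulate_fluence(cfg, c(0, 0.01))
  expect_equal(p[2] / p[1], exp(-1), tolerance = 1e-12)

  # pure Malus: theta(z) = pi/3 gives cos^2(60 deg) = 1/4
  zs <- 0.002
  cfgm <- simulator_config(mu_a = 0, amplitude = 1,
                           rotation_per_depth = (pi / 3) / zs)
  pm <- simulate_fluence(cfgm, c(0, zs))
  expect_equal(pm[2] / pm[1], 0.25, tolerance = 1e-12)

  expect_error(simulate_fluence(cfg, c(-1e-3, 0)), "non-negative")
  expect_error(simulate_fluence(cfg, c(0.01, 0.001)), "increasing")
})

test_that("fluence profile is non-increasing while rotation stays below pi/2", {
  z <- seq(0, 2e-3, length.out = 400)
  for (mua in c(0, 200, 1500)) for (rot in c(0, 300, pi / 2 / 2e-3)) {
    cfg <- simulator_config(mu_a = mua, amplitude = 1,
                            rotation_per_depth = rot)
    p <- simulate_fluence(cfg, z)
    expect_true(all(diff(p) <= 1e-12),
                label = sprintf("monotone for mu_a=%g rot=%g", mua, rot))
  }
})

test_that("make_transducer_ir hits the requested spectral shape", {
  ir <- make_transducer_ir(7.5e6, 0.6, 1e9)
  expect_equal(sum(ir$samples^2), 1, tolerance = 1e-12)

  N <- 2^18
  H <- Mod(stats::fft(c(ir$samples, numeric(N - length(ir$samples)))))
  H <- H[1:(N / 2)]
  f <- (0:(N / 2 - 1)) * 1e9 / N
  pk <- which.max(H)
  expect_lt(abs(f[pk] - 7.5e6), 1e9 / N + 1)  # peak within one FFT bin
  inband <- range(f[H >= max(H) * 10^(-6 / 20)])
  frac <- diff(inband) / f[pk]
  expect_lt(abs(frac - 0.6) / 0.6, 0.02)      # -6 dB width within 2%

  expect_error(make_transducer_ir(7.5e8, 0.6, 1e9), "Nyquist")
})

test_that("simulate_pa_signal is seed-deterministic and noise-honest", {
  geom <- acquisition_geometry(sos = 1420)
  ir <- default_ir()
  cfg <- simulator_config(mu_a = 500, noise_sd = 0.05,
                          energy_jitter_cv = 0.02,
                          rotation_per_depth = 300)
  gt <- ground_truth(200, cfg)
  a <- simulate_pa_signal(gt, geom, ir, n_samples = 1024, seed = 99)
  b <- simulate_pa_signal(gt, geom, ir, n_samples = 1024, seed = 99)
  expect_identical(a$samples, b$samples)
  expect_identical(a$pulse_energy, b$pulse_energy)

  # noiseless, jitter-free trace equals the deterministic part
  cfg0 <- simulator_config(mu_a = 500, rotation_per_depth = 300)
  gt0 <- ground_truth(200, cfg0)
  c1 <- simulate_pa_signal(gt0, geom, ir, n_samples = 1024, seed = 1)
  c2 <- simulate_pa_signal(gt0, geom, ir, n_samples = 1024, seed = 2)
  expect_identical(c1$samples, c2$samples)
  expect_equal(c1$pulse_energy, cfg0$pulse_energy)

  expect_error(simulate_pa_signal(gt, geom, ir, n_samples = 5),
               "too\\s+small")
})

test_that("realized SNR tracks the requested level", {
  geom <- acquisition_geometry(sos = 1420)
  ir <- default_ir()
  cfg0 <- simulator_config(mu_a = 0, amplitude = 1, rotation_per_depth = 350)
  gt0 <- ground_truth(200, cfg0)
  clean <- simulate_pa_signal(gt0, geom, ir, n_samples = 1024)
  sdn <- noise_sd_for_snr(clean$meta$clean_rms, 20)
  cfg <- cfg0; cfg$noise_sd <- sdn
  gt <- ground_truth(200, cfg)
  snr <- vapply(1:100, function(s) {
    y <- simulate_pa_signal(gt, geom, ir, n_samples = 1024, seed = s)
    noise <- y$samples - clean$samples
    20 * log10(sqrt(mean(clean$samples^2)) / sqrt(mean(noise^2)))
  }, numeric(1))
  expect_lt(abs(mean(snr) - 20), 2)
})

test_that("simulate_dataset obeys the study design", {
  concs <- round(seq(90, 400, length.out = 10))
  ds <- simulate_dataset(concs, replicates = 3, sampling_rate = 1e8,
                         n_samples = 512,
                         ir = default_ir(1e8), seed = 5)
  expect_length(ds, 30)
  one <- simulate_dataset(100, replicates = 1, sampling_rate = 1e8,
                          n_samples = 512, ir = default_ir(1e8), seed = 5)
  expect_length(one, 1)
  expect_error(simulate_dataset(numeric(0)), "non-empty")

  # linearity: doubling concentration doubles theta at fixed depth
  two <- simulate_dataset(c(100, 200), replicates = 1, sampling_rate = 1e8,
                          n_samples = 512, ir = default_ir(1e8), seed = 5)
  l <- 1.5e-3
  expect_equal(two[[2]]$truth$theta_at(l), 2 * two[[1]]$truth$theta_at(l),
               tolerance = 1e-12)

  # reproducibility from the master seed
  ds2 <- simulate_dataset(concs, replicates = 3, sampling_rate = 1e8,
                          n_samples = 512, ir = default_ir(1e8), seed = 5)
  expect_identical(ds[[17]]$signal$samples, ds2[[17]]$signal$samples)
})
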