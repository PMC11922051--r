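test_that("pa_timeseries enforces its invariants", {
  expect_error(pa_timeseries(numeric(0), 1e9), "samples")
  expect_error(pa_timeseries(1:5, sampling_rate = 0), "sampling_rate")
  expect_error(pa_timeseries(1:5, 1e9, pulse_energy = -1), "pulse_energy")
  expect_error(pa_timeseries(1:5, 1e9, polarization = "X"))
  expect_error(pa_timeseries(c(1, NA, 2), 1e9), "finite")

  x <- pa_timeseries(rep(0.5, 1400), sampling_rate = 1e9, polarization = "R")
  expect_s3_class(x, "pa_timeseries")
  expect_length(signal_times(x), 1400)
  expect_equal(signal_times(x)[2] - signal_times(x)[1], 1e-9)
})

test_that("other constructors validate their fields", {
  expect_error(transducer_ir(numeric(0), 1e9, 7.5e6, 0.6), "non-empty")
  expect_error(transducer_ir(rep(0, 8), 1e9, 7.5e6, 0.6), "L2 norm")
  expect_error(transducer_ir(rnorm(8), 1e9, 6e8, 0.6), "Nyquist")
  expect_error(transducer_ir(rnorm(8), 1e9, 7.5e6, 2.5),
               "fractional_bandwidth")
  expect_error(acquisition_geometry(p0_depth = 0.05,
                                    known_path_length = 0.04), "p0_depth")
  expect_error(fluence_depth_profile(c(0, 1e-3, 1e-3), rep(1, 3), 1500),
               "strictly increasing")
  expect_error(fluence_depth_profile(c(0, 1e-3), c(1, -1), 1500),
               "non-negative")
  expect_error(specific_rotation_params(0), "specific_rotation")
  expect_error(piecewise_quad_model(1, 1, 1, 1, 1, Inf, 0.9),
               "coefficients")
  expect_error(pa_linear_model(1, 1, r_squared = 1.5), "r_squared")
})

test_that("delimited signals round-trip a 1 GS/s 1400-sample trace", {
  set.seed(11)
  x <- pa_timeseries(rnorm(1400), sampling_rate = 1e9, time_offset = 2e-8,
                     pulse_energy = 2.5e-3, wavelength = 1560,
                     polarization = "V", replicate_id = "day1_r3")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signal(x, path, format = "delimited", digits = 12)
  y <- read_signal(path, format = "delimited")
  expect_length(y$samples, 1400)
  expect_equal(y$sampling_rate, 1e9)
  expect_equal(y$samples, x$samples, tolerance = 1e-11)
  expect_equal(y$pulse_energy, 2.5e-3)
  expect_identical(y$polarization, "V")
  expect_identical(y$replicate_id, "day1_r3")
})

test_that("container signals round-trip bit-exactly", {
  set.seed(12)
  x <- pa_timeseries(rnorm(257), sampling_rate = 1e9, pulse_energy = 1.18e-3,
                     wavelength = 1500, polarization = "P")
  path <- withr::local_tempfile(fileext = ".json")
  write_signal(x, path, format = "container")
  y <- read_signal(path, format = "container")
  expect_identical(y$samples, x$samples)
  expect_identical(y$pulse_energy, x$pulse_energy)
  expect_identical(y$wavelength, x$wavelength)
  expect_identical(y$polarization, x$polarization)
})

test_that("readers reject structurally invalid inputs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  # missing pulse_energy header
  writeLines(c("# sampling_rate: 1e9", "# time_offset: 0",
               "# wavelength: 1560", "# polarization: V",
               "0\t1.0", "1e-9\t2.0"), path)
  expect_error(read_signal(path, "delimited"), "pulse_energy")
  # non-numeric samples
  writeLines(c("# sampling_rate: 1e9", "# time_offset: 0",
               "# pulse_energy: 1e-3", "# wavelength: 1560",
               "# polarization: V", "# replicate_id: a",
               "0\tok", "1e-9\t2.0"), path)
  expect_error(read_signal(path, "delimited"), "non-numeric")
  # zero samples
  writeLines(c("# sampling_rate: 1e9", "# time_offset: 0",
               "# pulse_energy: 1e-3", "# wavelength: 1560",
               "# polarization: V"), path)
  expect_error(read_signal(path, "delimited"), "no samples")
  expect_error(read_signal("/nonexistent/file.tsv", "delimited"),
               "not found")
})

test_that("models round-trip field-for-field and reject malformed files", {
  m <- piecewise_quad_model(a1 = -12.5, b1 = 310.2, k1 = 4.75,
                            a2 = 8.1, b2 = 205.0, k2 = -31.9,
                            theta_T = 0.88)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(unclass(m2), unclass(m))

  lin <- pa_linear_model(slope = 0, intercept = 5, r_squared = 0)
  write_model(lin, path)
  expect_identical(unclass(read_model(path)), unclass(lin))

  # truncated JSON
  txt <- readLines(path)
  writeLines(substr(paste(txt, collapse = ""), 1, 20), path)
  expect_error(read_model(path), "parse|malformed")
  # valid JSON but missing a key
  jsonlite::write_json(list(model = "linear", slope = 1), path,
                       auto_unbox = TRUE)
  expect_error(read_model(path), "intercept")
  jsonlite::write_json(list(model = "cubic"), path, auto_unbox = TRUE)
  expect_error(read_model(path), "unknown model")
})
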