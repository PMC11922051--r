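test_that("specific-rotation inversion follows c = theta / ([theta] l)", {
  p <- specific_rotation_params(2)
  expect_equal(concentration_from_specific_rotation(0, p, 0.5), 0)
  expect_equal(concentration_from_specific_rotation(1, p, 0.5), 1)
  c1 <- concentration_from_specific_rotation(0.3, p, 1)
  c2 <- concentration_from_specific_rotation(0.3, p, 2)
  expect_equal(c1, 2 * c2)
})

test_that("remove_outliers drops planted outliers and respects the cap", {
  th <- seq(0.1, 1.4, length.out = 20)
  cc <- 50 * th^2 + 200 * th + 10
  clean <- remove_outliers(th, cc)
  expect_length(clean$removed, 0)

  gross <- cc; gross[7] <- gross[7] + 500
  one <- remove_outliers(th, gross)
  expect_identical(one$removed, 7L)

  th40 <- seq(0.1, 1.4, length.out = 40)
  cc40 <- 50 * th40^2 + 200 * th40 + 10
  planted <- c(4L, 12L, 21L, 29L, 37L)
  many <- cc40; many[planted] <- many[planted] + c(500, 700, 900, 1100, 1300)
  capped <- remove_outliers(th40, many, max_removed = 3)
  expect_length(capped$removed, 3)
  expect_true(all(capped$removed %in% planted))

  expect_error(remove_outliers(th[1:5], cc[1:5]), "at least 6")
})

test_that("piecewise quadratic fit recovers planted coefficients exactly", {
  true <- list(a1 = -40, b1 = 290, k1 = 12, a2 = 55, b2 = 160, k2 = -20)
  tT <- 0.88
  th <- seq(0.05, 1.45, length.out = 40)
  cc <- ifelse(th <= tT,
               true$a1 * th^2 + true$b1 * th + true$k1,
               true$a2 * th^2 + true$b2 * th + true$k2)
  m <- fit_piecewise_quadratic(th, cc, theta_T = tT)
  for (f in names(true)) expect_lt(abs(m[[f]] - true[[f]]), 1e-8)

  # predictions reproduce the training data
  expect_lt(max(abs(predict_concentration(m, th) - cc)), 1e-6)

  # all-zero concentrations give all-zero coefficients
  z <- fit_piecewise_quadratic(th, numeric(40), theta_T = tT)
  for (f in c("a1", "b1", "k1", "a2", "b2", "k2"))
    expect_lt(abs(z[[f]]), 1e-10)

  expect_error(fit_piecewise_quadratic(th, cc, theta_T = 1.44),
               "theta > ")
  expect_error(fit_piecewise_quadratic(th, cc, theta_T = 0.01),
               "theta <= ")
})

test_that("automatic threshold search lands on the true changepoint", {
  th <- seq(0.1, 1.5, length.out = 30)
  tT <- th[16]   # changepoint on the observed grid
  cc <- ifelse(th <= tT, 100 * th + 5, 80 * th^2 - 30 * th + 260)
  m <- fit_piecewise_quadratic(th, cc, theta_T = "auto")
  expect_lte(abs(m$theta_T - tT), diff(th)[1] + 1e-12)
})

test_that("per-polarization threshold defaults are available", {
  expect_equal(default_theta_threshold("V", "serum"), 0.88)
  expect_equal(default_theta_threshold("P", "serum"), 0.98)
  expect_equal(default_theta_threshold("R", "serum"), 0.822)
  expect_equal(default_theta_threshold("P", "aqueous"), 1.025)
})

test_that("predict_concentration picks branches and floors negatives", {
  m <- piecewise_quad_model(0, 0, 100, 0, 0, 250, theta_T = 0.9)
  expect_equal(predict_concentration(m, 0.5), 100)
  expect_equal(predict_concentration(m, 0.9), 100)   # boundary inclusive
  expect_equal(predict_concentration(m, 0.90001), 250)

  neg <- piecewise_quad_model(0, 0, -5, 0, 0, 10, theta_T = 0.9)
  expect_warning(v <- predict_concentration(neg, 0.1), "floored")
  expect_equal(v, 0)
  expect_error(predict_concentration(m, NaN), "finite")
  expect_error(predict_concentration(m, numeric(0)), "finite")
})

test_that("linear model fit returns exact and degenerate cases correctly", {
  th <- seq(0.1, 1, length.out = 10)
  m <- fit_linear(th, 2 * th + 1)
  expect_equal(m$slope, 2, tolerance = 1e-10)
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(predict(m, 0.5), 2, tolerance = 1e-10)

  flat <- fit_linear(th, rep(7, 10))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)

  set.seed(31)
  thn <- runif(30, 0, 1.4)
  ccn <- 250 * thn + 20 + rnorm(30, 0, 4)
  mn <- fit_linear(thn, ccn)
  expect_lt(abs(mn$slope - 250), 3 * attr(mn, "slope_se"))

  expect_error(fit_linear(rep(0.5, 5), 1:5), "identical")
})
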