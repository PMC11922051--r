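test_that("cega_zone reproduces the canonical examples", {
  expect_identical(cega_zone(200, 200), "A")     # perfect prediction
  expect_identical(cega_zone(100, 119), "A")     # 19% relative error
  expect_identical(cega_zone(100, 120), "A")     # 20% boundary inclusive
  expect_identical(cega_zone(50, 250), "E")      # hypo read as hyper
  expect_identical(cega_zone(200, 60), "E")
  expect_identical(cega_zone(100, 140), "B")
  expect_identical(cega_zone(100, 220), "C")     # overcorrection stimulus
  expect_identical(cega_zone(150, 20), "C")
  expect_identical(cega_zone(40, 120), "D")      # missed hypoglycemia
  expect_identical(cega_zone(300, 150), "D")     # missed hyperglycemia
  expect_identical(cega_zone(65, 80), "D")       # above the 1.2 r slant
  expect_identical(cega_zone(65, 75), "A")       # inside 20% band
  expect_error(cega_zone(-1, 50), "non-negative")
  expect_error(cega_zone(50, Inf), "finite")
})

test_that("cega_zone agrees with the brute-force oracle on a dense grid", {
  g <- seq(0, 400, length.out = 120)
  pts <- expand.grid(r = g, p = g)
  expect_identical(cega_zone(pts$r, pts$p), cega_oracle(pts$r, pts$p))
})

test_that("zone boundary points fall to the alphabetically earlier zone", {
  # on the 20% line: A beats B
  expect_identical(cega_zone(100, 80), "A")
  # on the upper C edge p = r + 110: open C, so B
  expect_identical(cega_zone(100, 210), "B")
  # on the D band edge p = 180: open D, so B
  expect_identical(cega_zone(40, 180), "B")
  # oracle makes the same calls
  expect_identical(cega_oracle(c(100, 100, 40), c(80, 210, 180)),
                   c("A", "B", "B"))
})

test_that("zone_percentages conserves counts and sums to 100", {
  zp <- zone_percentages(c(rep("A", 28), rep("B", 4)))
  expect_equal(zp$zone_percentages[1], 87.5)   # 28 of 32
  expect_equal(sum(zp$zone_percentages), 100, tolerance = 1e-9)
  expect_equal(zp$n_points, 32L)

  expect_equal(zone_percentages(rep("A", 7))$zone_percentages,
               c(100, 0, 0, 0, 0))
  expect_equal(zone_percentages(c("A", "B", "C", "D", "E"))$zone_percentages,
               rep(20, 5))
  expect_error(zone_percentages(character(0)), "empty")
  expect_error(zone_percentages(c("A", "F")), "labels")
})

test_that("zone-A LOD is the smallest always-accurate concentration", {
  refs <- rep(c(80, 100, 150, 200, 300), each = 3)
  good <- refs                                  # perfect predictions
  expect_equal(estimate_lod(refs, good), 80)

  bad <- refs * 3 + 100                         # nothing in zone A
  expect_true(is.na(estimate_lod(refs, bad)))

  # fails below 100, passes at and above
  mixed <- ifelse(refs < 100, refs * 2.5 + 60, refs)
  expect_equal(estimate_lod(refs, mixed), 100)

  # one bad replicate at 150 pushes the LOD up under the replicate rule
  one_bad <- good
  one_bad[refs == 150][1] <- 190
  expect_equal(estimate_lod(refs, one_bad), 200)
  # ... but not under the mean rule
  expect_equal(estimate_lod(refs, one_bad, membership = "mean"), 80)

  # monotone: adding a passing concentration above the LOD never raises it
  refs2 <- c(refs, 350, 350)
  mixed2 <- c(mixed, 350, 350)
  expect_lte(estimate_lod(refs2, mixed2), estimate_lod(refs, mixed))

  expect_error(estimate_lod(numeric(0), numeric(0)), "empty")
  expect_error(estimate_lod(rep(100, 4), rep(100, 4)), "distinct")
})

test_that("calibration-curve LOD follows 3.3 sigma over slope", {
  set.seed(41)
  refs <- rep(seq(90, 400, length.out = 10), each = 3)
  preds <- refs + rnorm(30, 0, 5)
  lod <- estimate_lod(refs, preds, rule = "calibration")
  fit <- lm(preds ~ refs)
  expect_equal(lod, 3.3 * sd(resid(fit)) / coef(fit)[["refs"]])
})

test_that("repeatability summarises day-by-concentration groups", {
  day <- rep(c(1, 2), each = 6)
  conc <- rep(rep(c(120, 250, 400), each = 2), 2)
  val <- rep(rep(c(0.4, 0.8, 1.2), each = 2), 2)
  rs <- repeatability(day, conc, val)
  expect_equal(nrow(rs), 6)
  expect_true(all(rs$cv == 0))                   # identical replicates
  d1 <- rs$mean[rs$day == 1]; d2 <- rs$mean[rs$day == 2]
  expect_equal(d1, d2)                           # no between-day drift

  # a planted 10% day-2 shift is recovered exactly
  val2 <- val * ifelse(day == 2, 1.1, 1)
  rs2 <- repeatability(day, conc, val2)
  shift <- rs2$mean[rs2$day == 2] / rs2$mean[rs2$day == 1] - 1
  expect_equal(shift, rep(0.1, 3), tolerance = 1e-12)

  expect_error(repeatability(1, 1, numeric(0)), "empty")
})
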