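# Calibration models linking rotation to concentration: direct inversion
# through the specific rotation, piecewise quadratic regression (glucose),
# single linear regression (naproxen), and a deterministic outlier policy.

#' Concentration from the specific rotation
#'
#' `c = theta / (specific_rotation * path_length)`, the direct polarimetric
#' inversion. Units must be consistent: theta in the angular unit the
#' specific rotation is quoted in, path length in its length unit.
#'
#' @param theta observed rotation.
#' @param params a [specific_rotation_params].
#' @param path_length optical path length (positive).
#' @return Concentration in the unit system implied by `params`.
#' @export
concentration_from_specific_rotation <- function(theta, params, path_length) {
  stopifnot(inherits(params, "specific_rotation_params"))
  path_length <- check_scalar_positive(path_length, "path_length")
  theta / (params$specific_rotation * path_length)
}

#' Deterministic outlier removal for calibration pairs
#'
#' Fits a provisional quadratic `c ~ theta + theta^2` and iteratively drops
#' the observation with the largest absolute externally studentized
#' residual, while it exceeds `threshold`, at most `max_removed` times.
#'
#' @param theta rotation values.
#' @param concentration matching reference concentrations.
#' @param max_removed cap on removals (default 3, matching the roughly
#'   three outliers eliminated per calibration set).
#' @param threshold studentized-residual cutoff.
#' @return `list(theta = , concentration = , removed = )` where `removed`
#'   holds the indices (into the original vectors) that were dropped.
#' @export
remove_outliers <- function(theta, concentration, max_removed = 3,
                            threshold = 2.5) {
  n <- length(theta)
  if (n != length(concentration))
    stop("theta and concentration lengths differ", call. = FALSE)
  if (n < 6L) stop("need at least 6 pairs for outlier screening",
                   call. = FALSE)
  keep <- seq_len(n)
  removed <- integer(0)
  while (length(removed) < max_removed && length(keep) > 4L) {
    df <- data.frame(th = theta[keep], cc = concentration[keep])
    fit <- stats::lm(cc ~ th + I(th^2), data = df)
    # an essentially perfect fit has no detectable outliers; studentized
    # residuals of pure rounding noise are meaningless
    sigma <- suppressWarnings(summary(fit)$sigma)
    if (sigma <= 1e-8 * (max(abs(df$cc)) + 1)) break
    rs <- abs(stats::rstudent(fit))
    # a non-finite value means deleting the point leaves a perfect fit:
    # the strongest possible outlier signal
    rs[!is.finite(rs)] <- Inf
    worst <- which.max(rs)
    if (rs[worst] <= threshold) break
    removed <- c(removed, keep[worst])
    keep <- keep[-worst]
  }
  list(theta = theta[keep], concentration = concentration[keep],
       removed = removed)
}

quad_fit <- function(theta, concentration) {
  fit <- stats::lm(cc ~ th + I(th^2),
                   data = data.frame(th = theta, cc = concentration))
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  list(k = unname(co[1]), b = unname(co[2]), a = unname(co[3]),
       rss = sum(stats::resid(fit)^2))
}

#' Fit the piecewise quadratic calibration model
#'
#' Two quadratics in theta, fitted by independent ordinary least squares on
#' either side of the rotation threshold `theta_T` (no continuity
#' constraint; the two branches are free). With `theta_T = "auto"` the
#' threshold is chosen from the unique observed rotation values, minimizing
#' the total residual sum of squares; ties break toward the smaller
#' threshold. The split is inclusive on the left: `theta <= theta_T` belongs
#' to the first branch.
#'
#' @param theta rotation values in radians.
#' @param concentration matching reference concentrations.
#' @param theta_T threshold in radians, or `"auto"`.
#' @param units_out concentration unit label.
#' @return A [piecewise_quad_model]; `attr(, "rss")` holds the total
#'   residual sum of squares.
#' @export
fit_piecewise_quadratic <- function(theta, concentration, theta_T = "auto",
                                    units_out = "mg/dl") {
  if (length(theta) != length(concentration))
    stop("theta and concentration lengths differ", call. = FALSE)
  fit_at <- function(tt) {
    lo <- theta <= tt
    if (sum(lo) < 3L)
      stop(sprintf("segment theta <= %.4g has fewer than 3 points", tt),
           call. = FALSE)
    if (sum(!lo) < 3L)
      stop(sprintf("segment theta > %.4g has fewer than 3 points", tt),
           call. = FALSE)
    f1 <- quad_fit(theta[lo], concentration[lo])
    f2 <- quad_fit(theta[!lo], concentration[!lo])
    list(f1 = f1, f2 = f2, rss = f1$rss + f2$rss)
  }
  if (identical(theta_T, "auto")) {
    cand <- sort(unique(theta))
    cand <- cand[vapply(cand, function(tt)
      sum(theta <= tt) >= 3L && sum(theta > tt) >= 3L, logical(1))]
    if (length(cand) == 0L)
      stop("no admissible threshold: need >= 3 points on each side",
           call. = FALSE)
    rss <- vapply(cand, function(tt) fit_at(tt)$rss, numeric(1))
    theta_T <- cand[which.min(rss)]  # first minimum = smallest threshold
  }
  ft <- fit_at(theta_T)
  m <- piecewise_quad_model(ft$f1$a, ft$f1$b, ft$f1$k,
                            ft$f2$a, ft$f2$b, ft$f2$k,
                            theta_T = theta_T, units_out = units_out)
  attr(m, "rss") <- ft$rss
  m
}

#' Default rotation thresholds per polarization
#'
#' Thresholds (radians) near the 200 mg/dl rotation magnitude for vertical
#' (V), +45 linear (P) and right-circular (R) incidence, for serum-based
#' and aqueous glucose samples.
#'
#' @param polarization `"V"`, `"P"` or `"R"`.
#' @param matrix `"serum"` or `"aqueous"`.
#' @return Threshold in radians.
#' @export
default_theta_threshold <- function(polarization = c("V", "P", "R"),
                                    matrix = c("serum", "aqueous")) {
  polarization <- match.arg(polarization)
  matrix <- match.arg(matrix)
  tab <- list(serum = c(V = 0.88, P = 0.98, R = 0.822),
              aqueous = c(V = 0.88, P = 1.025, R = 0.97))
  unname(tab[[matrix]][polarization])
}

#' Predict concentration from rotation
#'
#' Branch selected by `theta <= theta_T` (inclusive). Negative predictions
#' are floored at zero with a warning.
#'
#' @param model a [piecewise_quad_model].
#' @param theta rotation values in radians (finite).
#' @return Predicted concentrations, same length as `theta`.
#' @export
predict_concentration <- function(model, theta) {
  stopifnot(inherits(model, "piecewise_quad_model"))
  if (length(theta) == 0L || any(!is.finite(theta)))
    stop("theta must be finite", call. = FALSE)
  lo <- theta <= model$theta_T
  cp <- ifelse(lo,
               model$a1 * theta^2 + model$b1 * theta + model$k1,
               model$a2 * theta^2 + model$b2 * theta + model$k2)
  if (any(cp < 0)) {
    warning("negative predicted concentration floored at 0", call. = FALSE)
    cp <- pmax(cp, 0)
  }
  cp
}

#' @export
predict.piecewise_quad_model <- function(object, theta, ...) {
  predict_concentration(object, theta)
}

#' Fit the linear rotation-concentration model
#'
#' Ordinary least squares `c = slope * theta + intercept`, as used when the
#' rotation varies linearly with concentration (the naproxen case). R^2 is
#' defined as 0 when the response has zero variance.
#'
#' @param theta rotation values (at least two distinct).
#' @param concentration matching reference concentrations.
#' @return A [pa_linear_model].
#' @export
fit_linear <- function(theta, concentration) {
  if (length(theta) != length(concentration))
    stop("theta and concentration lengths differ", call. = FALSE)
  if (length(unique(theta)) < 2L)
    stop("all theta values identical; cannot fit a line", call. = FALSE)
  fit <- stats::lm(cc ~ th, data = data.frame(th = theta, cc = concentration))
  co <- stats::coef(fit)
  tss <- sum((concentration - mean(concentration))^2)
  rsq <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 0
  m <- pa_linear_model(slope = unname(co[2]), intercept = unname(co[1]),
                       r_squared = max(0, min(1, rsq)))
  attr(m, "slope_se") <-
    suppressWarnings(summary(fit)$coefficients["th", "Std. Error"])
  m
}

#' @export
predict.pa_linear_model <- function(object, theta, ...) {
  object$slope * theta + object$intercept
}
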