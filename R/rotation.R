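# Malus-law rotation estimation from fluence-depth profiles.
#
# The PA amplitude ratio is read as the Malus relation P = P0 cos^2(theta),
# so theta = acos(sqrt(P / P0)). In faithful mode the ratio is used as-is,
# which conflates Beer-Lambert decay with chiral rotation; an optional
# attenuation correction divides P by exp(-mu_a * (depth - p0_depth)) first.

#' Extract the P0 and P amplitudes from a depth profile
#'
#' Each amplitude is the mean of `window` samples centred on the sample
#' nearest the requested depth.
#'
#' @param profile a [fluence_depth_profile].
#' @param target_depth depth of the P reading, metres.
#' @param p0_depth depth of the P0 reference reading, metres (default
#'   0.018 mm, close to the illumination point).
#' @param window odd number of samples to average.
#' @param noise_floor P0 must exceed this level to be usable.
#' @return `list(P0 = , P = , p0_depth = , target_depth = )` with the
#'   actual grid depths used.
#' @export
extract_amplitudes <- function(profile, target_depth, p0_depth = 1.8e-5,
                               window = 5, noise_floor = 0) {
  stopifnot(inherits(profile, "fluence_depth_profile"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd sample count", call. = FALSE)
  rng <- range(profile$depth)
  for (d in c(p0 = p0_depth, target = target_depth)) {
    if (d < rng[1] || d > rng[2])
      stop(sprintf("requested depth %.4g m outside profile range [%.4g, %.4g]",
                   d, rng[1], rng[2]), call. = FALSE)
  }
  half <- (window - 1L) %/% 2L
  grab <- function(d) {
    i <- which.min(abs(profile$depth - d))
    lo <- max(1L, i - half)
    hi <- min(length(profile$amplitude), i + half)
    mean(profile$amplitude[lo:hi])
  }
  P0 <- grab(p0_depth)
  P <- grab(target_depth)
  if (P0 <= noise_floor)
    stop("unusable reference: P0 does not exceed the noise floor",
         call. = FALSE)
  list(P0 = P0, P = P, p0_depth = p0_depth, target_depth = target_depth)
}

#' Rotation from the Malus amplitude ratio
#'
#' `theta = acos(sqrt(P / P0))`, with the ratio clamped to `[0, 1]` by
#' default (a warning is emitted when clamping occurred, as happens for
#' noisy P slightly above P0). The result lies in `[0, pi/2]` radians.
#'
#' @param P amplitude at the path length of interest (non-negative).
#' @param P0 reference amplitude near the illumination point (positive).
#' @param clamp clamp the ratio into `[0, 1]`; with `clamp = FALSE` a ratio
#'   above 1 is an error.
#' @return Rotation in radians; vectorized over `P` and `P0`.
#' @export
estimate_rotation <- function(P, P0, clamp = TRUE) {
  if (any(P0 <= 0)) stop("P0 must be positive", call. = FALSE)
  if (any(P < 0)) stop("P must be non-negative", call. = FALSE)
  r <- P / P0
  if (any(r > 1)) {
    if (!clamp)
      stop("P exceeds P0 and clamp = FALSE", call. = FALSE)
    warning("amplitude ratio P/P0 above 1 clamped to 1", call. = FALSE)
  }
  acos(sqrt(pmin(pmax(r, 0), 1)))
}

#' Attenuation-corrected rotation estimate
#'
#' Divides P by the Beer-Lambert factor `exp(-mu_a * (target_depth -
#' p0_depth))` before the Malus inversion, removing the known confound of
#' fluence decay from the faithful estimator.
#'
#' @param amplitudes result of [extract_amplitudes()].
#' @param mu_a user-supplied absorption coefficient in 1/m.
#' @param clamp see [estimate_rotation()].
#' @return Rotation in radians.
#' @export
estimate_rotation_corrected <- function(amplitudes, mu_a, clamp = TRUE) {
  mu_a <- check_scalar_nonneg(mu_a, "mu_a")
  dz <- amplitudes$target_depth - amplitudes$p0_depth
  estimate_rotation(amplitudes$P * exp(mu_a * dz), amplitudes$P0,
                    clamp = clamp)
}

#' Per-concentration rotation summary
#'
#' @param theta rotation estimates in radians.
#' @param concentration matching reference concentrations.
#' @return A data frame sorted by concentration with columns
#'   `concentration`, `n`, `mean_theta`, `sd_theta` (`NA`, not 0, when a
#'   group has a single replicate).
#' @export
rotation_curve <- function(theta, concentration) {
  if (length(theta) == 0L) stop("no measurements given", call. = FALSE)
  if (length(theta) != length(concentration))
    stop("theta and concentration lengths differ", call. = FALSE)
  groups <- split(theta, concentration)
  conc <- as.numeric(names(groups))
  out <- data.frame(
    concentration = conc,
    n = vapply(groups, length, integer(1)),
    mean_theta = vapply(groups, mean, numeric(1)),
    sd_theta = vapply(groups, function(g)
      if (length(g) > 1L) stats::sd(g) else NA_real_, numeric(1)),
    row.names = NULL)
  out[order(out$concentration), , drop = FALSE]
}
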