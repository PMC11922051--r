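# Clarke Error Grid Analysis, zone percentages, limit of detection and
# repeatability summaries for glucose-style predictions.

#' Clarke error grid zone of a prediction
#'
#' Assigns each (reference, predicted) pair in mg/dl to one of the Clarke
#' zones A-E. Zone A is clinically accurate: within 20% of the reference,
#' or both values below 70 mg/dl. Zones C, D and E are encoded as open
#' regions (strict inequalities), so a point exactly on one of their
#' boundaries falls to the alphabetically earlier zone; the A criterion is
#' inclusive. Zone B is the residual region.
#'
#' @param reference reference concentrations, mg/dl (non-negative, finite).
#' @param predicted predicted concentrations, mg/dl (non-negative, finite).
#' @return Character vector of zone labels `"A"`..`"E"`.
#' @export
cega_zone <- function(reference, predicted) {
  if (length(reference) != length(predicted))
    stop("reference and predicted lengths differ", call. = FALSE)
  if (any(!is.finite(reference)) || any(!is.finite(predicted)))
    stop("reference and predicted must be finite", call. = FALSE)
  if (any(reference < 0) || any(predicted < 0))
    stop("reference and predicted must be non-negative", call. = FALSE)
  R <- reference; P <- predicted
  inA <- abs(P - R) <= 0.2 * R | (R < 70 & P < 70)
  inC <- (R > 70 & R < 290 & P > R + 110) |
         (R > 130 & R < 180 & P < 7 / 5 * R - 182)
  inD <- (P > 70 & P < 180) &
         (R < 175 / 3 | (R > 175 / 3 & R < 70 & P > 6 / 5 * R) | R > 240)
  inE <- (R < 70 & P > 180) | (R > 180 & P < 70)
  zone <- rep("B", length(R))
  zone[inE] <- "E"
  zone[inD] <- "D"
  zone[inC] <- "C"
  zone[inA] <- "A"
  zone
}

#' Zone percentages of a Clarke error grid
#'
#' @param zones character vector of zone labels from [cega_zone()].
#' @return An object of class `cega_result` with fields `zones`,
#'   `zone_percentages` (named numeric over A-E, summing to 100) and
#'   `n_points`.
#' @export
zone_percentages <- function(zones) {
  if (length(zones) == 0L) stop("empty zone list", call. = FALSE)
  if (!all(zones %in% c("A", "B", "C", "D", "E")))
    stop("zones must be labels A-E", call. = FALSE)
  counts <- table(factor(zones, levels = c("A", "B", "C", "D", "E")))
  structure(list(zones = as.character(zones),
                 zone_percentages = 100 * as.numeric(counts) / length(zones),
                 n_points = length(zones)),
            class = "cega_result")
}

#' @export
print.cega_result <- function(x, ...) {
  cat(sprintf("<cega_result> %d points\n", x$n_points))
  pz <- x$zone_percentages
  names(pz) <- c("A", "B", "C", "D", "E")
  print(round(pz[pz > 0 | names(pz) == "A"], 2))
  invisible(x)
}

#' Limit of detection from Clarke zone-A membership
#'
#' With the `"zoneA"` rule (default) the LOD is the smallest reference
#' concentration `c*` such that every tested concentration at or above `c*`
#' has all of its replicate predictions in zone A (`membership =
#' "replicate"`), or its mean prediction in zone A (`membership = "mean"`).
#' `NA` is returned when no such concentration exists. The `"calibration"`
#' rule instead returns `3.3 * sd(residuals) / slope` from a linear
#' regression of predicted on reference.
#'
#' @param reference reference concentrations, mg/dl.
#' @param predicted matching predictions, mg/dl.
#' @param rule `"zoneA"` or `"calibration"`.
#' @param membership `"replicate"` (stricter, default) or `"mean"`.
#' @return The LOD in mg/dl, or `NA_real_` when undefined.
#' @export
estimate_lod <- function(reference, predicted,
                         rule = c("zoneA", "calibration"),
                         membership = c("replicate", "mean")) {
  if (length(reference) == 0L) stop("empty input", call. = FALSE)
  if (length(reference) != length(predicted))
    stop("reference and predicted lengths differ", call. = FALSE)
  rule <- match.arg(rule)
  membership <- match.arg(membership)
  if (rule == "calibration") {
    fit <- stats::lm(p ~ r, data = data.frame(r = reference, p = predicted))
    slope <- stats::coef(fit)[["r"]]
    if (!is.finite(slope) || slope <= 0) return(NA_real_)
    return(3.3 * stats::sd(stats::resid(fit)) / slope)
  }
  levels_c <- sort(unique(reference))
  if (length(levels_c) < 2L)
    stop("need at least 2 distinct reference concentrations", call. = FALSE)
  ok <- vapply(levels_c, function(cc) {
    idx <- reference == cc
    if (membership == "replicate") {
      all(cega_zone(reference[idx], predicted[idx]) == "A")
    } else {
      cega_zone(cc, mean(predicted[idx])) == "A"
    }
  }, logical(1))
  # smallest concentration from which everything above also passes
  pass_from <- rev(cumprod(rev(ok))) > 0
  if (!any(pass_from)) return(NA_real_)
  levels_c[which(pass_from)[1L]]
}

#' Repeatability summary by day and concentration
#'
#' @param day grouping label for the acquisition day.
#' @param concentration reference concentration of each measurement.
#' @param value measured quantity (e.g. rotation in radians).
#' @return A data frame keyed by `(day, concentration)` with the group
#'   `n`, `mean`, `sd` (`NA` for singletons) and coefficient of variation
#'   `cv = sd / mean`.
#' @export
repeatability <- function(day, concentration, value) {
  if (length(value) == 0L) stop("empty input", call. = FALSE)
  if (length(day) != length(value) || length(concentration) != length(value))
    stop("day, concentration and value lengths differ", call. = FALSE)
  key <- interaction(day, concentration, drop = TRUE, lex.order = TRUE)
  groups <- split(seq_along(value), key)
  rows <- lapply(groups, function(idx) {
    v <- value[idx]
    s <- if (length(v) > 1L) stats::sd(v) else NA_real_
    data.frame(day = day[idx[1]], concentration = concentration[idx[1]],
               n = length(v), mean = mean(v), sd = s,
               cv = if (is.na(s) || mean(v) == 0) NA_real_ else s / mean(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$day, out$concentration), , drop = FALSE]
}
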