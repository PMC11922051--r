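# Reading and writing of signals and fitted models.
#
# Two signal formats are supported:
#  * "delimited": two columns (time_s, amplitude) preceded by '#'-prefixed
#    "key: value" metadata lines; human-inspectable, exact to the printed
#    precision.
#  * "container": a JSON record with full-precision samples; round-trips
#    bit-exactly.

signal_meta_fields <- c("sampling_rate", "time_offset", "pulse_energy",
                        "wavelength", "polarization", "replicate_id")

#' Write a PA trace to disk
#'
#' @param x a [pa_timeseries].
#' @param path output file path.
#' @param format `"delimited"` (two-column text with a metadata header) or
#'   `"container"` (JSON, bit-exact round trip).
#' @param digits significant digits for the delimited amplitude column.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, format = c("delimited", "container"),
                         digits = 10) {
  stopifnot(inherits(x, "pa_timeseries"))
  format <- match.arg(format)
  if (format == "container") {
    # doubles are stored as %.17g strings: shortest text that parses back
    # to the identical IEEE-754 value, making the round trip bit-exact
    f17 <- function(v) sprintf("%.17g", v)
    rec <- list(format = "papeors-signal", version = 1L,
                samples = f17(x$samples), sampling_rate = f17(x$sampling_rate),
                time_offset = f17(x$time_offset),
                pulse_energy = f17(x$pulse_energy),
                wavelength = f17(x$wavelength), polarization = x$polarization,
                replicate_id = x$replicate_id, meta = x$meta)
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    hdr <- vapply(signal_meta_fields, function(f) {
      sprintf("# %s: %s", f, format(x[[f]], digits = 17, scientific = NA))
    }, character(1))
    tm <- signal_times(x)
    body <- sprintf("%.*g\t%.*g", digits, tm, digits, x$samples)
    writeLines(c(hdr, "# time_s\tamplitude", body), path)
  }
  invisible(path)
}

#' Read a PA trace from disk
#'
#' @param path input file path.
#' @param format `"delimited"` or `"container"`; see [write_signal()].
#' @return A validated [pa_timeseries].
#' @export
read_signal <- function(path, format = c("delimited", "container")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "container") {
    rec <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e)
                      stop("cannot parse signal container ", path, ": ",
                           conditionMessage(e), call. = FALSE))
    for (f in c("samples", signal_meta_fields)) {
      if (is.null(rec[[f]]))
        stop("missing metadata field in ", path, ": ", f, call. = FALSE)
    }
    num <- function(f) {
      v <- suppressWarnings(as.numeric(rec[[f]]))
      if (anyNA(v)) stop("non-numeric values for field '", f, "' in ", path,
                         call. = FALSE)
      v
    }
    pa_timeseries(samples = num("samples"), sampling_rate = num("sampling_rate"),
                  time_offset = num("time_offset"),
                  pulse_energy = num("pulse_energy"),
                  wavelength = num("wavelength"),
                  polarization = rec$polarization,
                  replicate_id = rec$replicate_id,
                  meta = as.list(rec$meta))
  } else {
    lines <- trimws(readLines(path))
    hdr <- grep("^#", lines, value = TRUE)
    body <- grep("^#", lines, value = TRUE, invert = TRUE)
    body <- body[nzchar(body)]
    meta <- list()
    for (h in hdr) {
      m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
      if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
    }
    for (f in setdiff(signal_meta_fields, "replicate_id")) {
      if (is.null(meta[[f]]))
        stop("missing metadata field in ", path, ": ", f, call. = FALSE)
    }
    if (length(body) == 0L)
      stop("no samples found in ", path, call. = FALSE)
    parts <- strsplit(body, "[\t ,]+")
    amp <- suppressWarnings(
      vapply(parts, function(p) as.numeric(p[2]), numeric(1)))
    if (anyNA(amp))
      stop("non-numeric sample values in ", path, call. = FALSE)
    num <- function(f) {
      v <- suppressWarnings(as.numeric(meta[[f]]))
      if (is.na(v)) stop("non-numeric metadata field in ", path, ": ", f,
                         call. = FALSE)
      v
    }
    pa_timeseries(samples = amp, sampling_rate = num("sampling_rate"),
                  time_offset = num("time_offset"),
                  pulse_energy = num("pulse_energy"),
                  wavelength = num("wavelength"),
                  polarization = meta$polarization,
                  replicate_id = if (is.null(meta$replicate_id)) ""
                                 else meta$replicate_id)
  }
}

#' Write a fitted calibration model as structured text
#'
#' Serializes a [piecewise_quad_model] or [pa_linear_model] to JSON so that
#' `read_model(write_model(m, path))` reproduces it field for field.
#'
#' @param model the model object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "piecewise_quad_model")) {
    rec <- c(list(model = "piecewise_quadratic"),
             model[c("a1", "b1", "k1", "a2", "b2", "k2",
                     "theta_T", "units_out")])
  } else if (inherits(model, "pa_linear_model")) {
    rec <- c(list(model = "linear"),
             model[c("slope", "intercept", "r_squared")])
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"),
         call. = FALSE)
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted calibration model
#'
#' @param path path written by [write_model()].
#' @return A [piecewise_quad_model] or [pa_linear_model].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse model file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(rec$model))
    stop("malformed model file ", path, ": missing key 'model'",
         call. = FALSE)
  need <- function(keys) {
    for (k in keys) if (is.null(rec[[k]]))
      stop("malformed model file ", path, ": missing key '", k, "'",
           call. = FALSE)
  }
  if (identical(rec$model, "piecewise_quadratic")) {
    need(c("a1", "b1", "k1", "a2", "b2", "k2", "theta_T", "units_out"))
    piecewise_quad_model(rec$a1, rec$b1, rec$k1, rec$a2, rec$b2, rec$k2,
                         theta_T = rec$theta_T, units_out = rec$units_out)
  } else if (identical(rec$model, "linear")) {
    need(c("slope", "intercept"))
    pa_linear_model(rec$slope, rec$intercept,
                    r_squared = if (is.null(rec$r_squared)) NA_real_
                                else rec$r_squared)
  } else {
    stop("malformed model file ", path, ": unknown model type '",
         rec$model, "'", call. = FALSE)
  }
}
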