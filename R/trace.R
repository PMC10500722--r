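#' Time-domain trace container
#'
#' Light container for sampled time-domain signals: dressed-echo dipolar
#' modulations (axis = the dipolar evolution delay tau1) or relaxation
#' decays. Carries axis metadata so files and pipelines stay self-describing.
#'
#' @param t Time axis, us, strictly increasing.
#' @param y Real amplitude (dimensionless).
#' @param ... Named metadata (generating parameters, seed, units ...).
#' @return Object of class `epr_trace` with fields `t`, `y`, `meta`.
#' @export
epr_trace <- function(t, y, ...) {
  if (length(t) != length(y)) stop("`t` and `y` must have equal length")
  if (length(t) < 1) stop("empty trace")
  if (any(diff(t) <= 0)) stop("time axis must be strictly increasing")
  if (!all(is.finite(t)) || !all(is.finite(y)))
    stop("trace values must be finite")
  meta <- list(...)
  if (is.null(meta$time_unit)) meta$time_unit <- "us"
  if (is.null(meta$amplitude_unit)) meta$amplitude_unit <- "dimensionless"
  structure(list(t = as.numeric(t), y = as.numeric(y), meta = meta),
            class = "epr_trace")
}

#' @export
print.epr_trace <- function(x, ...) {
  cat(sprintf("<epr_trace> %d points, t in [%.4g, %.4g] %s\n",
              length(x$t), x$t[1], x$t[length(x$t)], x$meta$time_unit))
  keys <- setdiff(names(x$meta), c("time_unit", "amplitude_unit"))
  if (length(keys))
    cat("  meta:", paste(keys, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.epr_trace <- function(x, ...) data.frame(t = x$t, y = x$y)

# uniform-grid check with tolerance, returns the spacing
trace_spacing <- function(trace, tol = 1e-8) {
  dt <- diff(trace$t)
  if (max(abs(dt - dt[1])) > tol * max(abs(dt)))
    stop("trace requires a uniform time grid")
  dt[1]
}

#' Frequency-domain dipolar spectrum container
#'
#' @param frequency Frequency axis, MHz (half-sided, non-negative).
#' @param amplitude Real spectral amplitude.
#' @param ... Named metadata (window, zero-fill factor, ...).
#' @return Object of class `dipolar_spectrum`.
#' @export
dipolar_spectrum <- function(frequency, amplitude, ...) {
  if (length(frequency) != length(amplitude))
    stop("`frequency` and `amplitude` must have equal length")
  structure(list(frequency = as.numeric(frequency),
                 amplitude = as.numeric(amplitude), meta = list(...)),
            class = "dipolar_spectrum")
}

#' @export
print.dipolar_spectrum <- function(x, ...) {
  cat(sprintf("<dipolar_spectrum> %d points, f in [%.4g, %.4g] MHz\n",
              length(x$frequency), min(x$frequency), max(x$frequency)))
  if (!is.null(x$meta$singularities))
    cat("  singularities:",
        paste(sprintf("%.4g", x$meta$singularities), collapse = ", "),
        "MHz\n")
  invisible(x)
}
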