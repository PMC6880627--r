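#' Uniformly sampled concentration time-series
#'
#' Light container for a concentration curve on a strictly increasing uniform
#' time grid. Time is in minutes, concentration in mM. All model code in the
#' package assumes the grid starts at zero and shares its spacing `dt` with
#' the arterial input function.
#'
#' @param times Numeric vector of sampling times (min), uniform spacing,
#'   at least two points.
#' @param values Numeric vector of concentrations (mM), same length as
#'   `times`.
#' @return An object of class `sampled_curve`: a list with elements `times`,
#'   `values` and the grid spacing `dt` (min).
#' @examples
#' tg <- time_grid(dt = 0.012, duration = 3)
#' curve <- sampled_curve(tg, rep(0, length(tg)))
#' curve$dt
#' @export
sampled_curve <- function(times, values) {
  if (length(times) < 2L) stop("`times` needs at least 2 points", call. = FALSE)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length", call. = FALSE)
  dts <- diff(times)
  dt <- dts[1L]
  if (dt <= 0 || any(abs(dts - dt) > 1e-9 * max(dt, 1)))
    stop("`times` must be a strictly increasing uniform grid", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 dt = dt),
            class = "sampled_curve")
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("<sampled_curve> %d samples, dt = %g min, t in [%g, %g] min\n",
              length(x$times), x$dt, x$times[1L],
              x$times[length(x$times)]))
  cat(sprintf("  values: [%g, %g] mM\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.sampled_curve <- function(x) length(x$times)

#' Uniform time grid starting at zero
#'
#' @param dt Sampling interval (min).
#' @param duration Total duration `T` (min); the grid covers `[0, T]`.
#' @return Numeric vector `seq(0, duration, by = dt)` (the last point is the
#'   largest multiple of `dt` not exceeding `duration`).
#' @export
time_grid <- function(dt, duration) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (duration <= dt) stop("`duration` must exceed `dt`", call. = FALSE)
  seq(0, duration + 1e-12, by = dt)
}

# shared check that a curve and a time grid / second curve live on one grid
check_same_grid <- function(a, b) {
  if (length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9)
    stop("curves are defined on mismatched time grids", call. = FALSE)
  invisible(TRUE)
}

#' Read or write a concentration curve as two-column CSV
#'
#' The on-disk format is a CSV with columns `time_min` and
#' `concentration_mM`.
#'
#' @param path File path.
#' @return `read_curve` returns a [sampled_curve()].
#' @export
read_curve <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_min", "concentration_mM") %in% names(d)))
    stop("expected columns time_min, concentration_mM in ", path,
         call. = FALSE)
  sampled_curve(d$time_min, d$concentration_mM)
}

#' @param curve A [sampled_curve()].
#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  write.csv(data.frame(time_min = curve$times,
                       concentration_mM = curve$values),
            path, row.names = FALSE)
  invisible(path)
}
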