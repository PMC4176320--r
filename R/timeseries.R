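#' Paired ss/dsDNA mass time series
#'
#' The universal exchange object between the closed-form model, the
#' stochastic simulator and the fitter: a data frame with strictly
#' increasing, non-negative times (seconds) and non-negative ss, ds and
#' total mass columns. `total_mass` defaults to `ss_mass + ds_mass` and, if
#' supplied, must agree with that sum elementwise.
#'
#' @param times non-negative, strictly increasing times in seconds.
#' @param ss_mass ssDNA mass at each time (>= 0).
#' @param ds_mass dsDNA mass at each time (>= 0).
#' @param total_mass optional total mass; checked against `ss_mass + ds_mass`.
#' @param tol relative tolerance for the total-mass consistency check.
#' @return A `data.frame` of class `rcr_timeseries` with columns `time_s`,
#'   `ss_mass`, `ds_mass`, `total_mass`.
#' @export
rcr_timeseries <- function(times, ss_mass, ds_mass, total_mass = NULL,
                           tol = 1e-8) {
  times <- as.numeric(times)
  if (length(times) == 0L) stop("'times' must be non-empty", call. = FALSE)
  if (any(times < 0)) stop("'times' must be non-negative", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  ss_mass <- as.numeric(ss_mass)
  ds_mass <- as.numeric(ds_mass)
  if (length(ss_mass) != length(times) || length(ds_mass) != length(times))
    stop("mass vectors must match 'times' in length", call. = FALSE)
  if (any(ss_mass < 0) || any(ds_mass < 0))
    stop("mass values must be non-negative", call. = FALSE)
  tot <- ss_mass + ds_mass
  if (!is.null(total_mass)) {
    total_mass <- as.numeric(total_mass)
    scale <- pmax(abs(tot), 1)
    if (any(abs(total_mass - tot) > tol * scale))
      stop("'total_mass' must equal ss_mass + ds_mass", call. = FALSE)
    tot <- total_mass
  }
  structure(
    data.frame(time_s = times, ss_mass = ss_mass, ds_mass = ds_mass,
               total_mass = tot),
    class = c("rcr_timeseries", "data.frame")
  )
}

#' @export
plot.rcr_timeseries <- function(x, xunit = c("h", "s"), ...) {
  xunit <- match.arg(xunit)
  tt <- if (xunit == "h") x$time_s / 3600 else x$time_s
  graphics::matplot(tt, cbind(x$ss_mass, x$ds_mass, x$total_mass),
                    type = "l", lty = c(1, 1, 2), col = c("#1b9e77", "#d95f02", "grey40"),
                    xlab = paste0("time (", xunit, ")"), ylab = "mass (arbitrary units)",
                    ...)
  graphics::legend("right", c("ssDNA", "dsDNA", "total"), lty = c(1, 1, 2),
                   col = c("#1b9e77", "#d95f02", "grey40"), bty = "n")
  invisible(x)
}
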