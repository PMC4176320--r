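#' Closed-form kinetics of template switching in rolling circle replication
#'
#' A strand-displacing polymerase on a circular template produces a
#' single-stranded concatamer until, at an exponentially distributed time
#' (rate `lam`), it switches onto the displaced strand and converts the
#' accumulated ssDNA to double-stranded form, terminating when the ssDNA runs
#' out. Averaging over the switch-time distribution yields closed forms for
#' the population ss/dsDNA mass, implemented here.
#'
#' With A = `amplitude` = 2\*n0\*phi:
#' \deqn{N_{ds}(t) = (A/\lambda)(e^{-\lambda t} - 2e^{-\lambda t/2} + 1)}
#' \deqn{N_{ss}(t) = (A/\lambda)(e^{-\lambda t/2} - e^{-\lambda t})}
#' \deqn{N_{ss}(t) + N_{ds}(t) = (A/\lambda)(1 - e^{-\lambda t/2})}
#'
#' At `lam = 0` (switching blocked, e.g. by saturating SSB protein) the
#' analytic limits apply: pure linear ssDNA production `A*t/2 = n0*phi*t` and
#' no dsDNA. Times are in seconds throughout; mass units are arbitrary
#' (the amplitude carries the scale).
#'
#' @name kinetics
NULL

check_time <- function(t) {
  if (any(!is.finite(t) & !is.infinite(t)) || any(t < 0, na.rm = TRUE))
    stop("time must be non-negative", call. = FALSE)
  invisible(t)
}

#' Fraction of templates that have switched by time t
#'
#' The cumulative distribution function of the exponential switch-time law,
#' `1 - exp(-lam * t)`: the fraction of the initial template pool on which a
#' switching event has occurred by time `t`.
#'
#' @param t time in seconds (vectorized, non-negative).
#' @param lam switching rate constant, per second (>= 0).
#' @return Fraction in \[0, 1\], same length as `t`.
#' @examples
#' switched_fraction(log(2) / 1.95e-5, 1.95e-5)  # 0.5 at the half-life
#' @export
switched_fraction <- function(t, lam) {
  check_time(t)
  if (length(lam) != 1L || !is.numeric(lam) || lam < 0)
    stop("'lam' must be a single non-negative rate", call. = FALSE)
  -expm1(-lam * t)
}

as_params <- function(params) {
  if (!inherits(params, "rcr_params"))
    stop("'params' must be created with model_params()", call. = FALSE)
  params
}

#' Instantaneous dsDNA production rate
#'
#' Only templates that switched between `t/2` and `t` are currently
#' converting ssDNA to dsDNA (earlier switchers have already consumed their
#' strand and terminated). The rate is the switch-time density integrated
#' over that window, times the amplitude:
#' `r_ds(t) = A * (exp(-lam*t/2) - exp(-lam*t))`.
#'
#' @param t time in seconds (vectorized, non-negative).
#' @param params an [model_params()] object.
#' @return dsDNA mass production rate, mass units per second.
#' @export
dsdna_rate <- function(t, params) {
  check_time(t)
  p <- as_params(params)
  # A e^{-lam t/2} (1 - e^{-lam t/2}); expm1 keeps both extremes of lam*t exact
  r <- -p$amplitude * exp(-p$lam * t / 2) * expm1(-p$lam * t / 2)
  r[is.infinite(t)] <- 0
  r
}

#' Total dsDNA mass produced by time t
#'
#' Closed form `N_ds(t) = (A/lam) * (exp(-lam*t) - 2*exp(-lam*t/2) + 1)`,
#' computed as `(A/lam) * expm1(-lam*t/2)^2` which is exact near `lam*t = 0`.
#' Monotone nondecreasing from 0 to the termination plateau `A/lam`.
#'
#' @inheritParams dsdna_rate
#' @return dsDNA mass, mass units.
#' @export
mass_ds <- function(t, params) {
  check_time(t)
  p <- as_params(params)
  if (p$lam == 0) return(rep(0, length(t)))
  m <- (p$amplitude / p$lam) * expm1(-p$lam * t / 2)^2
  m[is.infinite(t)] <- p$amplitude / p$lam
  m
}

#' Total ssDNA mass present at time t
#'
#' Closed form `N_ss(t) = (A/lam) * (exp(-lam*t/2) - exp(-lam*t))`: ssDNA
#' accumulates by strand displacement and is consumed by fill-in synthesis on
#' switched templates, so the curve rises, peaks at `2*log(2)/lam`, and
#' decays to zero. At `lam = 0` the limit is linear production `A*t/2`.
#'
#' @inheritParams dsdna_rate
#' @return ssDNA mass, mass units.
#' @export
mass_ss <- function(t, params) {
  check_time(t)
  p <- as_params(params)
  if (p$lam == 0) return(p$amplitude * t / 2)
  m <- -(p$amplitude / p$lam) * exp(-p$lam * t / 2) * expm1(-p$lam * t / 2)
  m[is.infinite(t)] <- 0
  m
}

#' Total DNA mass (ss + ds) produced by time t
#'
#' `(A/lam) * (1 - exp(-lam*t/2))`; equals all nucleotides incorporated,
#' with ssDNA consumed by fill-in re-counted inside the dsDNA mass.
#'
#' @inheritParams dsdna_rate
#' @return Total mass, mass units.
#' @export
total_mass <- function(t, params) {
  check_time(t)
  p <- as_params(params)
  if (p$lam == 0) return(p$amplitude * t / 2)
  m <- -(p$amplitude / p$lam) * expm1(-p$lam * t / 2)
  m[is.infinite(t)] <- p$amplitude / p$lam
  m
}

#' Half-life of the unswitched template population
#'
#' @param lam switching rate constant, per second (> 0).
#' @return `log(2) / lam`, seconds.
#' @examples
#' half_life(1.95e-5) / 3600  # ~9.9 hours
#' @export
half_life <- function(lam) {
  if (length(lam) != 1L || !is.numeric(lam) || !is.finite(lam) || lam <= 0)
    stop("'lam' must be a single positive rate", call. = FALSE)
  log(2) / lam
}

#' Time at which the ssDNA mass peaks
#'
#' The unique maximizer of [mass_ss()], `2 * log(2) / lam`: one template
#' half-life of rise and then net consumption dominates.
#'
#' @param lam switching rate constant, per second (> 0).
#' @return Peak time, seconds.
#' @export
ss_peak_time <- function(lam) {
  2 * half_life(lam)
}

#' Predict ss/dsDNA mass time courses
#'
#' Evaluates the closed-form model at each requested time, returning the
#' standard exchange object shared by the simulator, the synthetic-data
#' generator and the fitter.
#'
#' @param times sorted, non-negative times in seconds.
#' @param params an [model_params()] object.
#' @return An [rcr_timeseries()] with columns `time_s`, `ss_mass`, `ds_mass`,
#'   `total_mass`.
#' @examples
#' p <- model_params(lam = 1.95e-5, amplitude = 1)
#' rcr_predict(c(0, 3600, 86400), p)
#' @export
rcr_predict <- function(times, params) {
  p <- as_params(params)
  rcr_timeseries(times = times,
                 ss_mass = mass_ss(times, p),
                 ds_mass = mass_ds(times, p))
}
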