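#' Event-driven per-template simulation of template switching
#'
#' Each of `n_templates` circular templates carries one polymerase producing
#' ssDNA at rate `phi`. A single switching event per template occurs at an
#' Exponential(`lam`) time tau, after which the polymerase fills in the
#' displaced strand at the same rate and falls off at `2 * tau`, when the
#' ssDNA it had produced is fully double-stranded. No time discretization is
#' involved: given the sampled switch times every query is evaluated exactly.
#'
#' @name simulator
NULL

#' Stochastic simulation configuration
#'
#' @param n_templates number of templates in the population (>= 1).
#' @param lam switching rate constant, per second per template (>= 0).
#' @param phi elongation rate per template, mass units per second (> 0).
#' @param ssb_blocked if `TRUE`, saturating SSB protein blocks the displaced
#'   strand and no switching ever occurs (switch times degenerate at +Inf).
#' @param query_times sorted non-negative times (seconds) to evaluate.
#' @param seed integer RNG seed.
#' @return An object of class `rcr_sim_config`.
#' @export
sim_config <- function(n_templates, lam, phi, query_times,
                       ssb_blocked = FALSE, seed = 1L) {
  stopifnot(length(n_templates) == 1L, n_templates >= 1,
            n_templates == round(n_templates))
  if (length(lam) != 1L || lam < 0) stop("'lam' must be >= 0", call. = FALSE)
  if (length(phi) != 1L || phi <= 0) stop("'phi' must be > 0", call. = FALSE)
  query_times <- as.numeric(query_times)
  if (length(query_times) == 0L || any(query_times < 0) ||
      is.unsorted(query_times))
    stop("'query_times' must be sorted and non-negative", call. = FALSE)
  structure(
    list(n_templates = as.integer(n_templates), lam = as.numeric(lam),
         phi = as.numeric(phi), ssb_blocked = isTRUE(ssb_blocked),
         query_times = query_times, seed = as.integer(seed)),
    class = "rcr_sim_config"
  )
}

#' ss/dsDNA mass of a single template at time t
#'
#' Deterministic life history given the switch time `tau`: strand
#' displacement until `tau` (ssDNA grows as `phi * t`), fill-in between `tau`
#' and `2 * tau` during which ssDNA is consumed and each incorporated
#' nucleotide yields one base pair (two mass units) of dsDNA, then
#' termination with all mass double-stranded (`2 * phi * tau`).
#'
#' @param tau switch time, seconds (> 0, or `Inf` for a template that never
#'   switches). Vectorized; recycled against `t`.
#' @param phi elongation rate, mass units per second (> 0).
#' @param t query time, seconds (>= 0). Vectorized.
#' @return A list with components `ss` and `ds` (mass units).
#' @examples
#' template_masses(tau = 100, phi = 1, t = 150)  # ss 50, ds 100
#' @export
template_masses <- function(tau, phi, t) {
  if (any(tau <= 0)) stop("'tau' must be positive (or Inf)", call. = FALSE)
  if (any(phi <= 0)) stop("'phi' must be positive", call. = FALSE)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  n <- max(length(tau), length(t))
  tau <- rep_len(tau, n)
  t <- rep_len(t, n)
  displacing <- t < tau
  filling <- !displacing & t < 2 * tau
  ss <- ifelse(displacing, phi * t, ifelse(filling, phi * (2 * tau - t), 0))
  ds <- ifelse(displacing, 0, ifelse(filling, 2 * phi * (t - tau), 2 * phi * tau))
  list(ss = ss, ds = ds)
}

# Population sums at each query time; assumes switch times already sampled.
sim_population <- function(tau, phi, query_times) {
  k <- length(query_times)
  ss <- ds <- numeric(k)
  n_disp <- n_fill <- n_term <- integer(k)
  for (i in seq_len(k)) {
    t <- query_times[i]
    displacing <- tau > t
    terminated <- 2 * tau <= t
    filling <- !displacing & !terminated
    n_disp[i] <- sum(displacing)
    n_fill[i] <- sum(filling)
    n_term[i] <- sum(terminated)
    ss[i] <- phi * (t * n_disp[i] + sum(2 * tau[filling] - t))
    ds[i] <- 2 * phi * (sum(t - tau[filling]) + sum(tau[terminated]))
  }
  data.frame(time_s = query_times, ss_mass = ss, ds_mass = ds,
             n_displacing = n_disp, n_filling = n_fill, n_terminated = n_term)
}

#' Run the per-template stochastic simulation
#'
#' Draws one switch time per template, i.i.d. Exponential(`lam`) (all `+Inf`
#' when `ssb_blocked` or `lam = 0`), and sums the deterministic per-template
#' masses across the population at each query time. Reproducible for a fixed
#' seed; switch times are drawn in template-index order so the result does
#' not depend on the query-time layout.
#'
#' @param config an [sim_config()] object.
#' @return A `data.frame` of class `rcr_sim` with columns `time_s`,
#'   `ss_mass`, `ds_mass`, `n_displacing`, `n_filling`, `n_terminated`; the
#'   configuration is attached as attribute `config`.
#' @export
simulate_rcr <- function(config) {
  if (!inherits(config, "rcr_sim_config"))
    stop("'config' must be created with sim_config()", call. = FALSE)
  tau <- withr::with_seed(config$seed, draw_switch_times(config))
  res <- sim_population(tau, config$phi, config$query_times)
  structure(res, class = c("rcr_sim", "data.frame"), config = config)
}

draw_switch_times <- function(config) {
  if (config$ssb_blocked || config$lam == 0)
    rep(Inf, config$n_templates)
  else
    stats::rexp(config$n_templates, rate = config$lam)
}

#' Exact expectation of the stochastic simulation
#'
#' Delegates to the closed-form model with amplitude
#' `2 * n_templates * phi`; `ssb_blocked` maps to `lam = 0`.
#'
#' @param config an [sim_config()] object.
#' @return An [rcr_timeseries()] of expected masses at `config$query_times`.
#' @export
expected_masses <- function(config) {
  if (!inherits(config, "rcr_sim_config"))
    stop("'config' must be created with sim_config()", call. = FALSE)
  lam <- if (config$ssb_blocked) 0 else config$lam
  p <- model_params(lam = lam, n0 = config$n_templates, phi = config$phi)
  rcr_predict(config$query_times, p)
}

#' Compare the simulator with the closed-form model
#'
#' Runs the simulation and measures, at every query time and for both
#' channels, the deviation of the population total from its closed-form
#' expectation in units of the Monte-Carlo standard error (estimated from
#' the per-template sample standard deviation). Large populations should sit
#' within a few standard errors everywhere; `max_z > threshold` flags a
#' disagreement between the two routes.
#'
#' @param config an [sim_config()] object.
#' @param threshold pass/fail bound on `max_z`, in standard errors.
#' @return A list of class `rcr_sim_validation` with the per-time z-score
#'   table, `max_z`, and `pass`.
#' @export
validate_simulator <- function(config, threshold = 4) {
  if (!inherits(config, "rcr_sim_config"))
    stop("'config' must be created with sim_config()", call. = FALSE)
  tau <- withr::with_seed(config$seed, draw_switch_times(config))
  exp_ts <- expected_masses(config)
  k <- length(config$query_times)
  z_ss <- z_ds <- numeric(k)
  for (i in seq_len(k)) {
    t <- config$query_times[i]
    m <- template_masses(tau, config$phi, rep(t, length(tau)))
    se_ss <- stats::sd(m$ss) * sqrt(length(tau))
    se_ds <- stats::sd(m$ds) * sqrt(length(tau))
    dev_ss <- sum(m$ss) - exp_ts$ss_mass[i]
    dev_ds <- sum(m$ds) - exp_ts$ds_mass[i]
    z_ss[i] <- if (se_ss > 0) dev_ss / se_ss else if (dev_ss == 0) 0 else Inf
    z_ds[i] <- if (se_ds > 0) dev_ds / se_ds else if (dev_ds == 0) 0 else Inf
  }
  max_z <- max(abs(c(z_ss, z_ds)))
  structure(
    list(table = data.frame(time_s = config$query_times, z_ss = z_ss, z_ds = z_ds),
         max_z = max_z, threshold = threshold, pass = max_z <= threshold,
         config = config),
    class = "rcr_sim_validation"
  )
}

#' @export
print.rcr_sim_validation <- function(x, ...) {
  cat(sprintf("Simulator vs closed form: n_templates = %d, %d query times\n",
              x$config$n_templates, nrow(x$table)))
  cat(sprintf("  max |z| = %.3f standard errors (threshold %.1f): %s\n",
              x$max_z, x$threshold, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
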