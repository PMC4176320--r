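#' Measurement noise model for gel densitometry channels
#'
#' Band intensities on a gel scale with the amount loaded, so the dominant
#' error is multiplicative; a small additive term models background. Each
#' observed channel is `truth * LogNormal(mean 1, cv) + Normal(0, sigma)`,
#' floored at zero.
#'
#' @param cv_multiplicative coefficient of variation of the lognormal
#'   multiplicative noise (dimensionless, >= 0). Default 0.10.
#' @param sigma_additive standard deviation of the additive baseline noise,
#'   mass units (>= 0).
#' @param seed integer RNG seed.
#' @return An object of class `rcr_noise`.
#' @export
noise_model <- function(cv_multiplicative = 0.10, sigma_additive = 0,
                        seed = 1L) {
  if (length(cv_multiplicative) != 1L || cv_multiplicative < 0)
    stop("'cv_multiplicative' must be >= 0", call. = FALSE)
  if (length(sigma_additive) != 1L || sigma_additive < 0)
    stop("'sigma_additive' must be >= 0", call. = FALSE)
  structure(
    list(cv_multiplicative = as.numeric(cv_multiplicative),
         sigma_additive = as.numeric(sigma_additive),
         seed = as.integer(seed)),
    class = "rcr_noise"
  )
}

# lognormal factors with mean exactly 1 and the requested CV
lognormal_factors <- function(n, cv) {
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Default measurement time grid, hours
#'
#' Eleven sampling times spanning 1 to 72 h, the span over which an
#' unprotected rolling circle reaction goes from almost pure ssDNA to almost
#' pure dsDNA.
#'
#' @return Numeric vector of hours.
#' @export
default_times_h <- function() c(1, 3, 6, 9, 12, 16, 20, 24, 36, 48, 72)

#' Generate a noisy synthetic measurement table
#'
#' Emulates the two-gel densitometry readout of an RCA time course: a
#' denaturing-PAGE channel observing total DNA (ss + ds) and a native
#' agarose channel observing dsDNA, each independently corrupted by the
#' noise model; the ssDNA channel is then computed by subtraction and
#' floored at zero, mirroring how ssDNA is quantified from real gels. The
#' noiseless truth comes either from the closed-form model (`closed_form`)
#' or from one run of the per-template stochastic simulator (`stochastic`,
#' which adds finite-population fluctuations).
#'
#' @param params an [model_params()] object (the generating truth).
#' @param times_h sampling times in hours, sorted, non-negative.
#' @param noise an [noise_model()] object.
#' @param mode `"closed_form"` or `"stochastic"`.
#' @param n_templates population size for `mode = "stochastic"`.
#' @return A `data.frame` of class `rcr_measurements` with columns `time_h`,
#'   `total_dna`, `ds_dna`, `ss_dna`; generating parameters, noise model and
#'   mode are attached as attributes.
#' @examples
#' p <- model_params(lam = 1.95e-5, amplitude = 50 * 1.95e-5)
#' generate_measurements(p, default_times_h(), noise_model(seed = 7))
#' @export
generate_measurements <- function(params, times_h = default_times_h(),
                                  noise = noise_model(),
                                  mode = c("closed_form", "stochastic"),
                                  n_templates = 10000L) {
  p <- as_params(params)
  mode <- match.arg(mode)
  if (!inherits(noise, "rcr_noise"))
    stop("'noise' must be created with noise_model()", call. = FALSE)
  times_h <- as.numeric(times_h)
  if (length(times_h) == 0L || any(times_h < 0) ||
      is.unsorted(times_h, strictly = TRUE))
    stop("'times_h' must be non-empty, sorted, non-negative", call. = FALSE)
  times_s <- times_h * 3600

  obs <- withr::with_seed(noise$seed, {
    truth <- if (mode == "closed_form") {
      rcr_predict(times_s, p)
    } else {
      phi_sim <- p$amplitude / (2 * n_templates)
      tau <- if (p$lam == 0) rep(Inf, n_templates)
             else stats::rexp(n_templates, rate = p$lam)
      sim_population(tau, phi_sim, times_s)
    }
    truth_total <- truth$ss_mass + truth$ds_mass
    k <- length(times_s)
    total_obs <- truth_total * lognormal_factors(k, noise$cv_multiplicative) +
      stats::rnorm(k, 0, noise$sigma_additive)
    ds_obs <- truth$ds_mass * lognormal_factors(k, noise$cv_multiplicative) +
      stats::rnorm(k, 0, noise$sigma_additive)
    total_obs <- pmax(total_obs, 0)
    ds_obs <- pmax(ds_obs, 0)
    # subtraction first, then floor, as on real gels
    ss_obs <- pmax(total_obs - ds_obs, 0)
    data.frame(time_h = times_h, total_dna = total_obs, ds_dna = ds_obs,
               ss_dna = ss_obs)
  })
  structure(obs, class = c("rcr_measurements", "data.frame"),
            params = p, noise = noise, mode = mode,
            n_templates = as.integer(n_templates))
}
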