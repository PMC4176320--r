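#' Kinetic parameters of the template-switching model
#'
#' Bundles the two quantities that govern all closed-form mass curves: the
#' switching rate constant `lam` (per second per template) and the production
#' amplitude `amplitude` = 2 * n0 * phi (mass units per second), where `n0` is
#' the initial template concentration and `phi` the polymerase elongation
#' rate. Only the product `n0 * phi` is identifiable from mass data, so the
#' public parameterization is `(lam, amplitude)`; `n0` and `phi` are optional
#' metadata. If `amplitude` is omitted it is computed as `2 * n0 * phi`.
#'
#' @param lam switching rate constant, events per second per template (>= 0).
#' @param amplitude production amplitude 2\*n0\*phi, mass units per second
#'   (> 0). May be omitted when both `n0` and `phi` are given.
#' @param n0 optional initial template concentration (templates per volume).
#' @param phi optional polymerase elongation rate (mass units per second per
#'   template).
#' @return An object of class `rcr_params`.
#' @examples
#' model_params(lam = 1.95e-5, amplitude = 1)
#' model_params(lam = 1.95e-5, n0 = 1e4, phi = 25)
#' @export
model_params <- function(lam, amplitude = NULL, n0 = NULL, phi = NULL) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam))
  if (lam < 0) stop("'lam' must be non-negative", call. = FALSE)
  if (is.null(amplitude)) {
    if (is.null(n0) || is.null(phi))
      stop("supply 'amplitude' or both 'n0' and 'phi'", call. = FALSE)
    amplitude <- 2 * n0 * phi
  }
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude))
  if (amplitude <= 0) stop("'amplitude' must be positive", call. = FALSE)
  if (!is.null(n0) && !is.null(phi)) {
    if (abs(amplitude - 2 * n0 * phi) > 1e-9 * abs(amplitude))
      stop("'amplitude' is inconsistent with 2 * n0 * phi", call. = FALSE)
  }
  structure(
    list(lam = as.numeric(lam), amplitude = as.numeric(amplitude),
         n0 = if (is.null(n0)) NA_real_ else as.numeric(n0),
         phi = if (is.null(phi)) NA_real_ else as.numeric(phi)),
    class = "rcr_params"
  )
}

#' @export
print.rcr_params <- function(x, ...) {
  cat("Template-switching kinetic parameters\n")
  cat(sprintf("  lambda    : %.6g /s  (half-life %.3g h)\n", x$lam,
              if (x$lam > 0) log(2) / x$lam / 3600 else Inf))
  cat(sprintf("  amplitude : %.6g mass units /s  (2 n0 phi)\n", x$amplitude))
  if (!is.na(x$n0))  cat(sprintf("  n0        : %.6g templates/volume\n", x$n0))
  if (!is.na(x$phi)) cat(sprintf("  phi       : %.6g mass units /s /template\n", x$phi))
  invisible(x)
}

#' Serialize kinetic parameters to JSON
#'
#' @param params an [model_params()] object.
#' @return A JSON string with fields `lambda_per_s` and `amplitude_per_s`.
#' @export
params_to_json <- function(params) {
  stopifnot(inherits(params, "rcr_params"))
  jsonlite::toJSON(list(lambda_per_s = params$lam,
                        amplitude_per_s = params$amplitude),
                   auto_unbox = TRUE, digits = NA)
}

#' Deserialize kinetic parameters from JSON
#'
#' @param json a JSON string or path to a JSON file produced by
#'   [params_to_json()].
#' @return An [model_params()] object.
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  model_params(lam = x$lambda_per_s, amplitude = x$amplitude_per_s)
}
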