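#' Write a measurement table to CSV
#'
#' Comma-separated, dot decimal, UTF-8, header row
#' `time_h,total_dna,ds_dna,ss_dna`, preceded by `#`-prefixed provenance
#' comment lines recording the generating parameters, noise model, mode and
#' package version when the table carries them.
#'
#' @param x an `rcr_measurements` table (or any data frame with the four
#'   columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path) {
  cols <- c("time_h", "total_dna", "ds_dna", "ss_dna")
  if (!all(cols %in% names(x)))
    stop("table must have columns ", paste(cols, collapse = ", "), call. = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# rcaswitch ", as.character(utils::packageVersion("rcaswitch")),
                    " measurement table"), con)
  p <- attr(x, "params")
  if (inherits(p, "rcr_params"))
    writeLines(sprintf("# lambda_per_s=%.10g amplitude_per_s=%.10g",
                       p$lam, p$amplitude), con)
  nz <- attr(x, "noise")
  if (inherits(nz, "rcr_noise"))
    writeLines(sprintf("# cv=%.10g sigma=%.10g seed=%d mode=%s",
                       nz$cv_multiplicative, nz$sigma_additive, nz$seed,
                       attr(x, "mode") %||% "unknown"), con)
  utils::write.csv(as.data.frame(x)[cols], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a measurement table from CSV
#'
#' Reads the dialect written by [write_measurements()]; `#` comment lines
#' are skipped. The schema is validated: the four columns must be present,
#' times sorted strictly increasing and non-negative, masses non-negative —
#' violations raise an error naming the offending column.
#'
#' @param path CSV file path.
#' @return An `rcr_measurements` data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, comment.char = "#")
  cols <- c("time_h", "total_dna", "ds_dna", "ss_dna")
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop("malformed CSV: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cc in cols) {
    if (!is.numeric(x[[cc]]))
      stop("malformed CSV: column '", cc, "' is not numeric", call. = FALSE)
    x[[cc]] <- as.numeric(x[[cc]])
  }
  if (any(x$time_h < 0) || is.unsorted(x$time_h, strictly = TRUE))
    stop("malformed CSV: column 'time_h' must be strictly increasing and non-negative",
         call. = FALSE)
  for (cc in cols[-1]) {
    if (any(x[[cc]] < 0))
      stop("malformed CSV: column '", cc, "' has negative values", call. = FALSE)
  }
  structure(x[cols], class = c("rcr_measurements", "data.frame"))
}

#' Write a fit result to JSON
#'
#' @param fit an [fit_switching()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  if (!inherits(fit, "rcr_fit")) stop("'fit' must be an rcr_fit", call. = FALSE)
  jsonlite::write_json(
    list(lam_per_s = fit$lam_hat,
         lam_sd_per_s = fit$lam_sd,
         amplitude_per_s = fit$amplitude_hat,
         amplitude_sd_per_s = fit$amplitude_sd,
         half_life_h = fit$half_life_h,
         rss = fit$rss,
         n_points = fit$n_points,
         converged = fit$converged,
         n_iter = fit$n_iter,
         channels = fit$config$channels,
         message = fit$message),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Write a time series to CSV
#'
#' Same dialect as [write_measurements()]; model predictions and simulator
#' output are written with times converted to hours and `total_dna` =
#' `ss_dna` + `ds_dna`.
#'
#' @param ts an [rcr_timeseries()] (or `rcr_sim` result).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  if (!all(c("time_s", "ss_mass", "ds_mass") %in% names(ts)))
    stop("'ts' must have time_s, ss_mass, ds_mass columns", call. = FALSE)
  total <- ts$ss_mass + ts$ds_mass
  # the ss channel of a written table is by convention total - ds
  out <- data.frame(time_h = ts$time_s / 3600,
                    total_dna = total,
                    ds_dna = ts$ds_mass,
                    ss_dna = pmax(total - ts$ds_mass, 0))
  write_measurements(out, path)
}
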