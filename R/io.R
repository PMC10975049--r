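# Delimited-text IO for the trial tables.

#' Read / write a long-format measurement table
#'
#' The on-disk format is tab-separated with header columns
#' `participant_id`, `arm`, `timepoint`, `endpoint_id`, `value` -- one row
#' per measurement.
#'
#' @param measurements Measurement tibble.
#' @param path File path.
#' @param registry Optional registry; when supplied the measurements are
#'   validated against it on read.
#' @return `write_measurements()` returns the path invisibly;
#'   `read_measurements()` returns a tibble.
#' @export
write_measurements <- function(measurements, path) {
  readr::write_tsv(measurements, path)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path, registry = NULL) {
  m <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         participant_id = "c", arm = "c", timepoint = "c",
                         endpoint_id = "c", value = "d"))
  if (!is.null(registry)) .validate_measurements(m, registry)
  m
}

#' Read / write a participant covariate table
#'
#' Tab-separated with columns `participant_id`, `gender` (M/F),
#' `bmi_class` (normal 18.5-24.9 / overweight 25.0-29.9) and
#' `visit_order` (treatment-sequence label).
#'
#' @param covariates Covariate tibble.
#' @param path File path.
#' @return `write_covariates()` returns the path invisibly;
#'   `read_covariates()` returns a tibble.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_tsv(covariates, path)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}
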