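#' Write a clustered sample to CSV with a JSON metadata sidecar
#'
#' The CSV is long format with header `cluster,x,y`, one row per
#' observation. A `<path>.json` sidecar records the generating spec and the
#' realized `sd_shift`, `sample_icc` and attempt count so a generated
#' sample is self-describing.
#'
#' @param sample A `clustered_sample`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample <- function(sample, path) {
  stopifnot(inherits(sample, "clustered_sample"))
  utils::write.csv(sample$data, path, row.names = FALSE)
  meta <- c(
    sample$spec[!vapply(sample$spec, is.null, logical(1))],
    list(sample_icc = sample$sample_icc,
         x_dispersion = sample$x_dispersion,
         attempts = sample$attempts)
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a clustered sample from CSV
#'
#' Reads a long-format `cluster,x,y` CSV (as written by [write_sample()],
#' or any user data in that shape) into a data frame suitable for
#' [fit_ols()] and [fit_ri()]. Realized generative components are not
#' recoverable from data, so the result is a plain tibble, not a
#' `clustered_sample`.
#'
#' @param path CSV path.
#' @return Tibble with columns `cluster`, `x`, `y`.
#' @export
read_sample <- function(path) {
  data <- tibble::as_tibble(utils::read.csv(path))
  miss <- setdiff(c("cluster", "x", "y"), names(data))
  if (length(miss))
    stop(sprintf("%s lacks required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  data
}
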