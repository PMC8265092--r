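#' The six ICC levels of the simulation grid
#'
#' Each level pairs a cluster-level error SD (`sd_u`) with the target range
#' of admissible sample ICC used by the acceptance-rejection generator.
#' With an individual-level error SD of 1, `sd_u` is chosen so that the
#' expected sample ICC, `sd_u^2 / (sd_u^2 + 1)`, sits at the midpoint of the
#' target range; levels are labelled by those midpoints.
#'
#' @return A tibble with columns `level` (character label, e.g. `"0.01"`),
#'   `sd_u`, `icc_low`, `icc_high` and `icc_mid` (numeric midpoint label).
#' @examples
#' icc_grid()
#' @export
icc_grid <- function() {
  tibble::tibble(
    level    = c("0.001", "0.003", "0.01", "0.03", "0.1", "0.3"),
    icc_mid  = c(0.001, 0.003, 0.01, 0.03, 0.1, 0.3),
    sd_u     = c(0.0316, 0.05485, 0.1005, 0.1759, 0.3333, 0.6547),
    icc_low  = c(0.0005, 0.0025, 0.005, 0.025, 0.05, 0.25),
    icc_high = c(0.00149, 0.00349, 0.0149, 0.0349, 0.149, 0.349)
  )
}

#' The target prevalences of the binary-x grid
#' @return Numeric vector `c(0.05, 0.1, 0.2, 0.4)`.
#' @export
target_prevalence_grid <- function() c(0.05, 0.1, 0.2, 0.4)

#' Map a cluster-level SD to the implied ICC
#'
#' Computes `sd_u^2 / (sd_u^2 + sd_e^2)`, the intraclass correlation of the
#' outcome implied by the two variance components of a random-intercept
#' model.
#'
#' @param sd_u Non-negative cluster-level error SD.
#' @param sd_e Positive individual-level error SD (default 1).
#' @return ICC in `[0, 1)`.
#' @examples
#' icc_from_components(0.6547) # ~0.30
#' @export
icc_from_components <- function(sd_u, sd_e = 1) {
  stopifnot(all(sd_u >= 0), all(sd_e > 0))
  sd_u^2 / (sd_u^2 + sd_e^2)
}
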