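#' Parameterize one clustered-data generating scenario
#'
#' A `simulation_spec` fully describes one generative scenario of the study:
#' balanced cluster geometry, fixed effects, variance components, the type
#' and between-cluster shift of the explanatory variable, and the sample-ICC
#' target range used by the acceptance-rejection generator
#' ([generate_accepted_sample()]).
#'
#' The generative model is the random-intercept model
#' \deqn{y_{ij} = \beta_0 + \beta_1 x_{ij} + u_j + e_{ij},}
#' with \eqn{u_j \sim N(0, sd_u^2)} and \eqn{e_{ij} \sim N(0, sd_e^2)}.
#' For continuous x, \eqn{x_{ij} = x_{0ij} + shift_j} with
#' \eqn{x_{0ij} \sim N(0,1)} and \eqn{shift_j \sim N(0, sd_{shift}^2)}.
#' For binary x, each cluster is assigned the prevalence
#' `target_prevalence + shift_j` (clipped to `[0, 1]`) and the per-cluster
#' count of ones is the prevalence times the cluster size, rounded half away
#' from zero.
#'
#' @param n_clusters Number of clusters (default 100).
#' @param cluster_size Observations per cluster (default 100).
#' @param beta0 Fixed intercept (default 0).
#' @param beta1 True slope: 1 for effect scenarios, 0 for Type I scenarios.
#' @param sd_e Individual-level error SD (> 0, default 1).
#' @param sd_u Cluster-level error SD (>= 0).
#' @param icc_target_range Length-2 numeric `[low, high]` of admissible
#'   sample ICC, or `NULL` to accept any sample.
#' @param x_type `"continuous"` or `"binary"`.
#' @param sd_shift SD of the per-cluster shift distribution.
#' @param target_prevalence Target prevalence in (0,1); required iff
#'   `x_type == "binary"`.
#' @param max_attempts Cap on acceptance-rejection iterations (default 10000).
#' @return An object of class `"simulation_spec"` (a validated list).
#' @examples
#' spec <- simulation_spec(sd_u = 0.6547, icc_target_range = c(0.25, 0.349),
#'                         x_type = "continuous", sd_shift = 5)
#' spec
#' @export
simulation_spec <- function(n_clusters = 100,
                            cluster_size = 100,
                            beta0 = 0,
                            beta1 = 1,
                            sd_e = 1,
                            sd_u = 0,
                            icc_target_range = NULL,
                            x_type = c("continuous", "binary"),
                            sd_shift = 0,
                            target_prevalence = NULL,
                            max_attempts = 10000L) {
  x_type <- match.arg(x_type)
  stopifnot(
    length(n_clusters) == 1, n_clusters >= 1, n_clusters == round(n_clusters),
    length(cluster_size) == 1, cluster_size >= 1,
    cluster_size == round(cluster_size),
    is.numeric(beta0), is.numeric(beta1),
    sd_e > 0, sd_u >= 0, sd_shift >= 0,
    max_attempts >= 1
  )
  if (!is.null(icc_target_range)) {
    stopifnot(length(icc_target_range) == 2,
              icc_target_range[1] < icc_target_range[2],
              icc_target_range[1] >= 0, icc_target_range[2] < 1)
  }
  if (x_type == "binary") {
    if (is.null(target_prevalence))
      stop("`target_prevalence` is required when x_type = \"binary\"")
    stopifnot(target_prevalence > 0, target_prevalence < 1)
  } else if (!is.null(target_prevalence)) {
    stop("`target_prevalence` only applies to x_type = \"binary\"")
  }
  structure(
    list(
      n_clusters = as.integer(n_clusters),
      cluster_size = as.integer(cluster_size),
      beta0 = beta0, beta1 = beta1,
      sd_e = sd_e, sd_u = sd_u,
      icc_target_range = icc_target_range,
      x_type = x_type,
      sd_shift = sd_shift,
      target_prevalence = target_prevalence,
      max_attempts = as.integer(max_attempts)
    ),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("<simulation_spec>\n")
  cat(sprintf("  geometry: %d clusters x %d obs\n", x$n_clusters, x$cluster_size))
  cat(sprintf("  fixed effects: beta0 = %g, beta1 = %g\n", x$beta0, x$beta1))
  cat(sprintf("  variance components: sd_u = %g, sd_e = %g (ICC = %.4g)\n",
              x$sd_u, x$sd_e, icc_from_components(x$sd_u, x$sd_e)))
  cat(sprintf("  x: %s, sd_shift = %g%s\n", x$x_type, x$sd_shift,
              if (x$x_type == "binary")
                sprintf(", target prevalence = %g", x$target_prevalence)
              else ""))
  if (!is.null(x$icc_target_range))
    cat(sprintf("  sample-ICC target range: [%g, %g]\n",
                x$icc_target_range[1], x$icc_target_range[2]))
  invisible(x)
}

# Probability that the realized sample ICC lands in the target range, with
# V_e treated as fixed at sd_e^2 (it is tightly concentrated at n = J * m):
# V_u ~ sd_u^2 * chisq(J - 1) / (J - 1), ICC = V_u / (V_u + sd_e^2).
acceptance_probability <- function(spec) {
  if (is.null(spec$icc_target_range)) return(1)
  if (spec$sd_u == 0)
    return(as.numeric(spec$icc_target_range[1] <= 0))
  df <- spec$n_clusters - 1L
  vu_bounds <- spec$icc_target_range / (1 - spec$icc_target_range) * spec$sd_e^2
  q <- vu_bounds * df / spec$sd_u^2
  stats::pchisq(q[2], df) - stats::pchisq(q[1], df)
}

# Hard error when a scenario cannot plausibly yield accepted samples.
check_feasible <- function(spec, min_prob = 1e-6) {
  p <- acceptance_probability(spec)
  if (p < min_prob) {
    stop(sprintf(
      paste0("infeasible scenario: sd_u = %g with ICC target range [%g, %g] ",
             "has acceptance probability %.3g"),
      spec$sd_u, spec$icc_target_range[1], spec$icc_target_range[2], p))
  }
  invisible(p)
}
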