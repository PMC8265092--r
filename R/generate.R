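#' Draw a between-cluster shift SD
#'
#' The study draws the SD of the per-cluster shift distribution uniformly:
#' `U[0, 20]` for a continuous explanatory variable, `U[0, 0.05]` for a
#' binary one (where the shift perturbs cluster prevalences).
#'
#' @param x_type `"continuous"` or `"binary"`.
#' @param n Number of draws (default 1).
#' @return Numeric vector of non-negative shift SDs.
#' @export
draw_sd_shift <- function(x_type = c("continuous", "binary"), n = 1) {
  x_type <- match.arg(x_type)
  stats::runif(n, 0, if (x_type == "continuous") 20 else 0.05)
}

#' Generate a clustered continuous explanatory variable
#'
#' `x_ij = x0_ij + shift_j` with `x0_ij ~ N(0, 1)` i.i.d. and
#' `shift_j ~ N(0, sd_shift^2)` per cluster, so the within-cluster variance
#' of x is 1 regardless of how strongly x is clustered.
#'
#' @param spec A [simulation_spec()] with `x_type = "continuous"`.
#' @return List with `x` (length `n_clusters * cluster_size`) and `shift`
#'   (length `n_clusters`).
#' @export
generate_continuous_x <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"), spec$x_type == "continuous")
  shift <- stats::rnorm(spec$n_clusters, 0, spec$sd_shift)
  x0 <- stats::rnorm(spec$n_clusters * spec$cluster_size)
  list(x = x0 + rep(shift, each = spec$cluster_size), shift = shift)
}

#' Generate a clustered binary explanatory variable
#'
#' Each cluster is assigned prevalence
#' `p_j = clip(target_prevalence + shift_j, 0, 1)` with
#' `shift_j ~ N(0, sd_shift^2)`; within cluster j the first
#' `round(cluster_size * p_j)` observations (half away from zero) are set to
#' 1 and the rest to 0. The position of the ones within a cluster carries no
#' information under the exchangeable outcome model.
#'
#' @param spec A [simulation_spec()] with `x_type = "binary"`.
#' @return List with `x` (0/1 vector), `cluster_prevalence` (assigned,
#'   clipped prevalence per cluster) and `shift`.
#' @export
generate_binary_x <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"), spec$x_type == "binary")
  m <- spec$cluster_size
  shift <- stats::rnorm(spec$n_clusters, 0, spec$sd_shift)
  p <- pmin(pmax(spec$target_prevalence + shift, 0), 1)
  ones <- floor(m * p + 0.5) # round half away from zero (p >= 0)
  within <- rep(seq_len(m), spec$n_clusters)
  list(
    x = as.numeric(within <= rep(ones, each = m)),
    cluster_prevalence = p,
    shift = shift
  )
}

#' Generate outcomes under the random-intercept model
#'
#' `y_ij = beta0 + beta1 * x_ij + u_j + e_ij` with `u_j ~ N(0, sd_u^2)` and
#' `e_ij ~ N(0, sd_e^2)`, independent of x and of each other.
#'
#' @param x Explanatory values, ordered by cluster.
#' @param spec A [simulation_spec()].
#' @return List with `y`, `u` (length `n_clusters`) and `e` (length of `x`).
#' @export
generate_outcome <- function(x, spec) {
  stopifnot(inherits(spec, "simulation_spec"),
            length(x) == spec$n_clusters * spec$cluster_size)
  u <- stats::rnorm(spec$n_clusters, 0, spec$sd_u)
  e <- stats::rnorm(length(x), 0, spec$sd_e)
  list(y = spec$beta0 + spec$beta1 * x + rep(u, each = spec$cluster_size) + e,
       u = u, e = e)
}

#' Sample ICC from realized error draws
#'
#' The ICC of a simulated sample, computed from the realized cluster-level
#' and individual-level error draws as `var(u) / (var(u) + var(e))` with
#' unbiased (n - 1) sample variances. This is the quantity the
#' acceptance-rejection generator controls by construction.
#'
#' @param u Realized cluster-level errors (length >= 2).
#' @param e Realized individual-level errors (length >= 2).
#' @return ICC in `[0, 1)`.
#' @export
realized_sample_icc <- function(u, e) {
  stopifnot(length(u) >= 2, length(e) >= 2)
  vu <- stats::var(u)
  ve <- stats::var(e)
  if (vu + ve == 0)
    stop("sample ICC is not estimable: all realized errors are equal")
  vu / (vu + ve)
}

new_clustered_sample <- function(spec, cluster_id, x, y, u, e, shift,
                                 cluster_prevalence = NULL,
                                 sample_icc, attempts = 1L) {
  data <- tibble::new_tibble(list(cluster = cluster_id, x = x, y = y),
                             nrow = length(x))
  smp <- structure(
    list(
      data = data,
      spec = spec,
      u = u, e = e, shift = shift,
      cluster_prevalence = cluster_prevalence,
      sample_icc = sample_icc,
      attempts = as.integer(attempts)
    ),
    class = "clustered_sample"
  )
  smp$x_dispersion <- x_dispersion(smp)
  smp
}

#' @export
print.clustered_sample <- function(x, ...) {
  cat("<clustered_sample>\n")
  cat(sprintf("  %d observations in %d clusters (%s x)\n",
              nrow(x$data), x$spec$n_clusters, x$spec$x_type))
  cat(sprintf("  sample ICC = %.4g, x dispersion = %.4g, attempts = %d\n",
              x$sample_icc, x$x_dispersion, x$attempts))
  invisible(x)
}

#' @export
as.data.frame.clustered_sample <- function(x, ...) as.data.frame(x$data)

#' Generate one clustered sample (single attempt, no ICC screening)
#'
#' Draws x (continuous or binary per the spec), then the outcome, and
#' records realized components and the sample ICC. Use
#' [generate_accepted_sample()] for the acceptance-rejection version.
#'
#' @param spec A [simulation_spec()].
#' @return A `clustered_sample`.
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  cluster_id <- rep(seq_len(spec$n_clusters) - 1L, each = spec$cluster_size)
  if (spec$x_type == "continuous") {
    xp <- generate_continuous_x(spec)
    prev <- NULL
  } else {
    xp <- generate_binary_x(spec)
    prev <- xp$cluster_prevalence
  }
  out <- generate_outcome(xp$x, spec)
  new_clustered_sample(
    spec, cluster_id, xp$x, out$y, out$u, out$e, xp$shift,
    cluster_prevalence = prev,
    sample_icc = realized_sample_icc(out$u, out$e)
  )
}

#' Generate a clustered sample whose ICC falls in the target range
#'
#' Repeatedly generates complete samples (x, shifts and outcome are all
#' redrawn each attempt, keeping the same `sd_shift`) until the sample ICC
#' falls inside `spec$icc_target_range`, or errors after
#' `spec$max_attempts` attempts. The number of attempts used is recorded on
#' the returned sample.
#'
#' @param spec A [simulation_spec()] with a non-NULL `icc_target_range`.
#' @param icc_method How the screening ICC is computed: `"realized"`
#'   (default; from the simulated `u` and `e` draws) or `"fitted"` (from the
#'   random-intercept model's estimated variance components, one extra model
#'   fit per attempt).
#' @return A `clustered_sample` with `sample_icc` inside the target range.
#' @export
generate_accepted_sample <- function(spec,
                                     icc_method = c("realized", "fitted")) {
  icc_method <- match.arg(icc_method)
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(spec$icc_target_range))
    stop("spec has no `icc_target_range`; use generate_sample()")
  check_feasible(spec)
  lo <- spec$icc_target_range[1]
  hi <- spec$icc_target_range[2]
  for (attempt in seq_len(spec$max_attempts)) {
    smp <- generate_sample(spec)
    icc <- if (icc_method == "realized") smp$sample_icc
           else fit_ri(smp)$icc_hat
    if (icc >= lo && icc <= hi) {
      smp$sample_icc <- icc
      smp$attempts <- attempt
      return(smp)
    }
  }
  stop(sprintf(
    paste0("no sample with ICC in [%g, %g] after %d attempts ",
           "(sd_u = %g, sd_shift = %g, x_type = %s)"),
    lo, hi, spec$max_attempts, spec$sd_u, spec$sd_shift, spec$x_type))
}

#' Between-cluster dispersion of the explanatory variable
#'
#' The SD across clusters of the per-cluster mean of x. For binary x the
#' cluster mean is the realized cluster prevalence, so this is the SD of
#' realized prevalences. Computed with the unbiased (n - 1) sample SD.
#'
#' @param sample A `clustered_sample`, or a data frame with columns
#'   `cluster` and `x`.
#' @return Non-negative scalar.
#' @export
x_dispersion <- function(sample) {
  data <- if (inherits(sample, "clustered_sample")) sample$data else sample
  stopifnot(all(c("cluster", "x") %in% names(data)))
  sums <- cluster_sums(data$x, data$cluster)
  means <- if (!is.null(sums)) sums / (nrow(data) / length(sums))
           else tapply(data$x, data$cluster, mean)
  if (length(means) < 2)
    stop("x dispersion is not estimable with a single cluster")
  stats::sd(means)
}
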