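# Independent oracles for the random-intercept fitter.
#
# oracle_ri_ml maximizes the exact multivariate-normal likelihood with an
# explicitly assembled block covariance matrix, optimizing over the two SDs
# directly (multi-start L-BFGS-B, fixed effects profiled out by dense GLS).
# It shares no code with the package's profiled balanced-design fitter.

dense_gls <- function(data, sd_u, sd_e) {
  y <- data$y
  X <- cbind(1, data$x)
  Z <- outer(data$cluster, sort(unique(data$cluster)), `==`) * 1
  V <- sd_u^2 * tcrossprod(Z) + diag(sd_e^2, length(y))
  Vi <- chol2inv(chol(V))
  M <- crossprod(X, Vi %*% X)
  b <- drop(solve(M, crossprod(X, Vi %*% y)))
  list(beta0 = b[1], beta1 = b[2], se_beta1 = sqrt(solve(M)[2, 2]))
}

oracle_ri_ml <- function(data) {
  y <- data$y
  X <- cbind(1, data$x)
  n <- length(y)
  Z <- outer(data$cluster, sort(unique(data$cluster)), `==`) * 1
  ZZt <- tcrossprod(Z)
  nll <- function(par) {
    V <- par[1]^2 * ZZt + diag(par[2]^2, n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi <- chol2inv(ch)
    M <- crossprod(X, Vi %*% X)
    b <- tryCatch(solve(M, crossprod(X, Vi %*% y)),
                  error = function(e) NULL)
    if (is.null(b)) return(1e10)
    r <- y - X %*% b
    sum(log(diag(ch))) + 0.5 * drop(crossprod(r, Vi %*% r))
  }
  sy <- max(stats::sd(y), 1e-3)
  best <- NULL
  for (st in list(c(0.3 * sy, sy), c(1e-4, sy), c(sy, 0.3 * sy),
                  c(0.5 * sy, 0.5 * sy))) {
    o <- stats::optim(st, nll, method = "L-BFGS-B", lower = c(0, 1e-8),
                      control = list(factr = 10, maxit = 1000,
                                     ndeps = c(1e-7, 1e-7)))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish: a derivative-free pass from the best point
  p <- stats::optim(best$par, function(par)
    if (any(par < c(0, 1e-8))) 1e10 else nll(par),
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 2000))
  if (p$value <= best$value) best <- p
  g <- dense_gls(data, best$par[1], best$par[2])
  c(g, list(sd_u = best$par[1], sd_e = best$par[2], nll = best$value))
}

# A random tiny balanced clustered dataset (no package generator involved).
tiny_clustered_data <- function(n_clusters, cluster_size, sd_u = NULL,
                                sd_e = 1) {
  if (is.null(sd_u)) sd_u <- stats::runif(1, 0, 1.5)
  u <- stats::rnorm(n_clusters, 0, sd_u)
  x <- stats::rnorm(n_clusters * cluster_size)
  y <- 0.5 + x + rep(u, each = cluster_size) +
    stats::rnorm(length(x), 0, sd_e)
  tibble::tibble(cluster = rep(seq_len(n_clusters), each = cluster_size),
                 x = x, y = y)
}
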