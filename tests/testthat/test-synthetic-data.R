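test_that("shift SDs are uniform on the type-specific range", {
  set.seed(11)
  d <- draw_sd_shift("continuous", n = 10000)
  expect_true(all(d >= 0 & d <= 20))
  expect_equal(mean(d), 10, tolerance = 0.03)          # MC, +/- ~3 SEs
  expect_equal(stats::sd(d), 20 / sqrt(12), tolerance = 0.02)
  b <- draw_sd_shift("binary", n = 10000)
  expect_true(all(b >= 0 & b <= 0.05))
  expect_equal(mean(b), 0.025, tolerance = 0.03)
})

test_that("continuous x has unit within-cluster variance and the expected
           between-cluster dispersion", {
  set.seed(21)
  spec0 <- simulation_spec(x_type = "continuous", sd_shift = 0)
  g0 <- generate_continuous_x(spec0)
  expect_identical(g0$shift, rep(0, 100))
  m <- matrix(g0$x, 100, 100)
  # SD of cluster means of iid N(0,1): 1/sqrt(cluster_size)
  expect_equal(stats::sd(colMeans(m)), 0.1, tolerance = 0.25)

  spec20 <- simulation_spec(x_type = "continuous", sd_shift = 20)
  g20 <- generate_continuous_x(spec20)
  m20 <- matrix(g20$x, 100, 100)
  expect_equal(stats::sd(colMeans(m20)), 20, tolerance = 0.25)
  # within-cluster variance stays 1 no matter how clustered x is
  expect_equal(mean(apply(m20, 2, stats::var)), 1, tolerance = 0.05)

  spec1 <- simulation_spec(n_clusters = 1, x_type = "continuous",
                           sd_shift = 3)
  g1 <- generate_continuous_x(spec1)
  expect_length(g1$x, 100)
  expect_length(g1$shift, 1)
})

test_that("binary x honours per-cluster counts, rounding and clipping", {
  # fixed prevalence 0.223 must give exactly 22 ones in every cluster
  set.seed(31)
  spec <- simulation_spec(x_type = "binary", sd_shift = 0,
                          target_prevalence = 0.223)
  g <- generate_binary_x(spec)
  counts <- colSums(matrix(g$x, 100, 100))
  expect_true(all(counts == 22))

  # no shift, prevalence 0.4: every cluster has exactly 40 ones, zero
  # dispersion
  spec40 <- simulation_spec(x_type = "binary", sd_shift = 0,
                            target_prevalence = 0.4)
  s40 <- generate_sample(spec40)
  expect_true(all(colSums(matrix(s40$data$x, 100, 100)) == 40))
  expect_equal(s40$x_dispersion, 0)

  # count identity holds for every cluster under random shifts
  for (seed in 1:10) {
    set.seed(seed)
    sp <- simulation_spec(x_type = "binary",
                          sd_shift = stats::runif(1, 0, 0.05),
                          target_prevalence = sample(c(0.05, 0.1, 0.2, 0.4), 1))
    gb <- generate_binary_x(sp)
    counts <- colSums(matrix(gb$x, sp$cluster_size, sp$n_clusters))
    expect_identical(counts, floor(sp$cluster_size * gb$cluster_prevalence + 0.5))
  }

  # negative assigned prevalences are clipped to zero -> all-zero clusters
  set.seed(32)
  spc <- simulation_spec(x_type = "binary", sd_shift = 0.2,
                         target_prevalence = 0.05)
  gc <- generate_binary_x(spc)
  expect_true(all(gc$cluster_prevalence >= 0))
  zero <- which(gc$cluster_prevalence == 0)
  expect_gt(length(zero), 0)
  counts <- colSums(matrix(gc$x, 100, 100))
  expect_true(all(counts[zero] == 0))
})

test_that("outcomes follow the random-intercept generative model", {
  # noiseless limit: y collapses to x
  set.seed(41)
  spec <- simulation_spec(x_type = "continuous", sd_u = 0, sd_e = 1e-12)
  x <- stats::rnorm(spec$n_clusters * spec$cluster_size)
  out <- generate_outcome(x, spec)
  expect_equal(out$y, x, tolerance = 1e-9)

  # variance decomposition: var(y - x) = sd_u^2 + sd_e^2 at beta1 = 1
  set.seed(42)
  spec2 <- simulation_spec(n_clusters = 100, cluster_size = 1000,
                           x_type = "continuous", sd_u = 0.6547)
  x2 <- stats::rnorm(1e5)
  out2 <- generate_outcome(x2, spec2)
  expect_equal(stats::var(out2$y - x2), 0.6547^2 + 1, tolerance = 0.15)

  # null slope: y does not depend on x
  set.seed(43)
  spec0 <- simulation_spec(beta1 = 0, x_type = "continuous", sd_u = 0.3)
  x0 <- stats::rnorm(1e4)
  out0 <- generate_outcome(x0, spec0)
  expect_lt(abs(stats::cor(x0, out0$y)), 0.05)
})

test_that("realized sample ICC is the variance share of the cluster errors", {
  expect_equal(realized_sample_icc(rep(0, 10), stats::rnorm(50)), 0)
  expect_equal(realized_sample_icc(c(-1, 1), c(-1, 1)), 0.5)
  set.seed(51)
  expect_equal(
    realized_sample_icc(stats::rnorm(5000, 0, 0.6547), stats::rnorm(5000)),
    0.3, tolerance = 0.05)
  expect_error(realized_sample_icc(rep(1, 5), rep(2, 5)), "not estimable")
})

test_that("acceptance-rejection delivers samples inside the ICC target range
           and fails loudly when it cannot", {
  set.seed(61)
  spec <- simulation_spec(n_clusters = 100, cluster_size = 20,
                          sd_u = 0.6547, icc_target_range = c(0.25, 0.349),
                          x_type = "continuous", sd_shift = 2)
  for (i in 1:50) {
    smp <- generate_accepted_sample(spec)
    expect_true(smp$sample_icc >= 0.25 && smp$sample_icc <= 0.349)
    expect_gte(smp$attempts, 1)
  }

  # an ICC of exactly zero can never reach the range: rejected up front
  spec0 <- simulation_spec(sd_u = 0, icc_target_range = c(0.25, 0.349),
                           x_type = "continuous", max_attempts = 10)
  expect_error(generate_accepted_sample(spec0), "infeasible")

  # feasible but improbable range: the attempt cap is a hard error
  set.seed(62)
  specn <- simulation_spec(sd_u = 0.6547,
                           icc_target_range = c(0.25, 0.2501),
                           x_type = "continuous", sd_shift = 1,
                           max_attempts = 3)
  expect_error(generate_accepted_sample(specn), "after 3 attempts")

  # fitted-ICC screening is available and also lands in range
  set.seed(63)
  smp_f <- generate_accepted_sample(spec, icc_method = "fitted")
  expect_true(smp_f$sample_icc >= 0.25 && smp_f$sample_icc <= 0.349)
})

test_that("identical spec and seed reproduce the sample bit for bit", {
  spec <- simulation_spec(sd_u = 0.1005, icc_target_range = c(0.005, 0.0149),
                          x_type = "binary", sd_shift = 0.02,
                          target_prevalence = 0.2)
  set.seed(71); a <- generate_accepted_sample(spec)
  set.seed(71); b <- generate_accepted_sample(spec)
  expect_identical(a$data, b$data)
  expect_identical(a$u, b$u)
  expect_identical(a$sample_icc, b$sample_icc)
})

test_that("x dispersion is the between-cluster SD of cluster means", {
  d <- tibble::tibble(cluster = c(0, 0, 1, 1), x = c(0, 0, 2, 2))
  expect_equal(x_dispersion(d), sqrt(2))
  expect_equal(x_dispersion(tibble::tibble(cluster = rep(1:3, each = 2),
                                           x = rep(5, 6))), 0)
  expect_error(x_dispersion(tibble::tibble(cluster = rep(1, 4),
                                           x = stats::rnorm(4))),
               "single cluster")
})

test_that("continuous dispersion recovers sd_shift^2 + 1/cluster_size on
           average", {
  set.seed(81)
  spec <- simulation_spec(n_clusters = 50, cluster_size = 25,
                          x_type = "continuous", sd_shift = 1.5)
  disp2 <- replicate(300, x_dispersion(generate_sample(spec))^2)
  expect_equal(mean(disp2), 1.5^2 + 1 / 25, tolerance = 0.05)
})
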