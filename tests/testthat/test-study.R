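small_plan <- function(beta1_true = 1, master_seed = 7) {
  study_plan(
    "continuous",
    icc_levels = icc_grid()[c(3, 6), ],
    n_shift_values = 2, replicates_per_shift = 2,
    beta1_true = beta1_true, master_seed = master_seed,
    n_clusters = 50, cluster_size = 20
  )
}

test_that("run_study produces one tidy record pair per replicate", {
  rec <- run_study(small_plan())
  expect_s3_class(rec, "tbl_df")
  # 2 scenarios x 2 shift values x 2 replicates x 2 models
  expect_equal(nrow(rec), 16)
  expect_setequal(unique(rec$model), c("OLS", "RI"))
  expect_setequal(unique(rec$icc_level), c("0.01", "0.3"))
  expect_true(all(c("scenario_id", "sd_shift", "sample_icc", "x_dispersion",
                    "beta1_hat", "se_beta1", "ci_low", "ci_high", "p_value",
                    "sd_u_hat", "sd_e_hat", "converged") %in% names(rec)))
  # accepted ICCs sit inside each scenario's target range
  grid <- icc_grid()
  for (lev in c("0.01", "0.3")) {
    g <- grid[grid$level == lev, ]
    icc <- rec$sample_icc[rec$icc_level == lev]
    expect_true(all(icc >= g$icc_low & icc <= g$icc_high))
  }
})

test_that("the seed schedule makes studies bit-reproducible and
           order-independent", {
  a <- run_study(small_plan())
  b <- run_study(small_plan())
  expect_identical(a, b)

  # a plan holding only the first scenario reproduces exactly its slice of
  # the full run (the seed schedule keys on the scenario index)
  plan_first <- small_plan()
  plan_first$icc_levels <- icc_grid()[3, ]
  first <- run_study(plan_first)
  expect_identical(first[, -1], a[a$icc_level == "0.01", ][, -1])

  # different master seeds give different draws
  c2 <- run_study(small_plan(master_seed = 8))
  expect_false(identical(a$beta1_hat, c2$beta1_hat))
})

test_that("checkpointing resumes without recomputation", {
  dir <- withr::local_tempdir()
  a <- run_study(small_plan(), checkpoint_dir = dir)
  expect_length(list.files(dir, pattern = "scenario_.*csv"), 2)
  # poison one checkpoint: resumed run must read it rather than recompute
  ck <- file.path(dir, "scenario_001.csv")
  poisoned <- utils::read.csv(ck)
  poisoned$beta1_hat <- -999
  utils::write.csv(poisoned, ck, row.names = FALSE)
  b <- run_study(small_plan(), checkpoint_dir = dir)
  expect_true(all(b$beta1_hat[b$icc_level == "0.01"] == -999))
})

test_that("infeasible scenarios fail before simulating", {
  plan <- small_plan()
  plan$icc_levels <- tibble::tibble(level = "bad", icc_mid = 0.3,
                                    sd_u = 0.0316, icc_low = 0.25,
                                    icc_high = 0.349)
  expect_error(run_study(plan), "infeasible")
})

test_that("study plans round-trip through YAML configs", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "x_type: binary",
    "icc_levels: ['0.01', '0.3']",
    "target_prevalences: [0.05, 0.2]",
    "n_shift_values: 10",
    "replicates_per_shift: 4",
    "beta1_true: 0",
    "master_seed: 42",
    "scale_factor: 0.5"
  ), cfg)
  plan <- read_study_plan(cfg)
  expect_s3_class(plan, "study_plan")
  expect_equal(plan$x_type, "binary")
  expect_equal(nrow(plan$icc_levels), 2)
  expect_equal(plan$target_prevalences, c(0.05, 0.2))
  dims <- clusterbias:::scaled_dims(plan)
  expect_equal(dims, list(n_shift = 5L, reps = 2L))

  writeLines("x_type: continuous\nbogus_key: 1", cfg)
  expect_error(read_study_plan(cfg), "bogus_key")
  writeLines("icc_levels: ['0.42']", cfg)
  expect_error(read_study_plan(cfg), "0.42")

  # the packaged example configs parse
  shipped <- system.file("extdata", "plan_continuous_desk.yaml",
                         package = "clusterbias")
  expect_equal(read_study_plan(shipped)$x_type, "continuous")
  shipped_b <- system.file("extdata", "plan_binary_stress.yaml",
                           package = "clusterbias")
  expect_equal(read_study_plan(shipped_b)$beta1_true, 0)
})

test_that("replicate seeds stay in the 32-bit range and rarely collide", {
  seeds <- c(outer(1:50, 1:40,
                   function(s, r) mapply(function(a, b)
                     clusterbias:::replicate_seed(1, a %% 7, a, b), s, r)))
  expect_true(all(seeds >= 1 & seeds <= 2147483646))
  expect_gt(length(unique(seeds)) / length(seeds), 0.999)
})

test_that("reproduce_table1 lays out coverage by ICC level and fifths with
           reference totals", {
  set.seed(191)
  plan <- study_plan("continuous", icc_levels = icc_grid()[c(1, 6), ],
                     n_shift_values = 25, replicates_per_shift = 1,
                     beta1_true = 1, master_seed = 5,
                     n_clusters = 50, cluster_size = 20)
  rec <- run_study(plan)
  tab <- reproduce_table1(records = rec)
  expect_equal(tab$wide$icc_level, c("0.001", "0.3"))
  cover_cols <- c(paste0("ri_fifth", 1:5), "ri_total",
                  paste0("ols_fifth", 1:5), "ols_total")
  expect_true(all(cover_cols %in% names(tab$wide)))
  expect_true(all(c("coverage_ri_ref", "coverage_ols_ref") %in%
                    names(tab$wide)))
  # 25 replicates per level -> every fifth has 5 records -> low_n flag
  expect_true(all(tab$wide$flags == "low_n"))
  expect_true(all(tab$wide$ri_total >= 0 & tab$wide$ri_total <= 100))
})

test_that("samples round-trip through CSV with a JSON sidecar", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sample.csv")
  set.seed(201)
  spec <- simulation_spec(n_clusters = 10, cluster_size = 5,
                          x_type = "binary", sd_shift = 0.02,
                          target_prevalence = 0.2)
  smp <- generate_sample(spec)
  write_sample(smp, path)
  back <- read_sample(path)
  expect_equal(back$x, smp$data$x)
  expect_equal(back$y, smp$data$y)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$target_prevalence, 0.2)
  expect_equal(meta$sample_icc, smp$sample_icc)
  # both fitters run on re-read data
  expect_s3_class(fit_ols(back), "fit_result")
  expect_s3_class(fit_ri(back), "fit_result")

  bad <- file.path(dir, "bad.csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_sample(bad), "cluster")
})
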