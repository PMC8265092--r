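#' Plan a full factorial simulation study
#'
#' A `study_plan` describes one arm of the study: the explanatory-variable
#' type, the ICC levels to sweep (each an (`sd_u`, target range) pair), the
#' target prevalences (binary x), how many shift-SD values to draw and how
#' many replicate samples to generate per shift value, the true slope, and
#' a master seed. At full scale the continuous arm uses 1,000 shift values
#' x 100 replicates per ICC level and the binary arm 500 x 100 per
#' (ICC level, prevalence); `scale_factor` shrinks both dimensions
#' proportionally for desk-scale runs (total replicates scale with its
#' square), with a floor of 1 each.
#'
#' @param x_type `"continuous"` or `"binary"`.
#' @param icc_levels Data frame like [icc_grid()] (subset rows to sweep
#'   fewer levels).
#' @param target_prevalences Numeric vector (binary x only).
#' @param n_shift_values Shift-SD draws per scenario (default 1000
#'   continuous, 500 binary).
#' @param replicates_per_shift Samples per shift value (default 100).
#' @param beta1_true True slope: 1 for the effect study, 0 for Type I.
#' @param master_seed Integer master seed.
#' @param scale_factor In (0, 1]; multiplies both replication dimensions.
#' @param n_clusters,cluster_size Cluster geometry (default 100 x 100).
#' @param models Which models to fit per replicate (default both).
#' @return A `study_plan` object.
#' @export
study_plan <- function(x_type = c("continuous", "binary"),
                       icc_levels = icc_grid(),
                       target_prevalences = target_prevalence_grid(),
                       n_shift_values = NULL,
                       replicates_per_shift = 100,
                       beta1_true = 1,
                       master_seed = 1,
                       scale_factor = 1,
                       n_clusters = 100,
                       cluster_size = 100,
                       models = c("OLS", "RI")) {
  x_type <- match.arg(x_type)
  if (is.null(n_shift_values))
    n_shift_values <- if (x_type == "continuous") 1000 else 500
  stopifnot(
    all(c("level", "sd_u", "icc_low", "icc_high") %in% names(icc_levels)),
    nrow(icc_levels) >= 1,
    n_shift_values >= 1, replicates_per_shift >= 1,
    scale_factor > 0, scale_factor <= 1,
    beta1_true %in% c(0, 1) || is.numeric(beta1_true)
  )
  models <- match.arg(models, several.ok = TRUE)
  structure(
    list(
      x_type = x_type,
      icc_levels = icc_levels,
      target_prevalences = if (x_type == "binary") target_prevalences else NULL,
      n_shift_values = as.integer(n_shift_values),
      replicates_per_shift = as.integer(replicates_per_shift),
      beta1_true = beta1_true,
      master_seed = as.integer(master_seed),
      scale_factor = scale_factor,
      n_clusters = as.integer(n_clusters),
      cluster_size = as.integer(cluster_size),
      models = models
    ),
    class = "study_plan"
  )
}

#' @export
print.study_plan <- function(x, ...) {
  dims <- scaled_dims(x)
  cat("<study_plan>\n")
  cat(sprintf("  %s x, beta1 = %g, %d ICC level(s)%s\n",
              x$x_type, x$beta1_true, nrow(x$icc_levels),
              if (x$x_type == "binary")
                sprintf(", prevalences {%s}",
                        paste(x$target_prevalences, collapse = ", "))
              else ""))
  cat(sprintf("  %d shift values x %d replicates per scenario (scale %g)\n",
              dims$n_shift, dims$reps, x$scale_factor))
  cat(sprintf("  geometry %d x %d, master seed %d, models: %s\n",
              x$n_clusters, x$cluster_size, x$master_seed,
              paste(x$models, collapse = "+")))
  invisible(x)
}

scaled_dims <- function(plan) {
  list(n_shift = max(1L, as.integer(round(plan$n_shift_values * plan$scale_factor))),
       reps = max(1L, as.integer(round(plan$replicates_per_shift * plan$scale_factor))))
}

#' Read a study plan from a YAML config file
#'
#' The file holds `study_plan()` fields by name; `icc_levels` may be a
#' character vector of level labels from [icc_grid()] (e.g. `["0.01",
#' "0.3"]`) or omitted for all six.
#'
#' @param path Path to a YAML file.
#' @return A `study_plan`.
#' @export
read_study_plan <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(study_plan))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop(sprintf("unknown study_plan key(s) in %s: %s",
                 path, paste(bad, collapse = ", ")))
  if (!is.null(cfg$icc_levels)) {
    grid <- icc_grid()
    miss <- setdiff(as.character(cfg$icc_levels), grid$level)
    if (length(miss))
      stop(sprintf("unknown ICC level(s): %s", paste(miss, collapse = ", ")))
    cfg$icc_levels <- grid[grid$level %in% as.character(cfg$icc_levels), ]
  }
  do.call(study_plan, cfg)
}

# Deterministic Lehmer-style hash of the replicate coordinates; keeps every
# seed in [1, 2^31 - 2] so results are independent of loop order and safe
# for 32-bit R integers.
replicate_seed <- function(master_seed, scenario_idx, shift_idx, rep_idx) {
  M <- 2147483647
  h <- master_seed %% M
  for (k in c(scenario_idx, shift_idx, rep_idx))
    h <- (h * 69621 + k + 1) %% M
  as.integer(h %% (M - 1) + 1)
}

scenario_table <- function(plan) {
  lv <- plan$icc_levels
  if (plan$x_type == "binary") {
    grid <- expand.grid(i = seq_len(nrow(lv)), p = plan$target_prevalences)
    tibble::tibble(
      scenario_idx = seq_len(nrow(grid)),
      icc_level = lv$level[grid$i],
      sd_u = lv$sd_u[grid$i],
      icc_low = lv$icc_low[grid$i], icc_high = lv$icc_high[grid$i],
      target_prevalence = grid$p
    )
  } else {
    tibble::tibble(
      scenario_idx = seq_len(nrow(lv)),
      icc_level = lv$level, sd_u = lv$sd_u,
      icc_low = lv$icc_low, icc_high = lv$icc_high,
      target_prevalence = NA_real_
    )
  }
}

fit_to_row <- function(fit) {
  tibble::tibble(
    model = fit$model, beta1_hat = fit$beta1_hat, se_beta1 = fit$se_beta1,
    ci_low = fit$ci_low, ci_high = fit$ci_high, p_value = fit$p_value,
    sd_u_hat = fit$sd_u_hat, sd_e_hat = fit$sd_e_hat,
    converged = fit$converged
  )
}

run_scenario <- function(plan, scen) {
  dims <- scaled_dims(plan)
  base_spec <- simulation_spec(
    n_clusters = plan$n_clusters, cluster_size = plan$cluster_size,
    beta1 = plan$beta1_true, sd_u = scen$sd_u,
    icc_target_range = c(scen$icc_low, scen$icc_high),
    x_type = plan$x_type, sd_shift = 0,
    target_prevalence = if (plan$x_type == "binary") scen$target_prevalence
                        else NULL
  )
  check_feasible(base_spec)
  rows <- vector("list", dims$n_shift * dims$reps)
  r <- 0L
  for (s in seq_len(dims$n_shift)) {
    set.seed(replicate_seed(plan$master_seed, scen$scenario_idx, s, 0L))
    sd_shift <- draw_sd_shift(plan$x_type)
    spec <- base_spec
    spec$sd_shift <- sd_shift
    for (rep in seq_len(dims$reps)) {
      set.seed(replicate_seed(plan$master_seed, scen$scenario_idx, s, rep))
      smp <- generate_accepted_sample(spec)
      fits <- fit_both(smp, models = plan$models)
      r <- r + 1L
      rows[[r]] <- dplyr::mutate(
        dplyr::bind_rows(lapply(fits, fit_to_row)),
        scenario_id = sprintf("%s_icc%s%s", plan$x_type, scen$icc_level,
                              if (plan$x_type == "binary")
                                sprintf("_p%g", scen$target_prevalence)
                              else ""),
        icc_level = scen$icc_level,
        target_prevalence = scen$target_prevalence,
        replicate = (s - 1L) * dims$reps + rep,
        sd_shift = sd_shift,
        sample_icc = smp$sample_icc,
        x_dispersion = smp$x_dispersion,
        .before = 1
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Run a simulation study
#'
#' Executes every scenario of the plan (ICC levels, and prevalences for
#' binary x): draws shift SDs, generates ICC-accepted samples, fits the
#' requested models, and returns tidy replicate records, one row per
#' (replicate, model). Seeds are derived deterministically from
#' (master seed, scenario, shift index, replicate index), so any subset of
#' scenarios reproduces exactly the same records regardless of run order.
#'
#' @param plan A [study_plan()].
#' @param checkpoint_dir Optional directory; each scenario's records are
#'   written there as CSV on completion and reloaded instead of recomputed
#'   on a rerun, making interrupted studies resumable.
#' @param progress If `TRUE`, message per-scenario progress.
#' @return A tibble of replicate records with columns `scenario_id`,
#'   `icc_level`, `target_prevalence`, `replicate`, `sd_shift`,
#'   `sample_icc`, `x_dispersion`, `model`, `beta1_hat`, `se_beta1`,
#'   `ci_low`, `ci_high`, `p_value`, `sd_u_hat`, `sd_e_hat`, `converged`.
#' @export
run_study <- function(plan, checkpoint_dir = NULL, progress = FALSE) {
  stopifnot(inherits(plan, "study_plan"))
  scens <- scenario_table(plan)
  # fail fast if any scenario is infeasible before simulating anything
  for (i in seq_len(nrow(scens)))
    check_feasible(simulation_spec(
      n_clusters = plan$n_clusters, cluster_size = plan$cluster_size,
      sd_u = scens$sd_u[i],
      icc_target_range = c(scens$icc_low[i], scens$icc_high[i]),
      x_type = plan$x_type,
      target_prevalence = if (plan$x_type == "binary")
        scens$target_prevalence[i] else NULL
    ))
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  out <- vector("list", nrow(scens))
  for (i in seq_len(nrow(scens))) {
    scen <- scens[i, ]
    ckpt <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("scenario_%03d.csv", i))
    if (!is.null(ckpt) && file.exists(ckpt)) {
      out[[i]] <- tibble::as_tibble(utils::read.csv(ckpt))
      if (progress) message(sprintf("[%d/%d] %s (checkpoint)", i, nrow(scens),
                                    out[[i]]$scenario_id[1]))
      next
    }
    t0 <- Sys.time()
    out[[i]] <- run_scenario(plan, scen)
    if (!is.null(ckpt))
      utils::write.csv(out[[i]], ckpt, row.names = FALSE)
    if (progress)
      message(sprintf("[%d/%d] %s: %d records in %.1fs", i, nrow(scens),
                      out[[i]]$scenario_id[1], nrow(out[[i]]),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  dplyr::bind_rows(out)
}

#' Reference coverage rates from the full-scale study design
#'
#' Total-column coverage (%) of the true slope by 95% confidence intervals
#' for the continuous-x arm at full replication (100,000 samples per ICC
#' level), as reported by the original large-scale run of this simulation
#' design. These are comparison constants for [reproduce_table1()] output
#' only; nothing is computed from them.
#'
#' @return Tibble with columns `icc_level`, `coverage_ri_ref`,
#'   `coverage_ols_ref`.
#' @export
reference_coverage_continuous <- function() {
  tibble::tibble(
    icc_level = c("0.001", "0.003", "0.01", "0.03", "0.1", "0.3"),
    coverage_ri_ref = c(95.08, 95.33, 94.80, 94.87, 94.76, 94.75),
    coverage_ols_ref = c(94.08, 92.30, 84.75, 69.39, 47.80, 30.36)
  )
}

#' Reproduce the continuous-x coverage table
#'
#' Runs (or is given) the continuous-x effect study and tabulates coverage
#' of the true slope by 95% CIs for both models, by ICC level and fifths of
#' the dispersion of cluster means of x, in the wide 6-row layout of the
#' study's headline table, with the full-scale reference totals appended
#' for comparison. Cells resting on fewer than 20 replicates are flagged in
#' a `flags` column.
#'
#' @param scale_factor Replication scale passed to [study_plan()] (e.g.
#'   0.01 gives 100 shift values x 1 replicate = 100 samples per level).
#' @param master_seed Master seed.
#' @param records Optional precomputed records from a continuous effect
#'   study; when supplied, no simulation is run.
#' @param progress Passed to [run_study()].
#' @return List with `wide` (the 6 x (2 x 6) coverage grid plus reference
#'   columns) and `records`.
#' @export
reproduce_table1 <- function(scale_factor = 0.01, master_seed = 1,
                             records = NULL, progress = FALSE) {
  if (is.null(records)) {
    plan <- study_plan("continuous", beta1_true = 1,
                       master_seed = master_seed,
                       scale_factor = scale_factor)
    records <- run_study(plan, progress = progress)
  }
  summ <- summarize_records(records, beta1_true = 1, n_bins = 5)
  cov <- summ[summ$metric == "coverage", ]
  cov$cell <- sprintf("%s_%s", tolower(cov$model),
                      ifelse(cov$dispersion_bin == "total", "total",
                             paste0("fifth", cov$dispersion_bin)))
  wide <- tidyr::pivot_wider(
    cov[, c("icc_level", "cell", "value")],
    names_from = "cell", values_from = "value"
  )
  low_n <- unique(cov$icc_level[cov$n_replicates < 20])
  wide$flags <- ifelse(wide$icc_level %in% low_n, "low_n", "")
  wide <- dplyr::left_join(wide, reference_coverage_continuous(),
                           by = "icc_level")
  ord <- match(icc_grid()$level, wide$icc_level)
  list(wide = wide[ord[!is.na(ord)], ], records = records)
}
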