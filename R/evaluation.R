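#' Deviation of an estimated slope from the generating truth
#'
#' @param fit A `fit_result` (or anything with `$beta1_hat`).
#' @param beta1_true The slope used in generation.
#' @return `beta1_hat - beta1_true`.
#' @export
deviation_from_truth <- function(fit, beta1_true) {
  fit$beta1_hat - beta1_true
}

#' Ratio of RI to OLS slope standard errors
#'
#' `SE(beta1, RI) / SE(beta1, OLS)` for two fits of the same sample. Values
#' below 1 mean the cluster-unadjusted model overstates its own SE (and so
#' understates precision); values above 1 mean it is spuriously precise.
#'
#' @param ri,ols `fit_result`s for the same sample.
#' @return Positive scalar.
#' @export
se_ratio <- function(ri, ols) {
  stopifnot(ri$model == "RI", ols$model == "OLS")
  if (ols$se_beta1 <= 0) stop("SE ratio undefined: OLS SE is zero")
  ri$se_beta1 / ols$se_beta1
}

records_for <- function(records, model) {
  stopifnot(model %in% c("OLS", "RI"))
  recs <- records[records$model == model & records$converged, , drop = FALSE]
  if (nrow(recs) == 0) stop(sprintf("empty stratum: no converged %s records", model))
  recs
}

rate_with_mc_se <- function(hits) {
  n <- length(hits)
  p <- mean(hits)
  structure(100 * p, mc_se = 100 * sqrt(p * (1 - p) / n), n = n)
}

#' Coverage rate of confidence intervals
#'
#' Percent of converged replicates of one model whose CI contains the true
#' slope. The binomial Monte-Carlo SE (in percentage points) and the count
#' used are attached as attributes `mc_se` and `n`.
#'
#' @param records Tidy replicate records (see [run_study()]), long by model.
#' @param model `"OLS"` or `"RI"`.
#' @param beta1_true True slope the intervals should cover.
#' @return Percent in `[0, 100]`.
#' @export
coverage_rate <- function(records, model, beta1_true) {
  recs <- records_for(records, model)
  rate_with_mc_se(recs$ci_low <= beta1_true & beta1_true <= recs$ci_high)
}

#' Type I error rate
#'
#' Percent of converged replicates of one model whose two-sided slope test
#' rejects at level `alpha`. Meaningful for records generated under
#' `beta1 = 0`. Attributes as in [coverage_rate()].
#'
#' @inheritParams coverage_rate
#' @param alpha Significance level, default 0.05.
#' @return Percent in `[0, 100]`.
#' @export
type1_rate <- function(records, model, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  recs <- records_for(records, model)
  rate_with_mc_se(recs$p_value < alpha)
}

#' Assign replicates to empirical dispersion bins
#'
#' Bins replicates by their between-cluster dispersion of x into
#' `n_bins` equal-count bins (fifths and thirds in the study's summaries),
#' separately within each (`icc_level`, `target_prevalence`) stratum, since
#' shift SDs are drawn afresh for every scenario. Ties at bin boundaries are
#' broken deterministically by replicate order. When all dispersions in a
#' stratum are identical, every record goes to bin 1 with a warning.
#'
#' @param records Tidy replicate records.
#' @param n_bins Number of bins (3 and 5 reproduce the study's summaries).
#' @return `records` with an integer `dispersion_bin` column added.
#' @export
assign_dispersion_bins <- function(records, n_bins) {
  stopifnot(n_bins >= 1, nrow(records) >= n_bins)
  prev <- if ("target_prevalence" %in% names(records))
    records$target_prevalence else rep(0, nrow(records))
  prev[is.na(prev)] <- -1 # NA marks "not a binary scenario"; keep its rows
  strata <- interaction(records$icc_level, prev, drop = TRUE)
  records$dispersion_bin <- NA_integer_
  for (s in levels(strata)) {
    idx <- which(strata == s)
    reps <- unique(records[idx, c("scenario_id", "replicate", "x_dispersion")])
    if (length(unique(reps$x_dispersion)) == 1 && nrow(reps) > 1) {
      warning(sprintf("stratum %s: all dispersions identical; single bin", s))
      bins <- rep(1L, nrow(reps))
    } else {
      ord <- order(reps$x_dispersion, reps$replicate)
      r <- integer(nrow(reps))
      r[ord] <- seq_len(nrow(reps))
      bins <- as.integer(floor((r - 1) * n_bins / nrow(reps)) + 1L)
    }
    key <- paste(reps$scenario_id, reps$replicate)
    records$dispersion_bin[idx] <-
      bins[match(paste(records$scenario_id[idx], records$replicate[idx]), key)]
  }
  records
}

se_ratio_table <- function(records) {
  wide <- tidyr::pivot_wider(
    records[records$converged,
            c("scenario_id", "replicate", "model", "se_beta1")],
    names_from = "model", values_from = "se_beta1"
  )
  if (!all(c("RI", "OLS") %in% names(wide))) # single-model runs: no ratios
    return(tibble::tibble(scenario_id = character(), replicate = integer(),
                          se_ratio = numeric()))
  wide <- wide[!is.na(wide$RI) & !is.na(wide$OLS) & wide$OLS > 0, ]
  wide$se_ratio <- wide$RI / wide$OLS
  wide[, c("scenario_id", "replicate", "se_ratio")]
}

metric_row <- function(keys, model, metric, values) {
  tibble::tibble(
    !!!keys, model = model, metric = metric,
    value = mean(values),
    n_replicates = length(values),
    mc_se = if (metric %in% c("coverage", "type1"))
      sqrt(mean(values / 100) * (1 - mean(values / 100)) / length(values)) * 100
    else stats::sd(values) / sqrt(length(values))
  )
}

#' Aggregate replicate records into a summary table
#'
#' Produces the study's four metric families — mean deviation from the true
#' slope, mean SE ratio, CI coverage and rejection (Type I) rate — for both
#' models, stratified by ICC level, target prevalence (binary x) and,
#' optionally, equal-count dispersion bins (plus a pooled `"total"` row per
#' stratum). Non-converged replicates are excluded and counted.
#'
#' @param records Tidy replicate records from [run_study()].
#' @param beta1_true True slope of the generating model.
#' @param n_bins Number of dispersion bins, or `NULL` for totals only.
#' @param alpha Significance level for the rejection metric.
#' @return A tibble with columns `icc_level`, `target_prevalence`,
#'   `dispersion_bin` (`"total"` for pooled rows), `model`, `metric`,
#'   `value`, `n_replicates`, `mc_se`, `n_excluded`.
#' @export
summarize_records <- function(records, beta1_true, n_bins = NULL,
                              alpha = 0.05) {
  stopifnot(nrow(records) > 0)
  if (!"target_prevalence" %in% names(records))
    records$target_prevalence <- NA_real_
  if (!is.null(n_bins)) records <- assign_dispersion_bins(records, n_bins)
  else records$dispersion_bin <- NA_integer_

  ratios <- se_ratio_table(records)
  records$se_ratio_val <- ratios$se_ratio[
    match(paste(records$scenario_id, records$replicate),
          paste(ratios$scenario_id, ratios$replicate))]

  strata <- unique(records[, c("icc_level", "target_prevalence")])
  out <- list()
  for (i in seq_len(nrow(strata))) {
    sel <- records$icc_level == strata$icc_level[i] &
      (is.na(strata$target_prevalence[i]) |
         records$target_prevalence == strata$target_prevalence[i])
    sub <- records[sel, ]
    bins <- if (is.null(n_bins)) list(total = sub)
            else c(stats::setNames(
                     split(sub, sub$dispersion_bin),
                     paste0("bin", sort(unique(sub$dispersion_bin)))),
                   list(total = sub))
    for (bn in names(bins)) {
      bsub <- bins[[bn]]
      keys <- list(icc_level = strata$icc_level[i],
                   target_prevalence = strata$target_prevalence[i],
                   dispersion_bin = sub("bin", "", bn))
      excl <- sum(!bsub$converged) # rows, long by model
      for (mod in intersect(c("OLS", "RI"), unique(bsub$model))) {
        conv <- bsub[bsub$model == mod & bsub$converged, ]
        if (nrow(conv) == 0) next
        covered <- 100 * (conv$ci_low <= beta1_true &
                            beta1_true <= conv$ci_high)
        reject <- 100 * (conv$p_value < alpha)
        rows <- dplyr::bind_rows(
          metric_row(keys, mod, "mean_deviation", conv$beta1_hat - beta1_true),
          metric_row(keys, mod, "coverage", covered),
          metric_row(keys, mod, "type1", reject)
        )
        out[[length(out) + 1]] <- dplyr::mutate(rows, n_excluded = excl)
      }
      pair <- bsub$se_ratio_val[bsub$model == "OLS" & !is.na(bsub$se_ratio_val)]
      if (length(pair) > 0)
        out[[length(out) + 1]] <- dplyr::mutate(
          metric_row(keys, "RI/OLS", "mean_se_ratio", pair), n_excluded = excl)
    }
  }
  dplyr::bind_rows(out)
}
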