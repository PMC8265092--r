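# Hand-built replicate records (no simulation) for the evaluation tests.
# CIs and p-values follow the package's z-Wald convention so identities
# that depend on it hold exactly.
synth_records <- function(est, se, icc_level = "0.3",
                          target_prevalence = NA_real_,
                          dispersion = seq_along(est),
                          scenario_id = "s1",
                          models = c("OLS", "RI")) {
  one <- function(model) tibble::tibble(
    scenario_id = scenario_id,
    icc_level = icc_level,
    target_prevalence = target_prevalence,
    replicate = seq_along(est),
    sd_shift = NA_real_,
    sample_icc = NA_real_,
    x_dispersion = dispersion,
    model = model,
    beta1_hat = est,
    se_beta1 = se,
    ci_low = est - stats::qnorm(0.975) * se,
    ci_high = est + stats::qnorm(0.975) * se,
    p_value = 2 * stats::pnorm(-abs(est / se)),
    sd_u_hat = 0,
    sd_e_hat = 1,
    converged = TRUE
  )
  dplyr::bind_rows(lapply(models, one))
}
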