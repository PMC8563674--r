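#' MR-Egger regression
#'
#' Weighted least-squares regression of the outcome betas on the exposure
#' betas *with* an intercept, weights `1/se_y^2`, after orientation of all
#' records to the exposure-increasing allele (`beta_x >= 0`). The slope is
#' the pleiotropy-adjusted causal estimate; the intercept estimates the
#' average directional pleiotropic effect and its test is the standard probe
#' for directional pleiotropy. Standard errors use a multiplicative
#' overdispersion factor floored at 1 (`max(1, residual Q / (n - 2))`).
#'
#' @param harmonised Harmonised table ([harmonise()]) or data frame with
#'   `snp`, `beta_x`, `se_x`, `beta_y`, `se_y`; excluded rows dropped.
#' @param unit_label Passed to the result rows.
#' @param t_dist Use t-distribution p-values/CIs on `n - 2` degrees of
#'   freedom instead of normal ones (default `FALSE`).
#' @return A two-row estimate tibble: methods `"egger_slope"` and
#'   `"egger_intercept"`.
#' @export
mr_egger <- function(harmonised, unit_label = "SD outcome per SD exposure",
                     t_dist = FALSE) {
  h <- tibble::as_tibble(harmonised)
  if ("excluded_reason" %in% names(h)) h <- harmonised_kept(h)
  n <- nrow(h)
  if (n < 3L) {
    abort("MR-Egger requires at least three SNPs",
          class = "maternalmr_insufficient_data")
  }
  if (any(h$beta_x < 0)) {
    abort("MR-Egger requires records oriented to the exposure-increasing allele (beta_x >= 0)",
          class = "maternalmr_orientation_error")
  }
  if (diff(range(h$beta_x)) == 0) {
    abort("all exposure betas identical: Egger design matrix is rank deficient",
          class = "maternalmr_rank_deficiency")
  }
  w <- 1 / h$se_y^2
  fit <- lm(beta_y ~ beta_x, data = h, weights = w)
  est <- coef(fit)
  # unscaled (X' W X)^{-1}, then multiplicative overdispersion floored at 1
  xtx_inv <- summary(fit)$cov.unscaled
  phi <- max(1, sum(w * fit$residuals^2) / (n - 2))
  ses <- sqrt(diag(xtx_inv) * phi)

  crit <- if (t_dist) stats::qt(0.975, n - 2) else Z95
  pfun <- if (t_dist) {
    function(z) 2 * stats::pt(-abs(z), n - 2)
  } else {
    function(z) 2 * pnorm(-abs(z))
  }
  tibble::tibble(
    method = c("egger_slope", "egger_intercept"),
    beta = c(est[["beta_x"]], est[["(Intercept)"]]),
    se = c(ses[["beta_x"]], ses[["(Intercept)"]]),
    ci_low = beta - crit * se,
    ci_high = beta + crit * se,
    pvalue = pfun(beta / se),
    n_snps = n,
    unit_label = c(unit_label, "SD outcome per allele (intercept)")
  )
}
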