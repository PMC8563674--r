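#' Radial MR with per-SNP outlier detection
#'
#' Reparameterises the MR model on the radial scale: the response is
#' `beta_y / se_y` and the predictor `beta_x / se_y` (first-order weights).
#' The IVW variant regresses through the origin, which reproduces the IVW
#' estimate exactly; the Egger variant adds an intercept. Each SNP's squared
#' standardised residual is its contribution to the global heterogeneity
#' statistic (for the IVW variant these contributions sum exactly to
#' Cochran's Q), is referred to a chi-squared distribution with one degree
#' of freedom, and flags the SNP as an outlier when the p-value falls below
#' `alpha`.
#'
#' @inheritParams mr_egger
#' @param alpha Per-SNP outlier significance threshold (default 0.05; a
#'   Bonferroni threshold `0.05 / n_snps` is a common stricter choice).
#' @param model `"ivw"` (through the origin) or `"egger"` (with intercept).
#' @return A list with `estimate` (one-row estimate tibble, method
#'   `"radial_ivw"` or `"radial_egger"`), `rows` (per-SNP tibble: `snp`,
#'   `q_contribution`, `q_pvalue`, `is_outlier`), and `global_q`.
#' @export
radial_mr <- function(harmonised, alpha = 0.05, model = c("ivw", "egger"),
                      unit_label = "SD outcome per SD exposure") {
  model <- match.arg(model)
  h <- tibble::as_tibble(harmonised)
  if ("excluded_reason" %in% names(h)) h <- harmonised_kept(h)
  n <- nrow(h)
  if (n < 3L) {
    abort("radial MR requires at least three SNPs",
          class = "maternalmr_insufficient_data")
  }
  y_r <- h$beta_y / h$se_y
  x_r <- h$beta_x / h$se_y

  if (model == "ivw") {
    fit <- lm(y_r ~ 0 + x_r)
    slope_id <- "x_r"
    dfree <- n - 1L
  } else {
    fit <- lm(y_r ~ x_r)
    slope_id <- "x_r"
    dfree <- n - 2L
  }
  res <- unname(fit$residuals)
  q_j <- res^2
  Q <- sum(q_j)
  beta <- coef(fit)[[slope_id]]
  xtx_inv <- summary(fit)$cov.unscaled
  se <- sqrt(diag(xtx_inv)[[slope_id]] * max(1, Q / dfree))

  rows <- tibble::tibble(
    snp = h$snp,
    q_contribution = q_j,
    q_pvalue = pchisq(q_j, df = 1, lower.tail = FALSE),
    is_outlier = pchisq(q_j, df = 1, lower.tail = FALSE) < alpha
  )
  list(
    estimate = mr_estimate(paste0("radial_", model), beta, se, n, unit_label),
    rows = rows,
    global_q = Q
  )
}
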