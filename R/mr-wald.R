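#' Per-SNP Wald ratio estimates
#'
#' The Wald ratio divides a SNP's outcome association by its exposure
#' association, \eqn{\theta_j = \beta_{y,j}/\beta_{x,j}}, with first-order
#' standard error \eqn{se_{y,j}/|\beta_{x,j}|} (exposure-side uncertainty
#' ignored, appropriate for strong instruments).
#'
#' @param harmonised Harmonised table (see [harmonise()]) or any data frame
#'   with columns `snp`, `beta_x`, `se_x`, `beta_y`, `se_y`; excluded rows
#'   are dropped first.
#' @return A tibble with `snp`, `theta`, `se_theta`, `weight`
#'   (`1/se_theta^2`), in input order.
#' @export
wald_ratios <- function(harmonised) {
  h <- tibble::as_tibble(harmonised)
  if ("excluded_reason" %in% names(h)) h <- harmonised_kept(h)
  if (any(h$beta_x == 0)) {
    abort(paste0("undefined Wald ratio: zero exposure beta for ",
                 paste(h$snp[h$beta_x == 0], collapse = ", ")),
          class = "maternalmr_undefined_ratio")
  }
  if (any(h$se_y <= 0)) {
    abort("outcome standard errors must be positive",
          class = "maternalmr_domain_error")
  }
  tibble::tibble(
    snp = h$snp,
    theta = h$beta_y / h$beta_x,
    se_theta = h$se_y / abs(h$beta_x),
    weight = (h$beta_x / h$se_y)^2
  )
}

#' Pool Wald ratios by inverse-variance weighting
#'
#' Fixed-effect IVW pools per-SNP ratios as
#' \eqn{\hat\theta = \sum w_j \theta_j / \sum w_j} with
#' \eqn{se = \sqrt{1/\sum w_j}}, algebraically identical to a weighted
#' regression of `beta_y` on `beta_x` through the origin with weights
#' `1/se_y^2`. The multiplicative random-effects variant inflates the fixed
#' SE by \eqn{\sqrt{\max(1, Q/df)}} to absorb between-SNP heterogeneity;
#' point estimates are identical under both models.
#'
#' @param ratios Output of [wald_ratios()].
#' @param model `"fixed"` or `"multiplicative_random"`.
#' @param unit_label Passed to the result row.
#' @return A one-row estimate tibble (see [mr_estimate()]), method
#'   `"wald_ivw_fixed"` or `"ivw_mre"`.
#' @export
ivw_pool <- function(ratios, model = c("fixed", "multiplicative_random"),
                     unit_label = "SD outcome per SD exposure") {
  model <- match.arg(model)
  ratios <- tibble::as_tibble(ratios)
  pooled <- ivw_mean(ratios$theta, ratios$se_theta)
  se <- pooled$se
  method <- "wald_ivw_fixed"
  if (model == "multiplicative_random") {
    method <- "ivw_mre"
    if (nrow(ratios) > 1L) {
      het <- cochran_q(ratios, pooled$beta)
      se <- se * sqrt(max(1, het$Q / het$df))
    }
  }
  mr_estimate(method, pooled$beta, se, nrow(ratios), unit_label)
}

#' Cochran's Q and I-squared heterogeneity across Wald ratios
#'
#' \eqn{Q = \sum w_j (\theta_j - \hat\theta)^2} on `df = n - 1` degrees of
#' freedom, with \eqn{I^2 = \max(0, (Q - df)/Q) \times 100} describing the
#' percentage of variation between ratios attributable to heterogeneity
#' rather than sampling error.
#'
#' @param ratios Output of [wald_ratios()] (at least two rows).
#' @param pooled_beta Pooled estimate around which Q is computed; defaults
#'   to the fixed-effect IVW estimate of `ratios`.
#' @return A one-row tibble with `Q`, `df`, `i2_percent`, `pvalue`.
#' @export
cochran_q <- function(ratios, pooled_beta = NULL) {
  ratios <- tibble::as_tibble(ratios)
  if (nrow(ratios) < 2L) {
    abort("heterogeneity requires at least two ratios",
          class = "maternalmr_insufficient_data")
  }
  if (is.null(pooled_beta)) pooled_beta <- ivw_mean(ratios$theta, ratios$se_theta)$beta
  w <- 1 / ratios$se_theta^2
  Q <- sum(w * (ratios$theta - pooled_beta)^2)
  df <- nrow(ratios) - 1L
  tibble::tibble(
    Q = Q, df = df,
    i2_percent = i_squared(Q, df),
    pvalue = pchisq(Q, df, lower.tail = FALSE)
  )
}

#' I-squared from a Q statistic
#'
#' @param Q Cochran Q statistic (>= 0).
#' @param df Degrees of freedom.
#' @return Percentage in \[0, 100\]: `max(0, (Q - df)/Q) * 100`, and 0 when
#'   `Q` is 0.
#' @export
i_squared <- function(Q, df) {
  ifelse(Q > 0, pmax(0, (Q - df) / Q) * 100, 0)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the pooled IVW effect excluding each SNP in turn, exposing
#' instruments whose removal materially moves the estimate.
#'
#' @inheritParams mr_egger
#' @param model Pooling model passed to [ivw_pool()].
#' @return A tibble with one row per excluded SNP: `excluded_snp` plus the
#'   estimate columns; row order matches the input.
#' @export
leave_one_out <- function(harmonised, model = "fixed",
                          unit_label = "SD outcome per SD exposure") {
  ratios <- wald_ratios(harmonised)
  if (nrow(ratios) < 3L) {
    abort("leave-one-out requires at least three SNPs",
          class = "maternalmr_insufficient_data")
  }
  purrr::list_rbind(purrr::map(seq_len(nrow(ratios)), function(i) {
    est <- ivw_pool(ratios[-i, ], model = model, unit_label = unit_label)
    dplyr::bind_cols(tibble::tibble(excluded_snp = ratios$snp[i]), est)
  }))
}
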