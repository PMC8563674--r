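#' Decompose own- and offspring-birthweight associations into maternal and
#' fetal effects
#'
#' The weighted linear model (WLM) separates the maternal from the fetal
#' genetic effect of a SNP on birthweight using two marginal GWAS: the SNP's
#' association with the subject's *own* birthweight and with the subject's
#' *offspring's* birthweight. Because a mother transmits half her alleles,
#' the marginal expectations are
#' \deqn{E[\beta_{own}] = \beta_{fetal} + \tfrac{1}{2}\beta_{maternal},
#'       \quad E[\beta_{off}] = \tfrac{1}{2}\beta_{fetal} + \beta_{maternal},}
#' which invert to
#' \deqn{\beta_{maternal} = (4\beta_{off} - 2\beta_{own})/3, \quad
#'       \beta_{fetal} = (4\beta_{own} - 2\beta_{off})/3.}
#' Sampling variances follow by the same linear combination, allowing for a
#' user-supplied sampling covariance between the two marginal betas
#' (non-zero when the two GWAS share individuals):
#' \deqn{var(\beta_{maternal}) = (16\,se_{off}^2 + 4\,se_{own}^2 -
#'       16\,cov)/9,} and symmetrically for the fetal effect.
#'
#' @param pairs Data frame with columns `snp`, `beta_own`, `se_own`,
#'   `beta_off`, `se_off` and optionally `cov_own_off` (default 0; must
#'   satisfy `|cov| <= se_own * se_off`). Betas in outcome SD units.
#' @return A tibble with `snp`, `beta_maternal`, `se_maternal`,
#'   `beta_fetal`, `se_fetal`, preserving input order.
#' @export
wlm_decompose <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  required <- c("snp", "beta_own", "se_own", "beta_off", "se_off")
  missing_cols <- setdiff(required, names(pairs))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "maternalmr_format_error")
  }
  if (!"cov_own_off" %in% names(pairs)) pairs$cov_own_off <- 0
  pairs$cov_own_off[is.na(pairs$cov_own_off)] <- 0
  if (any(pairs$se_own <= 0) || any(pairs$se_off <= 0)) {
    abort("standard errors must be positive", class = "maternalmr_domain_error")
  }
  if (any(abs(pairs$cov_own_off) > pairs$se_own * pairs$se_off + 1e-12)) {
    abort("|cov_own_off| may not exceed se_own * se_off",
          class = "maternalmr_domain_error")
  }
  var_mat <- (16 * pairs$se_off^2 + 4 * pairs$se_own^2 - 16 * pairs$cov_own_off) / 9
  var_fet <- (16 * pairs$se_own^2 + 4 * pairs$se_off^2 - 16 * pairs$cov_own_off) / 9
  if (any(var_mat <= 0) || any(var_fet <= 0)) {
    abort("degenerate covariance: decomposed variance is non-positive",
          class = "maternalmr_degenerate_covariance")
  }
  tibble::tibble(
    snp = pairs$snp,
    beta_maternal = (4 * pairs$beta_off - 2 * pairs$beta_own) / 3,
    se_maternal = sqrt(var_mat),
    beta_fetal = (4 * pairs$beta_own - 2 * pairs$beta_off) / 3,
    se_fetal = sqrt(var_fet)
  )
}

#' Forward model: marginal betas implied by maternal and fetal effects
#'
#' Inverse of [wlm_decompose()] in the noiseless case; mainly used to
#' validate the decomposition and to build simulated inputs.
#'
#' @param beta_maternal,beta_fetal Numeric vectors of true effects.
#' @return A tibble with `beta_own` and `beta_off`.
#' @export
wlm_forward <- function(beta_maternal, beta_fetal) {
  tibble::tibble(
    beta_own = beta_fetal + beta_maternal / 2,
    beta_off = beta_fetal / 2 + beta_maternal
  )
}

#' Combine maternal-effect estimates from independent sample classes
#'
#' Fixed-effect inverse-variance-weighted meta-analysis of per-class
#' estimates of the same maternal effect, as used to merge sample classes
#' (own-birthweight-only, offspring-birthweight-only, both) into a single
#' per-SNP estimate.
#'
#' @param estimates Data frame with columns `beta` and `se` (one row per
#'   independent sample class).
#' @return A one-row tibble with `beta` and `se`.
#' @export
wlm_combine <- function(estimates) {
  estimates <- tibble::as_tibble(estimates)
  res <- ivw_mean(estimates$beta, estimates$se)
  tibble::tibble(beta = res$beta, se = res$se)
}
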