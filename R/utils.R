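# Internal helpers shared across the estimator and IO modules.

Z95 <- qnorm(0.975)

#' Build a single-row causal-estimate tibble
#'
#' All pooled estimators in the package report their result in a common
#' one-row tibble: method label, point estimate, standard error, 95% Wald
#' confidence interval, two-sided normal p-value, number of instruments and
#' a unit label. Rows from different methods stack into a tidy results table.
#'
#' @param method Method label, e.g. `"wald_ivw_fixed"`.
#' @param beta Point estimate.
#' @param se Standard error (> 0).
#' @param n_snps Number of instruments contributing after exclusions.
#' @param unit_label Free-text units, e.g. `"SD birthweight per SD exposure"`.
#' @return A one-row tibble with columns `method`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, `n_snps`, `unit_label`.
#' @export
mr_estimate <- function(method, beta, se, n_snps, unit_label = "SD outcome per SD exposure") {
  beta <- unname(beta); se <- unname(se)
  stopifnot(is.character(method), length(beta) == 1L, is.finite(beta))
  if (!is.finite(se) || se <= 0) {
    abort("standard error must be positive and finite", class = "maternalmr_domain_error")
  }
  tibble::tibble(
    method = method,
    beta = beta,
    se = se,
    ci_low = beta - Z95 * se,
    ci_high = beta + Z95 * se,
    pvalue = 2 * pnorm(-abs(beta / se)),
    n_snps = as.integer(n_snps),
    unit_label = unit_label
  )
}

# Fixed-effect inverse-variance-weighted mean of independent estimates.
# Returns list(beta, se). Shared by wlm_combine(), ivw_pool(), pool_cohorts().
ivw_mean <- function(beta, se) {
  if (length(beta) == 0L) {
    abort("at least one estimate is required", class = "maternalmr_empty_input")
  }
  if (any(!is.finite(se)) || any(se <= 0)) {
    abort("all standard errors must be positive and finite",
          class = "maternalmr_domain_error")
  }
  w <- 1 / se^2
  list(beta = sum(w * beta) / sum(w), se = sqrt(1 / sum(w)))
}

# Derive a reproducible 32-bit sub-seed from a base seed and a stream index,
# so independent simulation stages use distinct but deterministic streams.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 16807) %% (.Machine$integer.max - 1) + 1
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
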