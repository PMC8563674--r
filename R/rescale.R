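#' Rescale causal estimates from SD units to natural outcome units
#'
#' Multiplies the point estimate, standard error and confidence limits of
#' one or more pooled estimates by the size of one outcome SD in natural
#' units (for birthweight, 1 SD is approximately 484 g). P-values are scale
#' invariant and left unchanged.
#'
#' @param estimate A results tibble as produced by [mr_estimate()] or any of
#'   the pooled estimators (may hold several rows).
#' @param outcome_sd Natural units per outcome SD (> 0), e.g. 484 for
#'   birthweight in grams.
#' @param unit_label New unit label; default rewrites the SD label to the
#'   natural unit.
#' @return The rescaled tibble.
#' @export
rescale_estimate <- function(estimate, outcome_sd,
                             unit_label = sprintf("%.5g natural units per SD exposure", outcome_sd)) {
  if (!is_scalar_number(outcome_sd) || outcome_sd <= 0) {
    abort("outcome_sd must be a positive number", class = "maternalmr_domain_error")
  }
  dplyr::mutate(
    tibble::as_tibble(estimate),
    dplyr::across(dplyr::any_of(c("beta", "se", "ci_low", "ci_high")),
                  ~ .x * outcome_sd),
    unit_label = unit_label
  )
}
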