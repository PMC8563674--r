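#' Multivariable MR
#'
#' Joint weighted least-squares regression of the SNP-outcome betas on the
#' SNP-exposure betas of several exposures, without intercept and with
#' weights `1/se_y^2`. Each coefficient estimates the *direct* effect of its
#' exposure on the outcome holding the other exposures fixed; comparing a
#' univariable estimate with its multivariable counterpart after adding a
#' putative mediator (here, fasting glucose for the BMI-birthweight
#' relation) quantifies mediation. With a single exposure the fit reduces
#' exactly to fixed-effect IVW.
#'
#' @param data Data frame with the outcome association columns and one
#'   column of exposure betas per exposure.
#' @param exposures Character vector naming the exposure beta columns
#'   (`n_snps` must exceed their number).
#' @param beta_y,se_y Names of the outcome beta and SE columns.
#' @param unit_label Passed to the result rows.
#' @return An estimate tibble with one `"mvmr"` row per exposure; the
#'   `exposure` column names the trait.
#' @export
mvmr <- function(data, exposures, beta_y = "beta_y", se_y = "se_y",
                 unit_label = "SD outcome per SD exposure") {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c(exposures, beta_y, se_y), names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "maternalmr_format_error")
  }
  X <- as.matrix(data[, exposures, drop = FALSE])
  y <- data[[beta_y]]
  w <- 1 / data[[se_y]]^2
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k) {
    abort("multivariable MR needs more SNPs than exposures",
          class = "maternalmr_insufficient_data")
  }
  Xw <- X * sqrt(w)
  qr_x <- qr(Xw)
  if (qr_x$rank < k) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):k]]
    abort(paste0("collinear exposure column(s): ", paste(bad, collapse = ", ")),
          class = "maternalmr_collinearity_error")
  }
  fit <- lm(y ~ 0 + X, weights = w)
  est <- coef(fit)
  ses <- sqrt(diag(summary(fit)$cov.unscaled) * max(1, sum(w * fit$residuals^2) / (n - k)))
  out <- purrr::list_rbind(purrr::map(seq_len(k), function(j) {
    mr_estimate("mvmr", est[[j]], ses[[j]], n, unit_label)
  }))
  dplyr::bind_cols(tibble::tibble(exposure = exposures), out)
}
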