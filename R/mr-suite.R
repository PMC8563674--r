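#' Run the full causal-estimator suite on a harmonised table
#'
#' Convenience wrapper running the main fixed-effect IVW analysis together
#' with the sensitivity estimators (multiplicative-random-effects IVW,
#' MR-Egger slope and intercept, weighted median), Cochran's Q / I-squared
#' heterogeneity, leave-one-out analysis and radial-MR outlier detection,
#' returning everything as one object.
#'
#' @inheritParams mr_egger
#' @param methods Character subset of
#'   `c("ivw", "ivw_mre", "egger", "weighted_median", "leave_one_out", "radial")`.
#' @param n_boot,seed Weighted-median bootstrap controls.
#' @param radial_alpha Per-SNP outlier threshold for radial MR.
#' @return An object of class `mr_result`: a list with `estimates` (tidy
#'   tibble, one row per method), `heterogeneity`, `leave_one_out`,
#'   `radial`, `ratios`, `n_snps` and `failures` (named character vector of
#'   methods that errored, with messages). Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @export
mr_all <- function(harmonised,
                   methods = c("ivw", "ivw_mre", "egger", "weighted_median",
                               "leave_one_out", "radial"),
                   n_boot = 1000, seed = 1, radial_alpha = 0.05,
                   unit_label = "SD outcome per SD exposure") {
  h <- tibble::as_tibble(harmonised)
  if ("excluded_reason" %in% names(h)) h <- harmonised_kept(h)
  ratios <- wald_ratios(h)
  failures <- character(0)
  note_failure <- function(name, err) {
    failures[[name]] <<- conditionMessage(err)
    NULL
  }
  run <- function(name, expr) tryCatch(expr, error = function(e) note_failure(name, e))

  pieces <- list()
  if ("ivw" %in% methods) {
    pieces$ivw <- run("ivw", ivw_pool(ratios, "fixed", unit_label))
  }
  if ("ivw_mre" %in% methods) {
    pieces$ivw_mre <- run("ivw_mre", ivw_pool(ratios, "multiplicative_random", unit_label))
  }
  if ("egger" %in% methods) {
    pieces$egger <- run("egger", mr_egger(h, unit_label))
  }
  if ("weighted_median" %in% methods) {
    pieces$wm <- run("weighted_median",
                     weighted_median(h, n_boot = n_boot, seed = seed,
                                     unit_label = unit_label))
  }
  heterogeneity <- if (nrow(ratios) >= 2L) cochran_q(ratios) else NULL
  loo <- if ("leave_one_out" %in% methods) {
    run("leave_one_out", leave_one_out(h, unit_label = unit_label))
  }
  radial <- if ("radial" %in% methods) {
    run("radial", radial_mr(h, alpha = radial_alpha, unit_label = unit_label))
  }

  structure(
    list(
      estimates = purrr::list_rbind(purrr::compact(unname(pieces))),
      heterogeneity = heterogeneity,
      leave_one_out = loo,
      radial = radial,
      ratios = ratios,
      n_snps = nrow(ratios),
      failures = failures
    ),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result: %d instruments>\n", x$n_snps))
  print(x$estimates)
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("Heterogeneity: Q = %.2f (df = %d), I2 = %.1f%%, p = %.3g\n",
                x$heterogeneity$Q, x$heterogeneity$df,
                x$heterogeneity$i2_percent, x$heterogeneity$pvalue))
  }
  if (length(x$failures)) {
    cat("Failed methods:", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy the estimator suite into one row per method
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return Tibble with broom-style columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`, `n_snps`.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  dplyr::transmute(
    x$estimates,
    term = .data$method, estimate = .data$beta, std.error = .data$se,
    conf.low = .data$ci_low, conf.high = .data$ci_high,
    p.value = .data$pvalue, n_snps = .data$n_snps
  )
}

#' One-row summary of an estimator-suite fit
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return One-row tibble: IVW estimate, heterogeneity Q / I-squared, SNP
#'   and radial-outlier counts.
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  ivw <- dplyr::filter(x$estimates, .data$method == "wald_ivw_fixed")
  tibble::tibble(
    n_snps = x$n_snps,
    ivw_beta = if (nrow(ivw)) ivw$beta else NA_real_,
    ivw_se = if (nrow(ivw)) ivw$se else NA_real_,
    Q = if (!is.null(x$heterogeneity)) x$heterogeneity$Q else NA_real_,
    i2_percent = if (!is.null(x$heterogeneity)) x$heterogeneity$i2_percent else NA_real_,
    n_radial_outliers = if (!is.null(x$radial)) sum(x$radial$rows$is_outlier) else NA_integer_
  )
}

#' Forest plot of the estimator suite
#'
#' @param object An `mr_result`.
#' @param ... Unused.
#' @return A ggplot: point estimate and 95% CI per method.
#' @method autoplot mr_result
#' @export
autoplot.mr_result <- function(object, ...) {
  d <- object$estimates
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = unique(d$unit_label)[1], y = NULL) +
    ggplot2::theme_minimal()
}

#' Radial diagnostic plot
#'
#' Plots each SNP on the radial scale (`beta_x/se_y` against
#' `beta_y/se_y`) with the fitted slope, highlighting outliers.
#'
#' @param harmonised Harmonised table.
#' @param radial Result of [radial_mr()] on the same table; computed if
#'   `NULL`.
#' @param alpha,model Passed to [radial_mr()] when `radial` is `NULL`.
#' @return A ggplot.
#' @export
plot_radial <- function(harmonised, radial = NULL, alpha = 0.05, model = "ivw") {
  h <- harmonised_kept(tibble::as_tibble(harmonised))
  if (is.null(radial)) radial <- radial_mr(h, alpha = alpha, model = model)
  d <- dplyr::mutate(h, x_r = .data$beta_x / .data$se_y,
                     y_r = .data$beta_y / .data$se_y,
                     outlier = radial$rows$is_outlier)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_r, y = .data$y_r,
                                  colour = .data$outlier)) +
    ggplot2::geom_abline(intercept = 0, slope = radial$estimate$beta,
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(x = "sqrt(weight)", y = "ratio * sqrt(weight)",
                  colour = "outlier") +
    ggplot2::theme_minimal()
}
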