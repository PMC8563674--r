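# Weighted median of ratio estimates: order thetas ascending, form
# standardised cumulative weights p_j = (sum_{i<=j} w_i - w_j/2) / sum(w),
# and interpolate linearly between the two ratios bracketing p = 0.5.
weighted_median_point <- function(theta, weight) {
  ord <- order(theta)
  theta <- theta[ord]
  weight <- weight[ord]
  p <- (cumsum(weight) - weight / 2) / sum(weight)
  if (p[1] >= 0.5) return(theta[1])
  n <- length(theta)
  if (p[n] <= 0.5) return(theta[n])
  j <- max(which(p <= 0.5))
  theta[j] + (theta[j + 1] - theta[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios is a consistent causal
#' estimate when at least half the instrument weight comes from valid
#' instruments, making it robust to a minority of pleiotropic SNPs. Ratios
#' are weighted by inverse variance; the estimate interpolates the
#' cumulative-weight distribution at 50%. The standard error comes from a
#' parametric bootstrap: exposure and outcome betas are resampled from
#' normal distributions with their reported SEs, the median recomputed, and
#' the SD over draws taken.
#'
#' @inheritParams mr_egger
#' @param n_boot Bootstrap draws for the SE (default 1000; fewer than 100
#'   triggers a warning).
#' @param seed Integer seed for the bootstrap (required for reproducibility).
#' @return A one-row estimate tibble, method `"weighted_median"`.
#' @export
weighted_median <- function(harmonised, n_boot = 1000, seed = 1,
                            unit_label = "SD outcome per SD exposure") {
  h <- tibble::as_tibble(harmonised)
  if ("excluded_reason" %in% names(h)) h <- harmonised_kept(h)
  if (nrow(h) < 3L) {
    abort("weighted median requires at least three SNPs",
          class = "maternalmr_insufficient_data")
  }
  if (n_boot < 100) {
    warn("n_boot < 100 gives an unstable bootstrap standard error")
  }
  r <- wald_ratios(h)
  point <- weighted_median_point(r$theta, r$weight)

  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(nrow(h), h$beta_x, h$se_x)
      by <- rnorm(nrow(h), h$beta_y, h$se_y)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], (bx[ok] / h$se_y[ok])^2)
    }, numeric(1))
  })
  mr_estimate("weighted_median", point, sd(boot), nrow(h), unit_label)
}

# Evaluate an expression under a local, restored RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
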