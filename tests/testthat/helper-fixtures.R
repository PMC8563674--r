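# Shared fixture builders: all synthetic, constructed in code at test time.

# Minimal per-SNP association row.
assoc <- function(snp, ea, oa, beta, se, eaf = NA_real_) {
  tibble::tibble(snp = snp, effect_allele = ea, other_allele = oa,
                 beta = beta, se = se, eaf = eaf)
}

# A harmonised-table fixture straight from numbers (already oriented).
make_harmonised <- function(beta_x, se_x, beta_y, se_y,
                            snp = sprintf("snp%02d", seq_along(beta_x))) {
  tibble::tibble(
    snp = snp,
    effect_allele = "A", other_allele = "G",
    beta_x = beta_x, se_x = se_x, eaf_x = 0.3,
    beta_y = beta_y, se_y = se_y, eaf_y = 0.3,
    flipped = FALSE, strand_complemented = FALSE,
    excluded_reason = NA_character_
  )
}

# Random harmonised table under a fixed seed (positive exposure betas).
random_harmonised <- function(n, seed) {
  set.seed(seed)
  make_harmonised(
    beta_x = runif(n, 0.02, 0.15),
    se_x = runif(n, 0.005, 0.02),
    beta_y = rnorm(n, 0, 0.05),
    se_y = runif(n, 0.005, 0.03)
  )
}

write_tmp_tsv <- function(df, file = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, file, progress = FALSE)
  file
}

# Independent weighted-median oracle: dense scan over the cumulative-weight
# step function instead of the package's direct interpolation.
oracle_weighted_median <- function(theta, weight) {
  ord <- order(theta)
  th <- theta[ord]; w <- weight[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(p, th, xout = 0.5, rule = 2, ties = "ordered")$y
}
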