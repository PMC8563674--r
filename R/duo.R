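# Individual-level mother-child pair ("duo") analysis. Duo tables are
# tibbles with one row per pair: pair_id, maternal dosage columns m_<snp>,
# child dosage columns c_<snp> (same SNP order and allele orientation),
# an outcome column, and optional covariate columns.

duo_snp_names <- function(duos) {
  m <- sub("^m_", "", grep("^m_", names(duos), value = TRUE))
  c_ <- sub("^c_", "", grep("^c_", names(duos), value = TRUE))
  if (!identical(m, c_)) {
    abort("maternal and child dosage columns do not align",
          class = "maternalmr_alignment_error")
  }
  m
}

#' Maternal genotype effect conditional on fetal genotype
#'
#' Ordinary least squares of the outcome on the maternal dosage, the child
#' dosage and any covariates, within complete mother-child pairs. The
#' maternal coefficient is the maternal genetic effect adjusted for the
#' correlated fetal genotype: the individual-level analogue of the
#' summary-level WLM decomposition.
#'
#' @param duos Duo table (see [simulate_duos()] for the layout).
#' @param snp SNP identifier (the part after `m_` / `c_`).
#' @param covariates Character vector of covariate column names (optional).
#' @param outcome Name of the outcome column.
#' @return One-row tibble: `snp`, `beta`, `se`, `pvalue`, `n_pairs` for the
#'   maternal coefficient.
#' @export
conditional_maternal_effect <- function(duos, snp, covariates = NULL,
                                        outcome = "outcome") {
  duos <- tibble::as_tibble(duos)
  mcol <- paste0("m_", snp); ccol <- paste0("c_", snp)
  cols <- c(mcol, ccol, outcome, covariates)
  missing_cols <- setdiff(cols, names(duos))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "maternalmr_format_error")
  }
  d <- duos[complete.cases(duos[, cols]), cols]
  n_dropped <- nrow(duos) - nrow(d)
  if (n_dropped > 0) {
    inform(sprintf("conditional_maternal_effect(%s): dropped %d incomplete pair(s)",
                   snp, n_dropped))
  }
  if (nrow(d) < 30L) {
    abort("fewer than 30 complete mother-child pairs",
          class = "maternalmr_insufficient_data")
  }
  gm <- d[[mcol]]; gc_ <- d[[ccol]]
  if (var(gm) == 0 || var(gc_) == 0) {
    abort("dosage vector has no variance", class = "maternalmr_degenerate_error")
  }
  if (abs(stats::cor(gm, gc_)) > 0.999) {
    abort("maternal and child dosages are collinear",
          class = "maternalmr_collinearity_error")
  }
  fit <- lm(stats::reformulate(c(mcol, ccol, covariates), response = outcome),
            data = d)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    snp = snp,
    beta = sm[mcol, "Estimate"],
    se = sm[mcol, "Std. Error"],
    pvalue = sm[mcol, "Pr(>|t|)"],
    n_pairs = nrow(d)
  )
}

#' Conditional maternal effects for every SNP in a duo table
#'
#' @inheritParams conditional_maternal_effect
#' @return Tibble with one row per SNP in table order.
#' @export
duo_conditional_scan <- function(duos, covariates = NULL, outcome = "outcome") {
  snps <- duo_snp_names(duos)
  purrr::list_rbind(purrr::map(snps, function(s) {
    conditional_maternal_effect(duos, s, covariates = covariates,
                                outcome = outcome)
  }))
}

#' Weighted genetic score
#'
#' Per-individual weighted allele count
#' \eqn{\sum_j w_j \, dosage_{ij}}, with weights in exposure units aligned
#' to the harmonised exposure-increasing allele.
#'
#' @param duos Duo table.
#' @param weights Data frame with columns `snp` and `weight`.
#' @param who `"mother"` or `"child"`: which dosage block to score.
#' @return Numeric vector, one score per pair.
#' @export
genetic_score <- function(duos, weights, who = c("mother", "child")) {
  who <- match.arg(who)
  duos <- tibble::as_tibble(duos)
  weights <- tibble::as_tibble(weights)
  prefix <- if (who == "mother") "m_" else "c_"
  cols <- paste0(prefix, weights$snp)
  missing_cols <- setdiff(cols, names(duos))
  if (length(missing_cols)) {
    abort(paste0("weights reference SNPs absent from the duo table: ",
                 paste(sub(prefix, "", missing_cols), collapse = ", ")),
          class = "maternalmr_alignment_error")
  }
  as.vector(as.matrix(duos[, cols]) %*% weights$weight)
}

#' Association of a genetic score with a covariate
#'
#' Confounder check for instrument validity: regresses the covariate on the
#' genetic score. Continuous covariates use ordinary least squares; binary
#' covariates (two unique values) use logistic regression and report the
#' log-odds slope.
#'
#' @param score Numeric score vector ([genetic_score()]).
#' @param covariate Numeric (or 0/1) covariate of the same length.
#' @return One-row tibble: `beta`, `se`, `pvalue`, `model` (`"linear"` or
#'   `"logistic"`), `n`.
#' @export
score_covariate_check <- function(score, covariate) {
  if (length(score) != length(covariate)) {
    abort("score and covariate lengths differ", class = "maternalmr_alignment_error")
  }
  ok <- is.finite(score) & is.finite(covariate)
  score <- score[ok]; covariate <- covariate[ok]
  vals <- unique(covariate)
  if (length(vals) < 2L) {
    abort("covariate is constant", class = "maternalmr_degenerate_error")
  }
  if (length(vals) == 2L) {
    y <- as.integer(covariate == max(vals))
    fit <- glm(y ~ score, family = binomial())
    sm <- summary(fit)$coefficients
    tibble::tibble(beta = sm["score", "Estimate"], se = sm["score", "Std. Error"],
                   pvalue = sm["score", "Pr(>|z|)"], model = "logistic",
                   n = length(score))
  } else {
    fit <- lm(covariate ~ score)
    sm <- summary(fit)$coefficients
    tibble::tibble(beta = sm["score", "Estimate"], se = sm["score", "Std. Error"],
                   pvalue = sm["score", "Pr(>|t|)"], model = "linear",
                   n = length(score))
  }
}

#' Pool per-cohort estimates by fixed-effect meta-analysis
#'
#' Inverse-variance-weighted combination of independent per-cohort
#' estimates of the same effect (e.g. per-cohort pooled Wald ratios from
#' the individual-level secondary analyses).
#'
#' @param per_cohort Data frame with columns `beta` and `se`, one row per
#'   cohort.
#' @param unit_label Passed to the result row.
#' @return One-row estimate tibble, method `"pooled_cohorts"`; `n_snps`
#'   records the number of contributing cohorts.
#' @export
pool_cohorts <- function(per_cohort, unit_label = "SD outcome per SD exposure") {
  per_cohort <- tibble::as_tibble(per_cohort)
  res <- ivw_mean(per_cohort$beta, per_cohort$se)
  mr_estimate("pooled_cohorts", res$beta, res$se, nrow(per_cohort), unit_label)
}
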