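# Synthetic mother-child population generator. All randomness flows through
# the seed carried by the config, with draws made in a fixed order so a
# given config is reproducible across platforms.

NONPALINDROMIC_PAIRS <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))

#' Build and validate a simulation configuration
#'
#' Describes a synthetic mother-child population: biallelic instrument SNPs
#' with given allele frequencies and per-allele effects on a maternal
#' exposure; the exposure (unit variance, "SD units") built from the
#' maternal genetic score plus noise; a scalar mediator (the fasting-glucose
#' role) carrying a configurable fraction of the maternal causal path; and a
#' child outcome (SD units) combining the maternal causal effect, optional
#' per-SNP fetal direct effects, optional horizontal pleiotropy and noise.
#' Children receive one allele transmitted from the mother and one paternal
#' allele drawn from the population frequency, giving the mother-child
#' dosage correlation of 0.5 that the maternal/fetal decomposition exploits.
#'
#' @param n_snps Number of instrument SNPs (>= 1).
#' @param allele_freqs Effect-allele frequencies in (0.05, 0.95); default
#'   evenly spaced over \[0.15, 0.85\].
#' @param snp_exposure_betas Per-allele effects on the exposure before
#'   scaling; default a declining series. When `rescale_betas = TRUE`
#'   (default) they are rescaled so the genetic score explains exactly
#'   `exposure_h2_target` of the unit exposure variance.
#' @param exposure_h2_target Proportion of exposure variance explained by
#'   the score, in (0, 1). Default 0.027 (the share of BMI variance the 76
#'   BMI instruments explain in their source GWAS).
#' @param theta_maternal Causal effect of the maternal exposure on the
#'   outcome, SD outcome per SD exposure.
#' @param mediation_fraction Share of the maternal causal path routed
#'   through the mediator, in (0, 1\].
#' @param beta_fetal_direct Per-SNP fetal direct effects on the outcome
#'   (recycled; default 0).
#' @param pleiotropy List with `mode` (`"none"`, `"balanced"`,
#'   `"directional"`), `n_pleiotropic`, `magnitude` (per-allele outcome
#'   effect) and optional `channel` (`"maternal"`, the default, or
#'   `"fetal"`).
#' @param n_individuals Number of mother-child pairs.
#' @param mediator_noise_sd SD of mediator-specific noise around the
#'   exposure (default 0.5).
#' @param mediator_snp_effects Per-SNP direct genetic effects on the
#'   mediator beyond the exposure path (recycled; default 0). Non-zero
#'   values give the mediator its own genetic signal, which is what makes
#'   multivariable MR mediation analysis identifiable.
#' @param rescale_betas Rescale `snp_exposure_betas` to hit
#'   `exposure_h2_target` exactly (default). If `FALSE` the betas are taken
#'   literally and the score variance must stay below the unit exposure
#'   variance.
#' @param seed Integer seed (mandatory).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 14,
                       allele_freqs = NULL,
                       snp_exposure_betas = NULL,
                       exposure_h2_target = 0.027,
                       theta_maternal = -0.2,
                       mediation_fraction = 0.6,
                       beta_fetal_direct = 0,
                       pleiotropy = list(mode = "none", n_pleiotropic = 0,
                                         magnitude = 0),
                       n_individuals = 20000,
                       mediator_noise_sd = 0.5,
                       mediator_snp_effects = 0,
                       rescale_betas = TRUE,
                       seed) {
  if (missing(seed) || !is_scalar_number(seed)) {
    abort("a scalar integer seed is mandatory", class = "maternalmr_config_error")
  }
  if (!is_scalar_number(n_snps) || n_snps < 1) {
    abort("n_snps must be >= 1", class = "maternalmr_config_error")
  }
  n_snps <- as.integer(n_snps)
  if (is.null(allele_freqs)) {
    allele_freqs <- if (n_snps == 1L) 0.5 else seq(0.15, 0.85, length.out = n_snps)
  }
  if (length(allele_freqs) != n_snps ||
      any(allele_freqs <= 0.05 | allele_freqs >= 0.95)) {
    abort("allele_freqs must have length n_snps with values in (0.05, 0.95)",
          class = "maternalmr_config_error")
  }
  if (is.null(snp_exposure_betas)) {
    # skewed effect-size ladder: a few strong and many weak instruments,
    # as GWAS instrument sets typically show
    snp_exposure_betas <- seq_len(n_snps)^(-0.5)
  }
  if (length(snp_exposure_betas) != n_snps) {
    abort("snp_exposure_betas must have length n_snps",
          class = "maternalmr_config_error")
  }
  if (!is_scalar_number(exposure_h2_target) ||
      exposure_h2_target <= 0 || exposure_h2_target >= 1) {
    abort("exposure_h2_target must lie in (0, 1)", class = "maternalmr_config_error")
  }
  if (!is_scalar_number(mediation_fraction) ||
      mediation_fraction <= 0 || mediation_fraction > 1) {
    abort("mediation_fraction must lie in (0, 1]", class = "maternalmr_config_error")
  }
  beta_fetal_direct <- rep_len(beta_fetal_direct, n_snps)
  mediator_snp_effects <- rep_len(mediator_snp_effects, n_snps)
  pleiotropy$mode <- pleiotropy$mode %||% "none"
  pleiotropy$n_pleiotropic <- pleiotropy$n_pleiotropic %||% 0L
  pleiotropy$magnitude <- pleiotropy$magnitude %||% 0
  pleiotropy$channel <- pleiotropy$channel %||% "maternal"
  if (!pleiotropy$mode %in% c("none", "balanced", "directional")) {
    abort("pleiotropy mode must be none, balanced or directional",
          class = "maternalmr_config_error")
  }
  if (!pleiotropy$channel %in% c("maternal", "fetal")) {
    abort("pleiotropy channel must be maternal or fetal",
          class = "maternalmr_config_error")
  }
  if (pleiotropy$n_pleiotropic > n_snps) {
    abort("n_pleiotropic exceeds n_snps", class = "maternalmr_config_error")
  }

  score_var <- sum(2 * allele_freqs * (1 - allele_freqs) * snp_exposure_betas^2)
  if (score_var <= 0) {
    abort("genetic score has zero variance", class = "maternalmr_config_error")
  }
  if (rescale_betas) {
    snp_exposure_betas <- snp_exposure_betas *
      sqrt(exposure_h2_target / score_var)
    h2 <- exposure_h2_target
  } else {
    h2 <- score_var
    if (h2 >= 1) {
      abort("infeasible heritability: score variance exceeds the unit exposure variance target",
            class = "maternalmr_config_error")
    }
  }

  structure(list(
    n_snps = n_snps,
    snp_ids = sprintf("snp%02d", seq_len(n_snps)),
    allele_freqs = allele_freqs,
    snp_exposure_betas = snp_exposure_betas,
    exposure_h2 = h2,
    theta_maternal = theta_maternal,
    mediation_fraction = mediation_fraction,
    beta_fetal_direct = beta_fetal_direct,
    pleiotropy = pleiotropy,
    n_individuals = as.integer(n_individuals),
    mediator_noise_sd = mediator_noise_sd,
    mediator_snp_effects = mediator_snp_effects,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Per-SNP pleiotropic outcome effects implied by a config. Pleiotropic SNPs
# are spread evenly across the effect-size ladder so pleiotropy status is
# unrelated to instrument strength (the InSIDE condition holds by design).
pleiotropic_effects <- function(config) {
  alpha <- numeric(config$n_snps)
  pl <- config$pleiotropy
  if (pl$mode != "none" && pl$n_pleiotropic > 0) {
    idx <- unique(round(seq_len(pl$n_pleiotropic) * config$n_snps / pl$n_pleiotropic))
    sign_vec <- if (pl$mode == "balanced") rep_len(c(1, -1), length(idx)) else 1
    alpha[idx] <- pl$magnitude * sign_vec
  }
  alpha
}

snp_allele_table <- function(config) {
  pairs <- NONPALINDROMIC_PAIRS[((seq_len(config$n_snps) - 1L) %% 4L) + 1L]
  tibble::tibble(
    snp = config$snp_ids,
    effect_allele = vapply(pairs, `[`, "", 1L),
    other_allele = vapply(pairs, `[`, "", 2L),
    freq = config$allele_freqs
  )
}

#' Simulate a mother-child duo population
#'
#' Draws, in a fixed seeded order: maternal genotypes (Binomial(2, f) per
#' SNP under Hardy-Weinberg), child genotypes (one allele transmitted
#' uniformly from the mother plus one paternal Bernoulli(f) allele),
#' exposure noise, mediator noise, outcome noise and a balanced binary
#' `sex` covariate. The outcome (SD units) is
#' `theta * (mf * mediator + (1 - mf) * exposure)` plus fetal direct
#' effects on the child dosage, pleiotropic effects on the configured
#' dosage channel, and residual noise scaled so the outcome variance is
#' close to one.
#'
#' @param config A [sim_config()].
#' @return A list with `duos` (tibble: `pair_id`, maternal `m_<snp>` and
#'   child `c_<snp>` dosages, `exposure`, `mediator`, `outcome`, `sex`;
#'   SNP metadata in the `"snp_info"` attribute) and `truth` (ground-truth
#'   parameters, including the realised exposure variance explained).
#' @export
simulate_duos <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  p <- config$n_snps
  f <- config$allele_freqs
  set.seed(config$seed)

  g_m <- matrix(rbinom(n * p, 2L, rep(f, each = n)), nrow = n)
  transmitted <- matrix(rbinom(n * p, 1L, g_m / 2), nrow = n)
  paternal <- matrix(rbinom(n * p, 1L, rep(f, each = n)), nrow = n)
  g_c <- transmitted + paternal

  score <- as.vector(g_m %*% config$snp_exposure_betas)
  exposure <- score + rnorm(n, sd = sqrt(1 - config$exposure_h2))
  mediator <- exposure + as.vector(g_m %*% config$mediator_snp_effects) +
    rnorm(n, sd = config$mediator_noise_sd)

  mf <- config$mediation_fraction
  theta <- config$theta_maternal
  alpha <- pleiotropic_effects(config)
  g_pleio <- if (config$pleiotropy$channel == "fetal") g_c else g_m
  signal <- theta * (mf * mediator + (1 - mf) * exposure) +
    as.vector(g_c %*% config$beta_fetal_direct) +
    as.vector(g_pleio %*% alpha)
  hw_var <- 2 * f * (1 - f)
  signal_var <- theta^2 * (1 + mf^2 * config$mediator_noise_sd^2) +
    sum(hw_var * (config$beta_fetal_direct^2 + alpha^2 +
                    (theta * mf * config$mediator_snp_effects)^2))
  noise_sd <- sqrt(max(0.1, 1 - signal_var))
  outcome <- signal + rnorm(n, sd = noise_sd)
  sex <- rbinom(n, 1L, 0.5)

  colnames(g_m) <- paste0("m_", config$snp_ids)
  colnames(g_c) <- paste0("c_", config$snp_ids)
  duos <- dplyr::bind_cols(
    tibble::tibble(pair_id = seq_len(n)),
    tibble::as_tibble(g_m), tibble::as_tibble(g_c),
    tibble::tibble(exposure = exposure, mediator = mediator,
                   outcome = outcome, sex = sex)
  )
  attr(duos, "snp_info") <- snp_allele_table(config)

  truth <- structure(list(
    theta_maternal = theta,
    mediation_fraction = mf,
    snp_exposure_betas = config$snp_exposure_betas,
    mediator_snp_effects = config$mediator_snp_effects,
    pleiotropic_effects = alpha,
    pleiotropy_channel = config$pleiotropy$channel,
    beta_fetal_direct = config$beta_fetal_direct,
    allele_freqs = f,
    exposure_h2_target = config$exposure_h2,
    exposure_h2_realised = var(score) / var(exposure),
    outcome_noise_sd = noise_sd,
    seed = config$seed
  ), class = "sim_truth")

  list(duos = duos, truth = truth)
}

# Vectorised per-SNP simple linear regression of y on each column of G.
gwas_scan <- function(G, y) {
  n <- nrow(G)
  cm <- colMeans(G)
  yc <- y - mean(y)
  ss_g <- unname(colSums(G^2) - n * cm^2)
  poly <- ss_g > 0
  sxy <- as.vector(crossprod(G, yc))
  beta <- ifelse(poly, sxy / ss_g, NA_real_)
  ss_y <- sum(yc^2)
  rss <- pmax(ss_y - beta^2 * ss_g, 0)
  se <- sqrt(rss / ((n - 2) * ss_g))
  list(beta = beta, se = se, eaf = unname(cm / 2),
       p = 2 * stats::pt(-abs(beta / se), n - 2), polymorphic = poly)
}

#' Per-SNP GWAS from a duo population
#'
#' Runs, for every SNP, the simple regression that a marginal GWAS would:
#' the exposure or the mediator on the maternal dosage (`trait =
#' "exposure"` / `"mediator"`), the outcome on the child's own dosage
#' (`"own_outcome"`), or the outcome on the maternal dosage, i.e. the
#' offspring-birthweight design (`"offspring_outcome"`). Monomorphic SNPs
#' are excluded with a reason (attached as the `"excluded"` attribute).
#'
#' @param duos Duo tibble from [simulate_duos()].
#' @param trait One of `"exposure"`, `"own_outcome"`, `"offspring_outcome"`.
#' @param rows Optional row subset defining the GWAS sample.
#' @return Tibble of per-SNP associations: `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `p`, `n`.
#' @export
gwas_from_duos <- function(duos, trait = c("exposure", "own_outcome",
                                           "offspring_outcome", "mediator"),
                           rows = NULL) {
  trait <- match.arg(trait)
  info <- attr(duos, "snp_info")
  if (is.null(info)) {
    info <- tibble::tibble(snp = duo_snp_names(duos),
                           effect_allele = "A", other_allele = "G",
                           freq = NA_real_)
  }
  if (!is.null(rows)) duos <- duos[rows, ]
  block <- if (trait == "own_outcome") "c_" else "m_"
  y <- switch(trait, exposure = duos$exposure, mediator = duos$mediator,
              duos$outcome)
  G <- as.matrix(duos[, paste0(block, info$snp)])
  fit <- gwas_scan(G, y)
  out <- tibble::tibble(
    snp = info$snp,
    effect_allele = info$effect_allele,
    other_allele = info$other_allele,
    eaf = fit$eaf,
    beta = fit$beta,
    se = fit$se,
    p = fit$p,
    n = nrow(duos)
  )
  excluded <- out[!fit$polymorphic, "snp"]
  excluded$reason <- if (nrow(excluded)) "monomorphic" else character(0)
  out <- out[fit$polymorphic, ]
  attr(out, "excluded") <- excluded
  out
}

#' Generate a two-sample summary-statistic dataset with known truth
#'
#' Simulates two non-overlapping populations from the same configuration
#' (distinct seeded streams). The exposure GWAS comes from the mothers of
#' population 1. Population 2 supplies the outcome side and is split into
#' two disjoint halves so the two marginal birthweight GWAS are independent:
#' the first half contributes the own-birthweight GWAS (child dosage), the
#' second the offspring-birthweight GWAS (maternal dosage), mirroring the
#' own-birthweight-only and offspring-birthweight-only sample classes the
#' maternal/fetal decomposition was designed to combine (`cov_own_off = 0`).
#'
#' @param config A [sim_config()]; `n_individuals` is the size of *each*
#'   population.
#' @param keep_populations Also return the two simulated duo tables
#'   (`pop1`, `pop2`); off by default to keep the result small.
#' @return A list with `exposure` (an [instrument_set()]), `outcome`
#'   (tibble: `snp`, alleles, `eaf`, `beta_own`, `se_own`, `beta_off`,
#'   `se_off`, `cov_own_off`), and `truth`.
#' @export
make_two_sample_dataset <- function(config, keep_populations = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cfg1 <- config; cfg1$seed <- as.integer(derive_seed(config$seed, 1L))
  cfg2 <- config; cfg2$seed <- as.integer(derive_seed(config$seed, 2L))

  pop1 <- simulate_duos(cfg1)
  exposure_gwas <- gwas_from_duos(pop1$duos, "exposure")
  exposure <- instrument_set(exposure_gwas, exposure_name = "exposure",
                             unit_label = "SD exposure per allele", quiet = TRUE)

  pop2 <- simulate_duos(cfg2)
  n2 <- nrow(pop2$duos)
  half <- seq_len(n2 %/% 2)
  own <- gwas_from_duos(pop2$duos, "own_outcome", rows = half)
  off <- gwas_from_duos(pop2$duos, "offspring_outcome", rows = setdiff(seq_len(n2), half))
  outcome <- tibble::tibble(
    snp = own$snp,
    effect_allele = own$effect_allele,
    other_allele = own$other_allele,
    eaf = own$eaf,
    beta_own = own$beta, se_own = own$se,
    beta_off = off$beta[match(own$snp, off$snp)],
    se_off = off$se[match(own$snp, off$snp)],
    cov_own_off = 0
  )
  truth <- pop1$truth
  truth$exposure_h2_realised <- c(pop1 = pop1$truth$exposure_h2_realised,
                                  pop2 = pop2$truth$exposure_h2_realised)
  out <- list(exposure = exposure, outcome = outcome, truth = truth)
  if (keep_populations) {
    out$pop1 <- pop1$duos
    out$pop2 <- pop2$duos
  }
  out
}

#' Maternal outcome associations from own/offspring GWAS pairs
#'
#' Applies [wlm_decompose()] to a table of own- and offspring-birthweight
#' associations and returns the maternal effects in the layout
#' [harmonise()] expects on the outcome side.
#'
#' @param pairs Table with `snp`, allele columns, optional `eaf`,
#'   `beta_own`, `se_own`, `beta_off`, `se_off`, optional `cov_own_off`.
#' @return Tibble: `snp`, `effect_allele`, `other_allele`, `eaf`, `beta`
#'   (maternal), `se`, plus `beta_fetal`, `se_fetal` for reference.
#' @export
wlm_maternal_associations <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  dec <- wlm_decompose(pairs)
  tibble::tibble(
    snp = pairs$snp,
    effect_allele = pairs$effect_allele,
    other_allele = pairs$other_allele,
    eaf = if ("eaf" %in% names(pairs)) pairs$eaf else NA_real_,
    beta = dec$beta_maternal,
    se = dec$se_maternal,
    beta_fetal = dec$beta_fetal,
    se_fetal = dec$se_fetal
  )
}
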