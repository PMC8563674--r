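COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonise exposure and outcome associations to the exposure-increasing allele
#'
#' Aligns each outcome association onto the allele orientation of the
#' exposure instrument, then orients every record so the exposure beta is
#' non-negative (the exposure-increasing allele becomes the effect allele).
#' Matching proceeds per SNP: identical alleles are kept as-is; swapped
#' alleles negate the outcome beta and reflect its allele frequency; alleles
#' matching only after strand complementation (A<->T, C<->G) are
#' complemented first; anything else is excluded as an allele mismatch.
#'
#' Palindromic SNPs (A/T or G/C pairs) cannot be strand-resolved from allele
#' labels. They are excluded when either allele frequency is missing or lies
#' within `palindromic_eaf_window` of 0.5; otherwise orientation is resolved
#' by frequency agreement (both frequencies on the same side of 0.5 implies
#' the same strand).
#'
#' @param exposure An [instrument_set()] (or data frame with the same columns).
#' @param outcome Data frame of outcome associations with columns `snp`,
#'   `effect_allele`, `other_allele`, `beta`, `se` and optionally `eaf`.
#' @param palindromic_eaf_window Half-width of the frequency band around 0.5
#'   inside which palindromic SNPs are treated as unresolvable; in
#'   \[0, 0.5\], default 0.08.
#' @return A tibble with one row per exposure SNP: `snp`, `effect_allele`,
#'   `other_allele` (post-orientation), `beta_x`, `se_x`, `eaf_x`, `beta_y`,
#'   `se_y`, `eaf_y`, `flipped`, `strand_complemented`, `excluded_reason`
#'   (`NA` for analysable records). Non-excluded records satisfy
#'   `beta_x >= 0`. Exposure row order is preserved.
#' @export
harmonise <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  if (!is_scalar_number(palindromic_eaf_window) ||
      palindromic_eaf_window < 0 || palindromic_eaf_window > 0.5) {
    abort("palindromic_eaf_window must lie in [0, 0.5]",
          class = "maternalmr_domain_error")
  }
  exposure <- tibble::as_tibble(exposure)
  outcome <- tibble::as_tibble(outcome)
  if (!"eaf" %in% names(outcome)) outcome$eaf <- NA_real_
  if (!"eaf" %in% names(exposure)) exposure$eaf <- NA_real_
  if (!any(exposure$snp %in% outcome$snp)) {
    abort("exposure and outcome share no SNPs", class = "maternalmr_empty_overlap")
  }
  j <- match(exposure$snp, outcome$snp)
  miss <- is.na(j)
  ea_x <- exposure$effect_allele; oa_x <- exposure$other_allele
  ea_y <- outcome$effect_allele[j]; oa_y <- outcome$other_allele[j]
  beta_y <- outcome$beta[j]; se_y <- outcome$se[j]; eaf_y <- outcome$eaf[j]
  eaf_x <- exposure$eaf

  tf <- function(x) unname(!is.na(x) & x)    # NA-safe logical
  pal <- tf(COMPLEMENT[ea_x] == oa_x)
  cea <- unname(COMPLEMENT[ea_y]); coa <- unname(COMPLEMENT[oa_y])
  direct <- tf(ea_y == ea_x & oa_y == oa_x)
  swapped <- tf(ea_y == oa_x & oa_y == ea_x)
  # complementing a palindromic pair is a no-op, so only try the other
  # strand for non-palindromic SNPs
  comp_direct <- !pal & tf(cea == ea_x & coa == oa_x)
  comp_swapped <- !pal & tf(cea == oa_x & coa == ea_x)
  matched <- direct | swapped | comp_direct | comp_swapped

  negate <- swapped | comp_swapped
  beta_y <- ifelse(negate, -beta_y, beta_y)
  eaf_y <- ifelse(negate, 1 - eaf_y, eaf_y)
  flipped <- negate
  strand <- comp_direct | comp_swapped

  ambiguous <- pal & matched &
    (is.na(eaf_x) | is.na(eaf_y) |
       abs(eaf_x - 0.5) < palindromic_eaf_window |
       abs(eaf_y - 0.5) < palindromic_eaf_window)
  # frequencies disagreeing across a resolvable palindromic pair mean the
  # outcome was reported on the other strand
  pal_flip <- pal & matched & !ambiguous & tf((eaf_x - 0.5) * (eaf_y - 0.5) < 0)
  beta_y <- ifelse(pal_flip, -beta_y, beta_y)
  eaf_y <- ifelse(pal_flip, 1 - eaf_y, eaf_y)
  strand <- strand | pal_flip
  flipped <- xor(flipped, pal_flip)

  reason <- rep(NA_character_, nrow(exposure))
  reason[!matched & !miss] <- "allele mismatch"
  reason[miss] <- "missing in outcome"
  reason[ambiguous] <- "palindromic-ambiguous"
  drop_y <- miss | (!matched & !miss)
  beta_y[drop_y] <- NA_real_; se_y[drop_y] <- NA_real_; eaf_y[drop_y] <- NA_real_
  flipped[miss | !matched] <- FALSE
  strand[miss | !matched] <- FALSE

  # orient to the exposure-increasing allele
  beta_x <- exposure$beta
  flip_x <- is.na(reason) & beta_x < 0
  out_ea <- ifelse(flip_x, oa_x, ea_x)
  out_oa <- ifelse(flip_x, ea_x, oa_x)
  beta_y <- ifelse(flip_x, -beta_y, beta_y)
  beta_x <- ifelse(flip_x, -beta_x, beta_x)
  eaf_x <- ifelse(flip_x & !is.na(eaf_x), 1 - eaf_x, eaf_x)
  eaf_y <- ifelse(flip_x & !is.na(eaf_y), 1 - eaf_y, eaf_y)

  tibble::tibble(
    snp = exposure$snp,
    effect_allele = out_ea,
    other_allele = out_oa,
    beta_x = beta_x,
    se_x = exposure$se,
    eaf_x = eaf_x,
    beta_y = beta_y,
    se_y = se_y,
    eaf_y = eaf_y,
    flipped = flipped,
    strand_complemented = strand,
    excluded_reason = reason
  )
}

#' Keep only analysable harmonised records
#'
#' @param harmonised Output of [harmonise()].
#' @return The non-excluded rows.
#' @export
harmonised_kept <- function(harmonised) {
  dplyr::filter(harmonised, is.na(.data$excluded_reason))
}

#' Summarise harmonisation inclusions and exclusions
#'
#' @param harmonised Output of [harmonise()].
#' @return A tibble of counts per disposition (`analysed` plus one row per
#'   exclusion reason); counts sum to the number of exposure SNPs.
#' @export
harmonisation_audit <- function(harmonised) {
  disposition <- ifelse(is.na(harmonised$excluded_reason), "analysed",
                        harmonised$excluded_reason)
  dplyr::count(tibble::tibble(disposition = disposition), .data$disposition,
               name = "n_snps")
}
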