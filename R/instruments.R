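#' Construct an instrument set from per-SNP associations
#'
#' An instrument set is a tibble of SNP-exposure associations (one row per
#' biallelic SNP, oriented to a named effect allele) together with metadata
#' describing the exposure: its name, the unit its betas are expressed in,
#' and the size of one exposure SD in natural units (e.g. 6.5 percentage
#' points of body fat, or 4 kg/m2 of BMI) used when rescaling results.
#'
#' Rows that violate the per-SNP invariants (alleles not a single A/C/G/T
#' base, identical alleles, non-positive SE, allele frequency outside (0,1))
#' are dropped with a row-level diagnostic; the dropped rows are attached as
#' the `"rejected"` attribute.
#'
#' @param data Data frame with columns `snp`, `effect_allele`, `other_allele`,
#'   `beta`, `se` and optionally `eaf`, `p`, `n`.
#' @param exposure_name Label for the exposure trait.
#' @param unit_label Units of `beta` (per effect allele).
#' @param sd_natural Size of 1 exposure SD in natural units (> 0).
#' @param quiet Suppress the rejection message.
#' @return A tibble of class `instrument_set`; file row order is preserved.
#' @export
instrument_set <- function(data, exposure_name = "exposure",
                           unit_label = "SD exposure per allele",
                           sd_natural = 1, quiet = FALSE) {
  data <- tibble::as_tibble(data)
  required <- c("snp", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
          class = "maternalmr_format_error")
  }
  if (!is_scalar_number(sd_natural) || sd_natural <= 0) {
    abort("sd_natural must be a positive number", class = "maternalmr_domain_error")
  }
  for (opt in c("eaf", "p", "n")) {
    if (!opt %in% names(data)) data[[opt]] <- NA_real_
  }
  data <- dplyr::mutate(
    data,
    dplyr::across(c("effect_allele", "other_allele"), ~ toupper(trimws(as.character(.x)))),
    dplyr::across(c("beta", "se", "eaf", "p", "n"), as.numeric)
  )

  reason <- rep(NA_character_, nrow(data))
  bad_allele <- !grepl("^[ACGT]$", data$effect_allele) |
    !grepl("^[ACGT]$", data$other_allele)
  reason[bad_allele] <- "invalid allele (indel or multi-allelic)"
  same <- !bad_allele & data$effect_allele == data$other_allele
  reason[same] <- "identical alleles"
  bad_se <- is.na(reason) & (!is.finite(data$se) | data$se <= 0)
  reason[bad_se] <- "nonpositive SE"
  bad_beta <- is.na(reason) & !is.finite(data$beta)
  reason[bad_beta] <- "missing beta"
  bad_eaf <- is.na(reason) & !is.na(data$eaf) & (data$eaf <= 0 | data$eaf >= 1)
  reason[bad_eaf] <- "EAF outside (0,1)"

  rejected <- dplyr::mutate(data[!is.na(reason), required[1:3]],
                            row = which(!is.na(reason)),
                            reason = reason[!is.na(reason)])
  kept <- data[is.na(reason), c(required, "eaf", "p", "n")]

  dup <- unique(kept$snp[duplicated(kept$snp)])
  if (length(dup)) {
    abort(paste0("duplicate snp id(s): ", paste(dup, collapse = ", ")),
          class = "maternalmr_duplicate_error")
  }
  if (nrow(rejected) && !quiet) {
    inform(sprintf("instrument_set: rejected %d row(s): %s", nrow(rejected),
                   paste(sprintf("row %d (%s): %s", rejected$row, rejected$snp,
                                 rejected$reason), collapse = "; ")))
  }

  attr(kept, "exposure_name") <- exposure_name
  attr(kept, "unit_label") <- unit_label
  attr(kept, "sd_natural") <- sd_natural
  attr(kept, "rejected") <- rejected
  class(kept) <- c("instrument_set", setdiff(class(kept), "instrument_set"))
  kept
}

#' Default logical-to-file column mapping for GWAS summary tables
#'
#' Maps the logical column names the package uses to the header names
#' commonly found in GWAS catalog style summary-statistic files. Override
#' individual entries to read files with other headers; there is no header
#' auto-detection.
#'
#' @param ... Named overrides, e.g. `snp = "MarkerName"`.
#' @return Named character vector mapping logical names to file columns.
#' @export
default_column_map <- function(...) {
  map <- c(snp = "snp", effect_allele = "effect_allele",
           other_allele = "other_allele", eaf = "eaf",
           beta = "beta", se = "se", p = "p", n = "n")
  overrides <- c(...)
  map[names(overrides)] <- overrides
  map
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-separated file with a header row into an
#' [instrument_set()]. The delimiter is inferred from the header line.
#' Columns are located through an explicit `column_map`; `eaf`, `p` and `n`
#' are optional and filled with `NA` when unmapped or absent.
#'
#' @param path Path to the file.
#' @param column_map Named mapping from logical names (`snp`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `eaf`, `p`, `n`) to the
#'   file's column names; see [default_column_map()].
#' @inheritParams instrument_set
#' @return An `instrument_set` tibble preserving file row order.
#' @export
read_summary_table <- function(path, column_map = default_column_map(),
                               exposure_name = "exposure",
                               unit_label = "SD exposure per allele",
                               sd_natural = 1, quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "maternalmr_io_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)

  required <- c("snp", "effect_allele", "other_allele", "beta", "se")
  missing_req <- required[!column_map[required] %in% names(raw)]
  if (length(missing_req)) {
    abort(paste0("mapped column(s) not found in file: ",
                 paste(sprintf("%s -> '%s'", missing_req, column_map[missing_req]),
                       collapse = ", ")),
          class = "maternalmr_format_error")
  }
  out <- tibble::tibble(
    snp = as.character(raw[[column_map[["snp"]]]]),
    effect_allele = raw[[column_map[["effect_allele"]]]],
    other_allele = raw[[column_map[["other_allele"]]]],
    beta = raw[[column_map[["beta"]]]],
    se = raw[[column_map[["se"]]]]
  )
  for (opt in c("eaf", "p", "n")) {
    col <- column_map[[opt]] %||% NA_character_
    out[[opt]] <- if (!is.na(col) && col %in% names(raw)) as.numeric(raw[[col]]) else NA_real_
  }
  instrument_set(out, exposure_name = exposure_name, unit_label = unit_label,
                 sd_natural = sd_natural, quiet = quiet)
}

#' Write a summary or harmonised table as TSV
#'
#' @param x Data frame (instrument set, harmonised table, results table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
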