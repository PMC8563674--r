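#' Run the full summary-level causal analysis
#'
#' Config-driven orchestration: read the exposure and outcome tables,
#' harmonise to the exposure-increasing allele, decompose maternal from
#' fetal effects when the outcome table carries own/offspring GWAS pairs,
#' run the estimator and sensitivity suite, optionally run multivariable
#' MR against secondary exposures, and rescale to natural outcome units.
#' Every stage is deterministic given the config and seed; method failures
#' are recorded in the report rather than silently dropped.
#'
#' @param config Named list (or path to a YAML file) with keys:
#'   \describe{
#'     \item{exposure}{Path or data frame of exposure associations.}
#'     \item{outcome}{Path or data frame of outcome associations: either
#'       ready maternal betas (`beta`, `se`) or own/offspring GWAS pairs
#'       (`beta_own`, `se_own`, `beta_off`, `se_off`, optional
#'       `cov_own_off`) which are WLM-decomposed first.}
#'     \item{exposure_column_map, outcome_column_map}{Optional column maps
#'       for file inputs (see [default_column_map()]).}
#'     \item{methods}{Estimators to run, default all; see [mr_all()].}
#'     \item{radial_alpha, n_boot, palindromic_eaf_window, seed}{Tuning
#'       parameters with defaults 0.05, 1000, 0.08, 1.}
#'     \item{outcome_sd_grams}{Natural units per outcome SD for rescaling,
#'       default 484 (grams per SD of birthweight).}
#'     \item{mvmr_exposures}{Optional named list of secondary exposure
#'       tables (path or data frame with `snp` and `beta`) for
#'       multivariable MR alongside the primary exposure.}
#'   }
#' @return An object of class `mr_report`: a list with `estimates` (SD
#'   units), `estimates_natural` (rescaled), `heterogeneity`,
#'   `leave_one_out`, `radial`, `mvmr` (or `NULL`), `wlm` (per-SNP
#'   decomposition when applicable), `harmonisation` (audit counts),
#'   `harmonised` (full record table), `failures`, and `provenance`
#'   (config echo, hash, seed, package version).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the yaml package",
            class = "maternalmr_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(methods = c("ivw", "ivw_mre", "egger", "weighted_median",
                               "leave_one_out", "radial"),
                   radial_alpha = 0.05, n_boot = 1000,
                   palindromic_eaf_window = 0.08, outcome_sd_grams = 484,
                   seed = 1, exposure_name = "exposure",
                   unit_label = "SD outcome per SD exposure",
                   natural_unit_label = NULL, sd_natural = 1)
  config <- utils::modifyList(defaults, config)
  if (is.null(config[["exposure"]]) || is.null(config[["outcome"]])) {
    abort("config must name an exposure and an outcome input",
          class = "maternalmr_config_error")
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "maternalmr_pipeline_error", parent = e)
    })
  }
  load_table <- function(x, column_map) {
    if (is.character(x) && length(x) == 1L) {
      read_summary_table(x, column_map = column_map %||% default_column_map(),
                         quiet = TRUE)
    } else {
      tibble::as_tibble(x)
    }
  }

  exposure <- stage("read_exposure",
                    load_table(config[["exposure"]], config[["exposure_column_map"]]))
  outcome_raw <- stage("read_outcome", {
    x <- config[["outcome"]]
    if (is.character(x) && length(x) == 1L) {
      header <- strsplit(readLines(x, n = 1L), "[\t,]")[[1]]
      if (all(c("beta_own", "beta_off") %in% header)) {
        delim <- if (grepl("\t", readLines(x, n = 1L))) "\t" else ","
        readr::read_delim(x, delim = delim, show_col_types = FALSE, progress = FALSE)
      } else {
        load_table(x, config[["outcome_column_map"]])
      }
    } else {
      tibble::as_tibble(x)
    }
  })

  wlm_table <- NULL
  if (all(c("beta_own", "beta_off") %in% names(outcome_raw))) {
    outcome <- stage("wlm", wlm_maternal_associations(outcome_raw))
    wlm_table <- outcome
  } else {
    outcome <- outcome_raw
  }

  harmonised <- stage("harmonise",
                      harmonise(exposure, outcome,
                                palindromic_eaf_window = config$palindromic_eaf_window))
  audit <- harmonisation_audit(harmonised)

  suite <- stage("estimators",
                 mr_all(harmonised, methods = config$methods,
                        n_boot = config$n_boot, seed = config$seed,
                        radial_alpha = config$radial_alpha,
                        unit_label = config$unit_label))

  mvmr_res <- NULL
  if (!is.null(config[["mvmr_exposures"]])) {
    mvmr_res <- stage("mvmr", {
      kept <- harmonised_kept(harmonised)
      joined <- tibble::tibble(snp = kept$snp, primary = kept$beta_x,
                               beta_y = kept$beta_y, se_y = kept$se_y)
      for (nm in names(config[["mvmr_exposures"]])) {
        tab <- load_table(config[["mvmr_exposures"]][[nm]], NULL)
        joined[[nm]] <- tab$beta[match(joined$snp, tab$snp)]
      }
      joined <- joined[complete.cases(joined), ]
      mvmr(joined, exposures = c("primary", names(config[["mvmr_exposures"]])),
           unit_label = config$unit_label)
    })
  }

  natural_label <- config$natural_unit_label %||%
    sprintf("%.5g natural outcome units per SD exposure", config$outcome_sd_grams)
  estimates_natural <- stage("rescale",
                             rescale_estimate(suite$estimates,
                                              config$outcome_sd_grams,
                                              unit_label = natural_label))

  provenance <- list(
    config = config[setdiff(names(config), c("exposure", "outcome", "mvmr_exposures"))],
    config_hash = rlang::hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("maternalmr"))
  )
  structure(list(
    estimates = suite$estimates,
    estimates_natural = estimates_natural,
    heterogeneity = suite$heterogeneity,
    leave_one_out = suite$leave_one_out,
    radial = suite$radial,
    mvmr = mvmr_res,
    wlm = wlm_table,
    harmonisation = audit,
    harmonised = harmonised,
    failures = suite$failures,
    provenance = provenance
  ), class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("<mr_report>\n")
  print(x$estimates_natural)
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("Heterogeneity: Q = %.2f (df = %d), I2 = %.1f%%\n",
                x$heterogeneity$Q, x$heterogeneity$df, x$heterogeneity$i2_percent))
  }
  cat("Harmonisation audit:\n")
  print(x$harmonisation)
  if (length(x$failures)) {
    cat("Recorded failures:\n")
    for (nm in names(x$failures)) cat(sprintf("  %s: %s\n", nm, x$failures[[nm]]))
  }
  invisible(x)
}

#' Glance at a pipeline report
#'
#' @param x An `mr_report`.
#' @param ... Unused.
#' @return One-row tibble: main IVW estimate in natural units, its CI,
#'   heterogeneity Q and I-squared, instrument count, radial outlier count.
#' @method glance mr_report
#' @export
glance.mr_report <- function(x, ...) {
  ivw <- dplyr::filter(x$estimates_natural, .data$method == "wald_ivw_fixed")
  tibble::tibble(
    ivw_beta_natural = if (nrow(ivw)) ivw$beta else NA_real_,
    ivw_ci_low = if (nrow(ivw)) ivw$ci_low else NA_real_,
    ivw_ci_high = if (nrow(ivw)) ivw$ci_high else NA_real_,
    Q = if (!is.null(x$heterogeneity)) x$heterogeneity$Q else NA_real_,
    i2_percent = if (!is.null(x$heterogeneity)) x$heterogeneity$i2_percent else NA_real_,
    n_snps = if (nrow(ivw)) ivw$n_snps else NA_integer_,
    n_radial_outliers = if (!is.null(x$radial)) sum(x$radial$rows$is_outlier) else NA_integer_
  )
}

#' Write a pipeline report to disk
#'
#' Emits one tidy TSV per table, a single JSON bundle holding every value
#' in the report, and a plain-text log of exclusions and provenance.
#' Column order in the TSVs is fixed by the report tables, so repeated runs
#' of the same config produce byte-identical files.
#'
#' @param report An `mr_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "json")`.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir, formats = c("tsv", "json")) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(paste0("cannot create output directory: ", dir),
          class = "maternalmr_io_error")
  }
  written <- character(0)
  emit_tsv <- function(tbl, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, path, progress = FALSE)
    written <<- c(written, path)
  }
  if ("tsv" %in% formats) {
    emit_tsv(report$estimates, "estimates_sd")
    emit_tsv(report$estimates_natural, "estimates_natural")
    if (!is.null(report$heterogeneity)) emit_tsv(report$heterogeneity, "heterogeneity")
    if (!is.null(report$leave_one_out)) emit_tsv(report$leave_one_out, "leave_one_out")
    if (!is.null(report$radial)) emit_tsv(report$radial$rows, "radial_outliers")
    if (!is.null(report$mvmr)) emit_tsv(report$mvmr, "mvmr")
    if (!is.null(report$wlm)) emit_tsv(report$wlm, "wlm_maternal")
    emit_tsv(report$harmonisation, "harmonisation_audit")
    emit_tsv(report$harmonised, "harmonised_records")
  }
  if ("json" %in% formats) {
    path <- file.path(dir, "report.json")
    bundle <- report
    class(bundle) <- "list"
    jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    written <- c(written, path)
  }
  log_path <- file.path(dir, "run.log")
  lines <- c(
    sprintf("maternalmr %s", report$provenance$package_version),
    sprintf("seed: %s", report$provenance$seed),
    sprintf("config hash: %s", report$provenance$config_hash),
    "harmonisation audit:",
    sprintf("  %s: %d", report$harmonisation$disposition, report$harmonisation$n_snps),
    if (length(report$failures)) {
      c("recorded failures:",
        sprintf("  %s: %s", names(report$failures), unlist(report$failures)))
    } else "recorded failures: none"
  )
  writeLines(lines, log_path)
  written <- c(written, log_path)
  invisible(written)
}

#' Re-read a JSON report bundle
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return The report as a list with the main tables restored to tibbles.
#' @export
read_report <- function(path) {
  bundle <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("estimates", "estimates_natural", "heterogeneity",
               "leave_one_out", "mvmr", "wlm", "harmonisation", "harmonised")) {
    if (!is.null(bundle[[nm]]) && is.data.frame(bundle[[nm]])) {
      bundle[[nm]] <- tibble::as_tibble(bundle[[nm]])
    }
  }
  if (!is.null(bundle$radial) && is.data.frame(bundle$radial$rows)) {
    bundle$radial$rows <- tibble::as_tibble(bundle$radial$rows)
  }
  bundle
}
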