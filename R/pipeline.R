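#' Crude covariate-adjusted regressions of both traits
#'
#' The conventional observational-association companion to an MR analysis:
#' a logistic regression of the binary trait on the continuous trait plus
#' covariates, and a linear regression of the continuous trait on the binary
#' trait plus the same covariates. These quantify the crude (confounded)
#' association the MR analysis then interrogates causally.
#'
#' @param pheno Phenotype tibble.
#' @param exposure Name of the continuous trait column.
#' @param outcome Name of the binary trait column.
#' @param covariates Covariate column names (all must be present).
#' @return A tibble of coefficients: `response`, `model`, `term`,
#'   `estimate`, `se`, `p`.
#' @export
crude_regressions <- function(pheno, exposure = "exposure",
                              outcome = "outcome",
                              covariates = character()) {
  pheno <- as_tibble(pheno)
  missing <- setdiff(c(exposure, outcome, covariates), names(pheno))
  if (length(missing)) {
    abort(sprintf("column(s) not found in phenotype table: %s",
                  paste(missing, collapse = ", ")))
  }
  X_log <- as.matrix(pheno[c(exposure, covariates)])
  X_lin <- as.matrix(pheno[c(outcome, covariates)])
  logit <- fit_logistic(pheno[[outcome]], X_log)
  lin <- fit_linear(pheno[[exposure]], X_lin)
  dplyr::bind_rows(
    dplyr::mutate(logit$coefficients, response = outcome, model = "logistic",
                  .before = 1),
    dplyr::mutate(lin$coefficients, response = exposure, model = "linear",
                  .before = 1))
}

#' Run one causal direction of the MR pipeline
#'
#' Exposure association scan, p-value instrument selection, F-statistic
#' screening, outcome scan over the selected SNPs, harmonization, and the
#' four MR estimators — the full one-sample design in which instruments are
#' discovered in the same cohort used for estimation. Every intermediate is
#' kept in the returned object.
#'
#' @param g Genotype table (QC already applied, or apply [qc_pipeline()]
#'   first).
#' @param pheno Phenotype tibble.
#' @param exposure,outcome Trait column names for this direction.
#' @param covariates Covariate column names adjusted for in both scans.
#' @param exposure_model,outcome_model `"linear"`/`"logistic"`; by default
#'   inferred from whether the trait is 0/1-coded.
#' @param p_threshold Instrument selection threshold (strict; default 5e-6).
#' @param f_threshold Weak-instrument screen (inclusive; default 10).
#' @param seed Seed for the median bootstrap.
#' @param methods,n_boot,ivw_model Passed to [mr_all()].
#' @return An `mr_direction` list: `exposure`, `outcome`, `exposure_stats`,
#'   `outcome_stats`, `instruments`, `harmonized`, `results`, `status`,
#'   `settings`. When no instrument survives, `status` explains why and
#'   `results` is `NULL` (the other direction of a study is unaffected).
#' @export
run_direction <- function(g, pheno, exposure, outcome,
                          covariates = character(),
                          exposure_model = NULL, outcome_model = NULL,
                          p_threshold = 5e-6, f_threshold = 10,
                          seed = 1L,
                          methods = c("ivw", "simple_median",
                                      "weighted_median", "egger"),
                          n_boot = 2000, ivw_model = "fixed") {
  settings <- list(exposure = exposure, outcome = outcome,
                   covariates = covariates, p_threshold = p_threshold,
                   f_threshold = f_threshold, seed = seed,
                   ivw_model = ivw_model, n_boot = n_boot)
  exp_stats <- gwas(g, pheno, exposure, covariates, model = exposure_model)
  candidates <- withCallingHandlers(
    select_instruments(exp_stats, p_threshold),
    warning = function(w) invokeRestart("muffleWarning"))
  fail <- function(msg) {
    structure(list(exposure = exposure, outcome = outcome,
                   exposure_stats = exp_stats, outcome_stats = NULL,
                   instruments = NULL, harmonized = NULL, results = NULL,
                   status = msg, settings = settings),
              class = "mr_direction")
  }
  if (!nrow(candidates)) {
    return(fail(sprintf("no instrument passed p < %g", p_threshold)))
  }
  instruments <- tryCatch(
    screen_instruments(candidates, g, pheno, exposure, covariates,
                       f_threshold),
    error = function(e) e)
  if (inherits(instruments, "error")) return(fail(conditionMessage(instruments)))
  exposure_used <- if (is.null(exposure_model)) {
    v <- pheno[[exposure]]
    if (all(v[!is.na(v)] %in% c(0, 1))) "logistic" else "linear"
  } else exposure_model
  # logistic exposures (reverse direction): instrument strength is screened on
  # the linear scale but the harmonized beta_exposure stays on the log-odds
  # scale of the association scan
  out_stats <- gwas(g, pheno, outcome, covariates, model = outcome_model)
  out_sub <- out_stats[out_stats$snp_id %in% instruments$snp_id, ]
  h <- harmonize(instruments, out_sub)
  results <- mr_all(h, seed = seed, methods = methods, n_boot = n_boot,
                    ivw_model = ivw_model)
  structure(list(exposure = exposure, outcome = outcome,
                 exposure_stats = exp_stats, outcome_stats = out_stats,
                 instruments = instruments, harmonized = h,
                 results = results, status = "ok",
                 settings = c(settings, exposure_model = exposure_used)),
            class = "mr_direction")
}

#' Run a bi-directional MR study
#'
#' Runs [run_direction()] with the continuous trait as exposure (forward)
#' and with the binary trait as exposure (reverse), plus the crude
#' regressions, on one cohort. A failure in one direction (no surviving
#' instruments) is recorded in that direction's status and does not abort
#' the other.
#'
#' @param g Genotype table.
#' @param pheno Phenotype tibble.
#' @param trait_continuous,trait_binary Trait column names.
#' @param covariates Covariate names used throughout.
#' @param crude Also compute [crude_regressions()] (requires both traits and
#'   all covariates; default `TRUE`).
#' @param ... Passed to both [run_direction()] calls (thresholds, seed,
#'   methods, ...).
#' @return A `study_report` list: `forward`, `reverse`, `crude`, `qc`,
#'   `provenance`.
#' @export
run_bidirectional <- function(g, pheno, trait_continuous, trait_binary,
                              covariates = character(), crude = TRUE, ...) {
  fwd <- run_direction(g, pheno, exposure = trait_continuous,
                       outcome = trait_binary, covariates = covariates, ...)
  rev <- run_direction(g, pheno, exposure = trait_binary,
                       outcome = trait_continuous, covariates = covariates, ...)
  crude_tbl <- if (crude) {
    crude_regressions(pheno, exposure = trait_continuous,
                      outcome = trait_binary, covariates = covariates)
  }
  structure(list(forward = fwd, reverse = rev, crude = crude_tbl,
                 qc = qc_report(g),
                 provenance = list(
                   package_version = as.character(utils::packageVersion("bimr")),
                   settings = fwd$settings)),
            class = "study_report")
}

#' @export
print.mr_direction <- function(x, ...) {
  cat(sprintf("MR direction: %s (exposure) -> %s (outcome)\n", x$exposure, x$outcome))
  cat(sprintf("Status: %s\n", x$status))
  if (!is.null(x$instruments)) {
    cat(sprintf("Instruments: %d (min F = %.1f)\n", nrow(x$instruments),
                min(x$instruments$f_statistic)))
  }
  if (!is.null(x$results)) print(as_tibble(x$results))
  invisible(x)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Bi-directional MR study report\n\n")
  print(x$forward)
  cat("\n")
  print(x$reverse)
  invisible(x)
}

#' Render a study report
#'
#' Serializes a [run_bidirectional()] report as JSON (lossless round-trip
#' via [study_report_from_json()]), TSV (the stacked method table), or
#' markdown mirroring the conventional bidirectional results table (one
#' block per direction, columns Method / Estimate / Standard error / 95% CI
#' / P-value).
#'
#' @param report A `study_report`.
#' @param format `"json"`, `"tsv"` or `"markdown"`.
#' @param digits Decimal places for markdown formatting (default 3).
#' @return A single character string.
#' @export
render_report <- function(report, format = c("json", "tsv", "markdown"),
                          digits = 3) {
  format <- match.arg(format)
  stopifnot(inherits(report, "study_report"))
  direction_tbl <- function(d, label) {
    if (is.null(d$results)) {
      return(tibble(direction = label, method = NA_character_,
                    estimate = NA_real_, se = NA_real_, ci_lower = NA_real_,
                    ci_upper = NA_real_, p = NA_real_,
                    n_instruments = NA_integer_, status = d$status))
    }
    dplyr::mutate(as_tibble(d$results), direction = label, .before = 1)
  }
  tbl <- dplyr::bind_rows(
    direction_tbl(report$forward,
                  sprintf("%s -> %s", report$forward$exposure, report$forward$outcome)),
    direction_tbl(report$reverse,
                  sprintf("%s -> %s", report$reverse$exposure, report$reverse$outcome)))
  if (format == "tsv") {
    return(readr::format_tsv(tbl))
  }
  if (format == "markdown") {
    fmt <- function(v) ifelse(is.na(v), "-", formatC(v, digits = digits, format = "f"))
    lines <- c("| Method | Estimate | Standard error | 95%CI | P-value |",
               "|---|---|---|---|---|")
    for (dir in unique(tbl$direction)) {
      lines <- c(lines, sprintf("| **%s** | | | | |", dir))
      sub <- tbl[tbl$direction == dir, ]
      for (i in seq_len(nrow(sub))) {
        lines <- c(lines, sprintf(
          "| %s | %s | %s | [%s-%s] | %s |",
          sub$method[i] %||% "-", fmt(sub$estimate[i]), fmt(sub$se[i]),
          fmt(sub$ci_lower[i]), fmt(sub$ci_upper[i]), fmt(sub$p[i])))
      }
    }
    return(paste(lines, collapse = "\n"))
  }
  ser <- list(
    forward = serialize_direction(report$forward),
    reverse = serialize_direction(report$reverse),
    crude = report$crude,
    qc = list(summary = report$qc$summary, steps = report$qc$steps,
              removed = report$qc$removed),
    provenance = report$provenance)
  jsonlite::toJSON(ser, digits = NA, null = "null", na = "null",
                   auto_unbox = TRUE)
}

serialize_direction <- function(d) {
  list(exposure = d$exposure, outcome = d$outcome,
       exposure_stats = d$exposure_stats, outcome_stats = d$outcome_stats,
       instruments = if (!is.null(d$instruments)) as_tibble(d$instruments),
       harmonized = if (!is.null(d$harmonized)) as_tibble(d$harmonized),
       results = if (!is.null(d$results)) as_tibble(d$results),
       status = d$status, settings = d$settings)
}

#' @rdname render_report
#' @param json A JSON string produced by `render_report(..., "json")`.
#' @export
study_report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  restore_dir <- function(d) {
    structure(list(
      exposure = d$exposure, outcome = d$outcome,
      exposure_stats = if (!is.null(d$exposure_stats)) as_tibble(d$exposure_stats),
      outcome_stats = if (!is.null(d$outcome_stats)) as_tibble(d$outcome_stats),
      instruments = if (!is.null(d$instruments)) as_tibble(d$instruments),
      harmonized = if (!is.null(d$harmonized)) as_tibble(d$harmonized),
      results = if (!is.null(d$results)) {
        structure(as_tibble(d$results), class = c("mr_result", class(tibble())))
      },
      status = d$status, settings = d$settings), class = "mr_direction")
  }
  structure(list(
    forward = restore_dir(x$forward), reverse = restore_dir(x$reverse),
    crude = if (!is.null(x$crude)) as_tibble(x$crude),
    qc = structure(list(summary = as_tibble(x$qc$summary),
                        steps = as_tibble(x$qc$steps),
                        removed = as_tibble(x$qc$removed)),
                   class = "qc_report"),
    provenance = x$provenance), class = "study_report")
}
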