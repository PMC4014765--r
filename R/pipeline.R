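#' Default end-to-end run configuration
#'
#' @param seed integer root seed (mandatory).
#' @param n_subjects cohort size.
#' @param panel `"table1"` (52-chemical analysis panel) or `"panel70"`
#'   (70-chemical measurement panel exercising the exclusion bookkeeping;
#'   its two correlation exclusions are induced by near-collinear pair
#'   overrides so the correlation rule, not fiat, removes them).
#' @param prior_range main \eqn{\tau^2} prior range (score points).
#' @param coverage normal coverage of the prior range.
#' @param r_threshold correlation-exclusion threshold.
#' @param scenarios sensitivity scenarios to run (`character(0)` for none
#'   beyond the main model).
#' @param out_dir output directory (`NULL` = no files written).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, n_subjects = 175,
                       panel = c("table1", "panel70"),
                       prior_range = 20, coverage = 0.95,
                       r_threshold = 0.95,
                       scenarios = character(0),
                       out_dir = NULL) {
  if (missing(seed)) stop_mixshrink("config", "seed is mandatory")
  panel <- match.arg(panel)
  chems <- home_chemicals(panel)
  pair <- NULL
  if (panel == "panel70") {
    pair <- data.frame(a = c("PCB-180", "MEOHP"),
                       b = c("PCB-170", "MEHHP"),
                       r = c(0.97, 0.97), stringsAsFactors = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_subjects = n_subjects, panel = panel,
    chemicals = chems, pair_correlations = pair,
    prior_range = prior_range, coverage = coverage,
    r_threshold = r_threshold, scenarios = scenarios, out_dir = out_dir
  ), class = "run_config")
}

#' Run the full pipeline
#'
#' Simulate (or accept) a cohort, preprocess the exposures, fit the
#' first-stage repeated-measures model, apply the semi-Bayesian shrinkage,
#' optionally run the sensitivity suite, and write every output as CSV
#' with a JSON manifest recording the seed, \eqn{\tau^2}, and the chemical
#' accounting at each filter step
#' (analyzed = measured - low detection - correlation-excluded).
#'
#' @param config a [run_config] (or a path to a JSON file of its fields).
#' @param cohort optional pre-built `home_cohort` (skips simulation).
#' @return list of class `run_bundle`: `cohort`, `prep`, `first_stage`,
#'   `shrinkage`, `sensitivity` (or `NULL`), `results` (per-chemical
#'   table), `manifest`.
#' @export
run_all <- function(config, cohort = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    ccfg <- cohort_config(n_subjects = config$n_subjects,
                          chemicals = config$chemicals,
                          pair_correlations = config$pair_correlations,
                          seed = config$seed)
    cohort <- simulate_cohort(ccfg)
  }
  prep <- preprocess_panel(cohort$panel, r_threshold = config$r_threshold)
  cohort$prep <- prep
  fit <- fit_repeated_model(cohort$outcomes, prep$X, cohort$covariates)
  chems <- cohort$panel$chemicals
  zspec <- build_exchangeability(
    chems[match(colnames(prep$X), chems$name), , drop = FALSE])
  t2 <- tau2_from_range(config$prior_range, config$coverage)
  sr <- shrink(fit, zspec, t2)

  sens <- NULL
  if (length(config$scenarios)) {
    sens <- run_sensitivity_suite(cohort, prior_range = config$prior_range,
                                  scenarios = config$scenarios)
  }

  coding <- prep$coding[colnames(prep$X)]
  results <- data.frame(
    chemical = fit$labels,
    chem_class = chems$chem_class[match(fit$labels, chems$name)],
    coding = unname(coding),
    beta_raw = unname(fit$beta), se_raw = unname(fit$se),
    beta_star = unname(sr$beta_star), se_star = unname(sr$se_star),
    ci_low = unname(sr$ci95[, "lower"]), ci_high = unname(sr$ci95[, "upper"]),
    stringsAsFactors = FALSE
  )

  rep <- prep$report
  n_measured <- nrow(rep)
  n_low <- sum(rep$exclusion_reason == "detection < 20%")
  n_corr <- sum(grepl("^correlation", rep$exclusion_reason))
  manifest <- list(
    seed = config$seed, panel = config$panel,
    tau2 = t2$value, prior_range = config$prior_range,
    coverage = config$coverage, r_threshold = config$r_threshold,
    n_subjects = nrow(cohort$covariates),
    n_obs = fit$n_obs, n_children = fit$n_children,
    chemicals = list(measured = n_measured, low_detection = n_low,
                     correlation_excluded = n_corr,
                     analyzed = n_measured - n_low - n_corr),
    scenarios = config$scenarios
  )
  bundle <- structure(list(cohort = cohort, prep = prep, first_stage = fit,
                           shrinkage = sr, sensitivity = sens,
                           results = results, manifest = manifest,
                           config = config),
                      class = "run_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

#' Write a run bundle to disk as CSVs plus a JSON manifest
#'
#' CSV dialect: UTF-8, header row, "." decimal, empty cell for missing.
#'
#' @param bundle a `run_bundle`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     na = "")
  }
  panel <- bundle$cohort$panel
  long <- data.frame(
    subject_id = rep(panel$subjects, times = ncol(panel$values)),
    chemical = rep(colnames(panel$values), each = nrow(panel$values)),
    value = as.vector(panel$values),
    lod = rep(unname(panel$lod), each = nrow(panel$values)),
    censored = as.vector(panel$censored),
    stringsAsFactors = FALSE
  )
  w(long, "exposures.csv")
  w(bundle$cohort$covariates, "covariates.csv")
  w(bundle$cohort$outcomes, "outcomes.csv")
  w(bundle$prep$report, "preprocess_report.csv")
  fs <- data.frame(chemical = bundle$first_stage$labels,
                   beta = unname(bundle$first_stage$beta),
                   se = unname(bundle$first_stage$se))
  w(fs, "first_stage.csv")
  Vdf <- as.data.frame(bundle$first_stage$V)
  Vdf <- cbind(chemical = rownames(bundle$first_stage$V), Vdf)
  w(Vdf, "first_stage_cov.csv")
  Z <- bundle$shrinkage
  zs <- build_exchangeability(panel$chemicals[
    match(bundle$first_stage$labels, panel$chemicals$name), , drop = FALSE])
  w(cbind(chemical = rownames(zs$Z), as.data.frame(zs$Z)),
    "exchangeability.csv")
  w(bundle$results, "results.csv")
  if (!is.null(bundle$sensitivity)) w(bundle$sensitivity$table,
                                      "sensitivity.csv")
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Summarize a results table in display order
#'
#' Orders per-chemical results by chemical class (panel order), annotates
#' dichotomous chemicals as "detected vs. nondetectable", and flags
#' chemicals whose shrunken association is at least 1.5 score points in
#' magnitude with a standard error under 2.0 — the reasonably precise,
#' non-negligible associations worth highlighting.
#'
#' @param results per-chemical data.frame from [run_all] (`$results`), or
#'   a `run_bundle`.
#' @param beta_cut,se_cut highlight thresholds.
#' @return data.frame of class `run_summary`, ordered by class.
#' @export
summarize_run <- function(results, beta_cut = 1.5, se_cut = 2.0) {
  if (inherits(results, "run_bundle")) results <- results$results
  if (nrow(results) == 0L) {
    out <- results
    out$contrast <- character(0)
    out$highlight <- logical(0)
    class(out) <- c("run_summary", "data.frame")
    return(out)
  }
  class_order <- c("phthalate", "phenol", "PCB", "OC_pesticide", "BFR",
                   "PFAS")
  ord <- order(match(results$chem_class, class_order))
  out <- results[ord, , drop = FALSE]
  out$contrast <- ifelse(out$coding == "dichotomous",
                         "detected vs. nondetectable", "per 2-SD increase")
  out$highlight <- abs(out$beta_star) >= beta_cut & out$se_star < se_cut
  rownames(out) <- NULL
  class(out) <- c("run_summary", "data.frame")
  out
}

#' @export
print.run_bundle <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<run_bundle> seed %d, panel %s: %d measured -> %d analyzed (%d low detection, %d correlation)\n",
              m$seed, m$panel, m$chemicals$measured, m$chemicals$analyzed,
              m$chemicals$low_detection, m$chemicals$correlation_excluded))
  cat(sprintf("  first stage: %d obs on %d children; tau2 = %.2f\n",
              m$n_obs, m$n_children, m$tau2))
  invisible(x)
}
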