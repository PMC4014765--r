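#' Configuration for a synthetic birth-cohort simulation
#'
#' Describes the statistical world the downstream analysis assumes:
#' lognormal biomarker concentrations with class-structured correlation and
#' detection-frequency-derived limits of detection; a confounder set
#' mirroring the published cohort table (socioeconomic, perinatal,
#' caregiving and tobacco-smoke covariates); repeated child behavior scores
#' at ages 4 and 5 with a child-level random intercept; and covariate-
#' dependent loss to follow-up.
#'
#' Defaults state the published cohort's conditions: 175 subjects, the
#' 52-chemical panel with its printed geometric means, geometric SDs and
#' detection frequencies; outcome mean 51 and SD 9 (the cohort's overall
#' behavior-score summary); intraclass correlation 0.74; completion target
#' 57%. Within-class exposure correlations default to PCB 0.6, BFR 0.5,
#' phthalate 0.5, OC pesticide 0.4, PFAS 0.4, cross-class 0.1 — stand-ins
#' that produce the qualitative collinearity of real panels (the published
#' analysis reports pairwise r of 0.89 and exclusions above 0.95) while
#' keeping the joint correlation matrix positive definite.
#'
#' @param n_subjects number of mother-child pairs.
#' @param chemicals chemical metadata table (see [home_chemicals]).
#' @param within_class_correlation named per-class correlation in \[0, 1).
#' @param cross_class_correlation correlation between chemicals of
#'   different classes, in \[0, 1).
#' @param pair_correlations optional data.frame (`a`, `b`, `r`) of
#'   chemical-pair correlation overrides (e.g. near-collinear congeners).
#' @param true_betas per-chemical outcome effects on the coded scale
#'   (score points per 2-SD increase, or per detectable-vs-not); a scalar
#'   is recycled. Named vectors are matched to chemical names.
#' @param confounder_effects named vector of outcome effects for
#'   confounder design columns (see [default_confounder_effects]).
#' @param icc_target intraclass correlation of repeated scores, in (0, 1).
#' @param outcome_mean,outcome_sd marginal mean and SD of the score.
#' @param visit_effect fixed difference of the age-5 visit vs age 4.
#' @param p_both_visits probability a child attends both visits.
#' @param n_both_visits optional exact count of two-visit children
#'   (overrides `p_both_visits`).
#' @param dropout list: `enabled`, `completion_target` (marginal completion
#'   probability), `coefficients` (named logistic coefficients on
#'   confounder design columns), `intercept` (used when no target given).
#' @param ses_rho correlation of socioeconomic covariates with the latent
#'   disadvantage factor used by the covariate generator.
#' @param exposure_ses_loading loading of log10 exposures on the latent
#'   disadvantage factor (per-chemical log10-GSD units). Default 0:
#'   exposures independent of covariates, consistent with the near-equality
#'   of biomarker concentrations between completers and non-completers the
#'   cohort reported. Set nonzero to study exposure-confounder coupling and
#'   attrition bias.
#' @param seed integer root seed (mandatory).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 175,
                          chemicals = home_chemicals("table1"),
                          within_class_correlation = c(
                            phthalate = 0.5, phenol = 0.1, PCB = 0.6,
                            OC_pesticide = 0.4, BFR = 0.5, PFAS = 0.4),
                          cross_class_correlation = 0.1,
                          pair_correlations = NULL,
                          true_betas = 0,
                          confounder_effects = default_confounder_effects(),
                          icc_target = 0.74,
                          outcome_mean = 51,
                          outcome_sd = 9,
                          visit_effect = 0,
                          p_both_visits = 135 / 175,
                          n_both_visits = NULL,
                          dropout = list(enabled = FALSE),
                          ses_rho = 0.5,
                          exposure_ses_loading = 0,
                          seed) {
  if (missing(seed)) stop_mixshrink("config", "seed is mandatory")
  validate_chemicals(chemicals)
  if (icc_target <= 0 || icc_target >= 1) {
    stop_mixshrink("config", "icc_target must be in (0, 1)")
  }
  if (any(within_class_correlation < 0 | within_class_correlation >= 1) ||
      cross_class_correlation < 0 || cross_class_correlation >= 1) {
    stop_mixshrink("config", "correlations must be in [0, 1)")
  }
  if (length(true_betas) == 1L && is.null(names(true_betas))) {
    true_betas <- stats::setNames(rep(true_betas, nrow(chemicals)),
                                  chemicals$name)
  } else {
    tb <- stats::setNames(rep(0, nrow(chemicals)), chemicals$name)
    tb[names(true_betas)] <- true_betas
    true_betas <- tb
  }
  structure(list(
    n_subjects = as.integer(n_subjects), chemicals = chemicals,
    within_class_correlation = within_class_correlation,
    cross_class_correlation = cross_class_correlation,
    pair_correlations = pair_correlations,
    true_betas = true_betas, confounder_effects = confounder_effects,
    icc_target = icc_target, outcome_mean = outcome_mean,
    outcome_sd = outcome_sd, visit_effect = visit_effect,
    p_both_visits = p_both_visits, n_both_visits = n_both_visits,
    dropout = dropout, ses_rho = ses_rho,
    exposure_ses_loading = exposure_ses_loading, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Build the block exposure correlation matrix implied by a config
#'
#' @param config a [cohort_config].
#' @return p x p correlation matrix (log10 scale).
#' @keywords internal
exposure_correlation <- function(config) {
  chems <- config$chemicals
  p <- nrow(chems)
  R <- matrix(config$cross_class_correlation, p, p,
              dimnames = list(chems$name, chems$name))
  for (cl in unique(chems$chem_class)) {
    idx <- which(chems$chem_class == cl)
    r <- config$within_class_correlation[[cl]] %||%
      config$cross_class_correlation
    R[idx, idx] <- r
  }
  diag(R) <- 1
  pc <- config$pair_correlations
  if (!is.null(pc)) {
    for (k in seq_len(nrow(pc))) {
      i <- match(pc$a[k], chems$name); j <- match(pc$b[k], chems$name)
      if (is.na(i) || is.na(j)) {
        stop_mixshrink("synthetic", "pair correlation names unknown: ",
                       pc$a[k], " / ", pc$b[k])
      }
      R[i, j] <- R[j, i] <- pc$r[k]
    }
  }
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    classes <- paste(sort(unique(chems$chem_class)), collapse = ", ")
    stop_mixshrink("synthetic",
      sprintf("exposure correlation matrix is not positive definite (min eigenvalue %.2e); check within-class blocks [%s] and pair overrides",
              ev, classes))
  }
  R
}

#' Generate a synthetic exposure panel
#'
#' Log10 concentrations are drawn from a multivariate normal with mean
#' log10(GM), SD log10(GSD) and the block correlation structure implied by
#' the config. Each chemical's LOD is placed at the
#' (1 - detection_target) quantile of its marginal lognormal, so the
#' realized detection frequency matches the target in expectation; draws
#' below the LOD are flagged censored with the LOD retained
#' (detection target 1 gives LOD 0 and no censoring).
#'
#' @param config a [cohort_config].
#' @param ses optional latent disadvantage factor (length n); used with a
#'   nonzero `exposure_ses_loading` to couple exposures to the covariates.
#' @return an [exposure_panel]. Censored cells retain the latent draw;
#'   [preprocess_panel] performs the LOD/\eqn{\sqrt2} substitution.
#' @export
generate_exposures <- function(config, ses = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  chems <- config$chemicals
  n <- config$n_subjects
  p <- nrow(chems)
  R <- exposure_correlation(config)
  U <- chol(R)
  Zn <- matrix(stats::rnorm(n * p), n, p) %*% U
  lam <- config$exposure_ses_loading %||% 0
  if (lam != 0 && !is.null(ses)) {
    # shared disadvantage component; renormalize so marginal GSD is kept
    Zn <- (Zn + lam * ses) / sqrt(1 + lam^2)
  }
  mu <- log10(chems$gm)
  sdev <- log10(chems$gsd)
  logv <- sweep(sweep(Zn, 2, sdev, `*`), 2, mu, `+`)
  d <- chems$pct_detect / 100
  log_lod <- stats::qnorm(1 - d, mean = mu, sd = sdev)  # -Inf when d = 1
  lod <- 10^log_lod
  censored <- sweep(logv, 2, log_lod, `<`)
  censored[, d >= 1] <- FALSE
  values <- 10^logv
  subjects <- sprintf("S%04d", seq_len(n))
  exposure_panel(values, censored, lod, chems, subjects = subjects)
}

#' Default confounder outcome effects (score points)
#'
#' Effects on reference-coded confounder design columns, chosen to mimic
#' the published covariate-score gradients (socioeconomic disadvantage,
#' tobacco-smoke exposure and depressive symptoms raise scores; maternal
#' IQ and a stimulating caregiving environment lower them). Continuous
#' effects are per unit: depressive-symptom score points, IQ points,
#' caregiving-score points, log10 cotinine.
#'
#' @return named numeric vector over confounder design columns.
#' @export
default_confounder_effects <- function() {
  c(race_black = 6, race_other = -2,
    age_lt25 = 3, age_ge35 = -1,
    edu_somecollege = 2, edu_highschool = 3, edu_lt_highschool = 4,
    marital_cohab = 2, marital_alone = 3,
    income_40to80 = 0.5, income_20to40 = 2, income_lt20 = 4,
    parity_1to2 = 0.5, parity_3plus = 3,
    insurance_public = 2, employ_none = 2,
    vitamin_weekly = 1, vitamin_rare = 2,
    depress = 0.25, maternal_iq = -0.15, home_score = -0.3,
    log10_cotinine = 1.5, sex_boy = -2)
}

draw_categorical <- function(u, probs, labels) {
  labels[findInterval(u, cumsum(probs / sum(probs)), left.open = TRUE) + 1L]
}

#' Generate baseline covariates for a synthetic cohort
#'
#' Draws the confounder set of the published cohort table: maternal race,
#' age category, education, marital status, household income, parity,
#' insurance, employment, prenatal vitamin use (category probabilities
#' matched to the printed table), plus continuous depressive symptoms,
#' maternal IQ, caregiving (HOME) score and log10 serum cotinine, and child
#' sex. Socioeconomic covariates share a latent disadvantage factor
#' (Gaussian copula, loading `ses_rho`) so that confounding and
#' covariate-dependent dropout have the correlated structure real cohorts
#' show.
#'
#' @param n number of subjects.
#' @param ses_rho loading of SES-linked covariates on the latent factor.
#' @return data.frame with one row per subject, including the latent
#'   `ses` factor (kept for dropout-model testing).
#' @export
generate_covariates <- function(n, ses_rho = 0.5) {
  ses <- stats::rnorm(n)  # higher = more disadvantaged
  mix <- function(rho) stats::pnorm(rho * ses +
                                    sqrt(1 - rho^2) * stats::rnorm(n))
  r <- ses_rho
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    race = draw_categorical(mix(r), c(117, 50, 8) / 175,
                            c("white", "black", "other")),
    age_cat = draw_categorical(mix(r / 2), c(36, 115, 24) / 175,
                               c("lt25", "25to35", "ge35")),
    education = draw_categorical(mix(r), c(92, 48, 21, 14) / 175,
                                 c("graduate", "somecollege", "highschool",
                                   "lt_highschool")),
    marital = draw_categorical(mix(r), c(122, 15, 38) / 175,
                               c("married", "cohab", "alone")),
    income = draw_categorical(mix(r), c(46, 66, 26, 37) / 175,
                              c("ge80", "40to80", "20to40", "lt20")),
    parity = draw_categorical(mix(r / 3), c(80, 83, 12) / 175,
                              c("nulliparous", "1to2", "3plus")),
    insurance = draw_categorical(mix(r), c(129, 46) / 175,
                                 c("private", "public")),
    employment = draw_categorical(mix(r / 2), c(145, 30) / 175,
                                  c("any", "none")),
    vitamins = draw_categorical(mix(r / 2), c(132, 17, 26) / 175,
                                c("daily", "weekly", "rare")),
    depress = exp(stats::rnorm(n, log(6), 0.8) + 0.2 * ses),
    maternal_iq = 107 + 13 * (-r * ses + sqrt(1 - r^2) * stats::rnorm(n)),
    home_score = 40 + 6 * (-r * ses + sqrt(1 - r^2) * stats::rnorm(n)),
    log10_cotinine = -1.2 + 0.8 * ses + 0.6 * stats::rnorm(n),
    child_sex = ifelse(stats::runif(n) < 95 / 175, "girl", "boy"),
    ses = ses,
    stringsAsFactors = FALSE
  )
}

#' Reference-coded confounder design matrix
#'
#' Expands the covariate table into the numeric design used by both the
#' outcome generator and the first-stage model: reference-coded indicators
#' for the categorical covariates (reference = most common level) and the
#' four continuous covariates as-is.
#'
#' @param covariates data.frame from [generate_covariates] (or real data
#'   with the same columns).
#' @return numeric matrix, rownames = subject ids.
#' @export
confounder_design <- function(covariates) {
  cv <- covariates
  X <- cbind(
    race_black = as.numeric(cv$race == "black"),
    race_other = as.numeric(cv$race == "other"),
    age_lt25 = as.numeric(cv$age_cat == "lt25"),
    age_ge35 = as.numeric(cv$age_cat == "ge35"),
    edu_somecollege = as.numeric(cv$education == "somecollege"),
    edu_highschool = as.numeric(cv$education == "highschool"),
    edu_lt_highschool = as.numeric(cv$education == "lt_highschool"),
    marital_cohab = as.numeric(cv$marital == "cohab"),
    marital_alone = as.numeric(cv$marital == "alone"),
    income_40to80 = as.numeric(cv$income == "40to80"),
    income_20to40 = as.numeric(cv$income == "20to40"),
    income_lt20 = as.numeric(cv$income == "lt20"),
    parity_1to2 = as.numeric(cv$parity == "1to2"),
    parity_3plus = as.numeric(cv$parity == "3plus"),
    insurance_public = as.numeric(cv$insurance == "public"),
    employ_none = as.numeric(cv$employment == "none"),
    vitamin_weekly = as.numeric(cv$vitamins == "weekly"),
    vitamin_rare = as.numeric(cv$vitamins == "rare"),
    depress = cv$depress,
    maternal_iq = cv$maternal_iq,
    home_score = cv$home_score,
    log10_cotinine = cv$log10_cotinine,
    sex_boy = as.numeric(cv$child_sex == "boy")
  )
  rownames(X) <- cv$subject_id
  X
}

#' Generate repeated outcome scores
#'
#' Each child contributes up to two score records (ages 4 and 5):
#' \deqn{y_{ij} = \mu + x_i^\top\beta + c_i^\top\gamma + \delta\,
#'   \mathrm{age5}_{ij} + b_i + e_{ij}}
#' with child random intercept \eqn{b_i \sim N(0,\,\rho\sigma^2)} and
#' residual \eqn{e_{ij} \sim N(0,\,(1-\rho)\sigma^2)}, so the
#' random-intercept share of the noise variance equals the target
#' intraclass correlation \eqn{\rho} and its total equals
#' `outcome_sd`\eqn{^2}. Exposure and confounder design columns are
#' centered before effects are applied so the marginal score mean stays at
#' `outcome_mean`.
#'
#' @param X coded exposure matrix (subjects x chemicals), e.g.
#'   `preprocess_panel(...)$X`.
#' @param covariates covariate table for the same subjects.
#' @param config a [cohort_config].
#' @return data.frame (`subject_id`, `age`, `score`), 1-2 rows per child.
#' @export
generate_outcomes <- function(X, covariates, config) {
  stopifnot(inherits(config, "cohort_config"))
  rho <- config$icc_target
  if (rho <= 0 || rho >= 1) {
    stop_mixshrink("synthetic", "icc_target must be in (0, 1)")
  }
  n <- nrow(X)
  s2 <- config$outcome_sd^2
  beta <- config$true_betas[colnames(X)]
  beta[is.na(beta)] <- 0
  Xc <- sweep(X, 2, colMeans(X))
  C <- confounder_design(covariates)
  gamma <- stats::setNames(rep(0, ncol(C)), colnames(C))
  ce <- config$confounder_effects
  gamma[names(ce)[names(ce) %in% colnames(C)]] <-
    ce[names(ce) %in% colnames(C)]
  Cc <- sweep(C, 2, colMeans(C))
  lin <- config$outcome_mean + drop(Xc %*% beta) + drop(Cc %*% gamma)

  b <- stats::rnorm(n, 0, sqrt(rho * s2))

  # visit attendance: two visits for most children, one for the rest
  if (!is.null(config$n_both_visits)) {
    both <- rep(FALSE, n)
    both[sample.int(n, min(config$n_both_visits, n))] <- TRUE
  } else {
    both <- stats::runif(n) < config$p_both_visits
  }
  single_age <- ifelse(stats::runif(n) < 0.5, 4L, 5L)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    ages <- if (both[i]) c(4L, 5L) else single_age[i]
    data.frame(subject_id = rownames(X)[i], age = ages,
               stringsAsFactors = FALSE)
  }))
  i <- match(rows$subject_id, rownames(X))
  e <- stats::rnorm(nrow(rows), 0, sqrt((1 - rho) * s2))
  rows$score <- lin[i] + b[i] + config$visit_effect * (rows$age == 5L) + e
  rows
}

#' Default dropout (loss to follow-up) model
#'
#' Completion of at least one follow-up visit is a logistic function of
#' baseline covariates. By default completion is less likely for
#' socioeconomically disadvantaged families (low income, low education,
#' public insurance), with the intercept calibrated so the marginal
#' completion fraction matches the published 57%.
#'
#' @return list understood by [apply_dropout].
#' @export
default_dropout_model <- function() {
  list(enabled = TRUE, completion_target = 222 / 389,
       coefficients = c(income_lt20 = -0.8, edu_lt_highschool = -0.6,
                        race_black = -0.4, insurance_public = -0.3))
}

#' Apply covariate-dependent loss to follow-up
#'
#' Draws a completion indicator from a logistic model on the (centered)
#' confounder design and removes outcome rows for non-completers. Baseline
#' covariates are retained for all subjects so inverse-probability weights
#' can be estimated downstream. When `completion_target` is supplied the
#' intercept is solved so the average completion probability equals it;
#' otherwise the configured `intercept` is used directly (coefficients all
#' zero and intercept `qlogis(p)` give marginal completion `p`).
#'
#' @param cohort list with at least `outcomes` and `covariates`.
#' @param config a [cohort_config] whose `dropout` entry is used.
#' @return the cohort with `completed` flags, filtered `outcomes`, and the
#'   pre-dropout table kept as `outcomes_full`.
#' @export
apply_dropout <- function(cohort, config) {
  dm <- config$dropout
  n <- nrow(cohort$covariates)
  C <- confounder_design(cohort$covariates)
  coefs <- stats::setNames(rep(0, ncol(C)), colnames(C))
  if (!is.null(dm$coefficients)) {
    ok <- names(dm$coefficients) %in% colnames(C)
    coefs[names(dm$coefficients)[ok]] <- dm$coefficients[ok]
  }
  lp <- drop(sweep(C, 2, colMeans(C)) %*% coefs)
  if (!is.null(dm$completion_target)) {
    a <- stats::uniroot(
      function(a) mean(stats::plogis(a + lp)) - dm$completion_target,
      interval = c(-30, 30))$root
  } else {
    a <- dm$intercept %||% stats::qlogis(0.57)
  }
  pr <- stats::plogis(a + lp)
  completed <- stats::runif(n) < pr
  cohort$completion_prob <- stats::setNames(pr, cohort$covariates$subject_id)
  cohort$completed <- stats::setNames(completed,
                                      cohort$covariates$subject_id)
  cohort$outcomes_full <- cohort$outcomes
  keep <- cohort$outcomes$subject_id %in%
    cohort$covariates$subject_id[completed]
  cohort$outcomes <- cohort$outcomes[keep, , drop = FALSE]
  cohort
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates exposure generation, covariate generation, exposure
#' preprocessing (to obtain the coded matrix the outcome model acts on),
#' outcome generation and optional dropout, all from named seed streams
#' derived from the config's root seed (same seed, same cohort,
#' bit for bit).
#'
#' @param config a [cohort_config].
#' @return object of class `home_cohort`: `panel` (raw exposures), `prep`
#'   (preprocessed panel with coded matrix), `covariates`, `outcomes`,
#'   `completed` (if dropout enabled), and `truth` (generating parameters
#'   for recovery tests).
#' @examples
#' cfg <- cohort_config(n_subjects = 60, seed = 7)
#' coh <- simulate_cohort(cfg)
#' nrow(coh$outcomes)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(config$seed,
                        c("exposures", "covariates", "outcomes", "dropout"))
  set.seed(seeds[["covariates"]])
  covariates <- generate_covariates(config$n_subjects, config$ses_rho)
  set.seed(seeds[["exposures"]])
  panel <- generate_exposures(config, ses = covariates$ses)
  prep <- preprocess_panel(panel)
  set.seed(seeds[["outcomes"]])
  outcomes <- generate_outcomes(prep$X, covariates, config)
  cohort <- structure(
    list(panel = panel, prep = prep, covariates = covariates,
         outcomes = outcomes,
         truth = list(true_betas = config$true_betas[colnames(prep$X)],
                      confounder_effects = config$confounder_effects,
                      icc_target = config$icc_target,
                      outcome_mean = config$outcome_mean,
                      outcome_sd = config$outcome_sd),
         config = config),
    class = "home_cohort")
  if (isTRUE(config$dropout$enabled)) {
    set.seed(seeds[["dropout"]])
    cohort <- apply_dropout(cohort, config)
  }
  cohort
}

#' Follow-up bookkeeping
#'
#' @param n_completed number of pairs completing at least one follow-up.
#' @param n_total number of pairs at baseline.
#' @return list: `fraction`, and `percent` rounded to the nearest integer
#'   (222 of 389 gives 57).
#' @export
completion_summary <- function(n_completed, n_total) {
  if (n_total <= 0 || n_completed < 0 || n_completed > n_total) {
    stop_mixshrink("bookkeeping", "invalid completion counts")
  }
  frac <- n_completed / n_total
  list(n_completed = n_completed, n_total = n_total,
       fraction = frac, percent = round(100 * frac))
}

#' @export
print.home_cohort <- function(x, ...) {
  cat(sprintf("<home_cohort> %d subjects, %d outcome records, %d chemicals (%d analyzed)\n",
              nrow(x$covariates), nrow(x$outcomes),
              nrow(x$panel$chemicals), ncol(x$prep$X)))
  invisible(x)
}
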