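#' Fit the first-stage repeated-measures linear model
#'
#' Regresses the repeated child scores on every coded exposure plus the
#' confounder design in a single linear mixed model with a child-level
#' random intercept (with at most two records per child this is the only
#' identifiable classical repeated-measures covariance; it is equivalent to
#' compound symmetry). Estimation is by REML; the exposure coefficient
#' subvector and its joint covariance block are returned for the
#' second-stage shrinkage.
#'
#' @param outcomes data.frame (`subject_id`, `age`, `score`), 1-2 rows per
#'   child.
#' @param exposures coded exposure matrix, rownames = subject ids (e.g.
#'   `preprocess_panel(...)$X`).
#' @param covariates covariate table (see [generate_covariates]) or `NULL`
#'   to fit an exposure-only model.
#' @param weights optional named per-subject weights (e.g. stabilized
#'   inverse-probability-of-completion weights); each child's rows share
#'   the weight. All-ones weights reproduce the unweighted fit exactly.
#' @param include_age include the age-5 visit indicator (default `TRUE`;
#'   pooling two ages without an age term would confound visit age with
#'   exposure under differential follow-up).
#' @return object of class `first_stage_fit`: `beta` (exposure
#'   coefficients), `V` (their covariance), `se`, `labels`,
#'   `confounder_estimates`, `n_obs`, `n_children`, `sigma2`, `tau2_child`
#'   (random-intercept variance).
#' @export
fit_repeated_model <- function(outcomes, exposures, covariates = NULL,
                               weights = NULL, include_age = TRUE) {
  if (!all(outcomes$subject_id %in% rownames(exposures))) {
    stop_mixshrink("first_stage", "outcome subjects missing from exposure matrix")
  }
  labels <- colnames(exposures)
  p <- ncol(exposures)
  i <- match(outcomes$subject_id, rownames(exposures))
  Xe <- exposures[i, , drop = FALSE]
  colnames(Xe) <- sprintf("expo_%03d", seq_len(p))

  parts <- list(Xe)
  conf_labels <- character(0)
  if (!is.null(covariates)) {
    C <- confounder_design(covariates)
    ic <- match(outcomes$subject_id, rownames(C))
    if (anyNA(ic)) {
      stop_mixshrink("first_stage", "outcome subjects missing from covariates")
    }
    Cc <- C[ic, , drop = FALSE]
    conf_labels <- colnames(Cc)
    colnames(Cc) <- sprintf("conf_%03d", seq_along(conf_labels))
    parts <- c(parts, list(Cc))
  }
  if (include_age) {
    parts <- c(parts, list(age5 = matrix(as.numeric(outcomes$age == 5L),
                                         ncol = 1,
                                         dimnames = list(NULL, "age5"))))
  }
  Xfix <- do.call(cbind, parts)

  # per-chemical missingness masks are supported only per-fit: complete cases
  cc <- stats::complete.cases(Xfix) & is.finite(outcomes$score)
  Xfix <- Xfix[cc, , drop = FALSE]
  dat <- data.frame(score = outcomes$score[cc],
                    subject_id = outcomes$subject_id[cc],
                    Xfix, check.names = FALSE,
                    stringsAsFactors = FALSE)
  n_obs <- nrow(dat)
  if (ncol(Xfix) + 1L >= n_obs) {
    stop_mixshrink("first_stage",
                   sprintf("design too large: %d fixed effects for %d observations",
                           ncol(Xfix) + 1L, n_obs))
  }
  M <- cbind("(icpt)" = 1, Xfix)
  qrX <- qr(M)
  if (qrX$rank < ncol(M)) {
    dropped <- colnames(M)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(M))]]
    all_labels <- stats::setNames(c("(icpt)", labels, conf_labels, "age5"),
                                  c("(icpt)", colnames(Xe),
                                    sprintf("conf_%03d",
                                            seq_along(conf_labels)), "age5"))
    stop_mixshrink("first_stage", "singular fixed-effect design; collinear columns: ",
                   paste(all_labels[dropped], collapse = ", "))
  }

  if (!is.null(weights)) {
    w <- weights[dat$subject_id]
    if (anyNA(w)) stop_mixshrink("first_stage", "weights missing for some subjects")
    dat$.w <- as.numeric(w)
  }
  fml <- stats::as.formula(paste(
    "score ~", paste(colnames(Xfix), collapse = " + "), "+ (1 | subject_id)"))
  # singleton children (one record) are legal; suppress the nlev==nobs guard
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            check.nobs.vs.rankZ = "ignore")
  fit <- if (is.null(weights)) {
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = dat, REML = TRUE, control = ctrl)))
  } else {
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = dat, REML = TRUE, weights = .w,
                 control = ctrl)))
  }
  fe <- lme4::fixef(fit)
  Vfull <- as.matrix(stats::vcov(fit))
  expo_idx <- match(colnames(Xe), names(fe))
  beta <- stats::setNames(fe[expo_idx], labels)
  V <- Vfull[expo_idx, expo_idx, drop = FALSE]
  dimnames(V) <- list(labels, labels)
  if (min(eigen((V + t(V)) / 2, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8 * max(diag(V))) {
    stop_mixshrink("first_stage", "fitted coefficient covariance is not PSD")
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  conf_est <- NULL
  if (length(conf_labels)) {
    ci <- match(sprintf("conf_%03d", seq_along(conf_labels)), names(fe))
    conf_est <- stats::setNames(fe[ci], conf_labels)
  }
  structure(list(
    beta = beta, V = (V + t(V)) / 2, se = sqrt(pmax(diag(V), 0)),
    labels = labels, confounder_estimates = conf_est,
    intercept = fe[["(Intercept)"]],
    age_effect = if (include_age) fe[["age5"]] else NA_real_,
    n_obs = n_obs, n_children = length(unique(dat$subject_id)),
    tau2_child = vc$vcov[vc$grp == "subject_id"],
    sigma2 = vc$vcov[vc$grp == "Residual"]
  ), class = "first_stage_fit")
}

#' @export
print.first_stage_fit <- function(x, ...) {
  cat(sprintf("<first_stage_fit> %d exposures, %d observations on %d children\n",
              length(x$beta), x$n_obs, x$n_children))
  cat(sprintf("  child-level variance %.2f, residual %.2f (ICC %.2f)\n",
              x$tau2_child, x$sigma2,
              x$tau2_child / (x$tau2_child + x$sigma2)))
  invisible(x)
}

#' Intraclass correlation of repeated scores
#'
#' Share of score variance attributable to the child level, from a
#' variance-components (random-intercept, intercept-only) REML fit.
#'
#' @param outcomes data.frame (`subject_id`, `age`, `score`).
#' @return the ICC, a fraction in \[0, 1\].
#' @export
icc <- function(outcomes) {
  reps <- table(outcomes$subject_id)
  if (sum(reps >= 2L) < 2L) {
    stop_mixshrink("first_stage", "ICC needs at least two children with repeats")
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(score ~ 1 + (1 | subject_id), data = outcomes, REML = TRUE,
               control = ctrl)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- vc$vcov[vc$grp == "subject_id"]
  ve <- vc$vcov[vc$grp == "Residual"]
  vb / (vb + ve)
}
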