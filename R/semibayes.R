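#' Prior variance from an assumed coefficient range
#'
#' The second-stage residual variance \eqn{\tau^2} is set from a
#' prespecified range believed to contain the coefficients with a given
#' normal coverage: a 95% interval of total width \eqn{r} has SD
#' \eqn{r / (2 z_{0.975})}, so
#' \deqn{\tau^2 = \left(\frac{r}{2\,z_{(1+c)/2}}\right)^2.}
#' A 20-point range (effects between -10 and +10 score points, one
#' normative SD) gives \eqn{\tau^2 = 26.03}; a 10-point range gives 6.51.
#'
#' @param prior_range width of the assumed coefficient interval
#'   (score points).
#' @param coverage normal coverage of the interval (default 0.95).
#' @return object of class `tau2_spec` with fields `prior_range`,
#'   `coverage`, `value`.
#' @examples
#' tau2_from_range(20)$value   # 26.03
#' @export
tau2_from_range <- function(prior_range, coverage = 0.95) {
  if (prior_range <= 0) stop_mixshrink("semibayes", "prior_range must be > 0")
  if (coverage <= 0 || coverage >= 1) {
    stop_mixshrink("semibayes", "coverage must be in (0, 1)")
  }
  z <- stats::qnorm((1 + coverage) / 2)
  structure(list(prior_range = prior_range, coverage = coverage,
                 value = (prior_range / (2 * z))^2),
            class = "tau2_spec")
}

as_tau2 <- function(tau2) {
  if (inherits(tau2, "tau2_spec")) tau2$value else as.numeric(tau2)
}

#' Build the exchangeability (second-stage design) matrix
#'
#' Coefficients of structurally similar chemicals are assumed exchangeable:
#' the second-stage design holds an intercept plus 0/1 indicators for DBP
#' metabolites, DEHP metabolites, BFRs, PFASs, PCBs, OC pesticides, and
#' persistence (persistent chemicals are the serum-measured ones).
#' Phthalate metabolites outside the DBP/DEHP groups and the phenol load
#' only on the intercept.
#'
#' @param chemicals chemical metadata (rows define the coefficient order).
#' @return object of class `exchangeability_spec`: `Z` (p x q 0/1 matrix
#'   with intercept), `column_labels`, `chemicals` (names).
#' @export
build_exchangeability <- function(chemicals) {
  validate_chemicals(chemicals)
  cols <- c("intercept", "DBP_metabolites", "DEHP_metabolites", "BFR",
            "PFAS", "PCB", "OC_pesticide", "persistent")
  Z <- cbind(
    intercept = rep(1, nrow(chemicals)),
    DBP_metabolites = as.numeric(chemicals$metabolite_group == "DBP"),
    DEHP_metabolites = as.numeric(chemicals$metabolite_group == "DEHP"),
    BFR = as.numeric(chemicals$chem_class == "BFR"),
    PFAS = as.numeric(chemicals$chem_class == "PFAS"),
    PCB = as.numeric(chemicals$chem_class == "PCB"),
    OC_pesticide = as.numeric(chemicals$chem_class == "OC_pesticide"),
    persistent = as.numeric(chemicals$matrix == "serum")
  )
  rownames(Z) <- chemicals$name
  # on reduced panels some indicators are empty or duplicate the intercept
  # (e.g. all-serum toys); drop them so Z keeps full column rank
  keep <- c(TRUE, colSums(Z[, -1, drop = FALSE]) > 0)
  Z <- Z[, keep, drop = FALSE]
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    Z <- Z[, qz$pivot[seq_len(qz$rank)], drop = FALSE]
    Z <- Z[, order(match(colnames(Z), cols)), drop = FALSE]
  }
  structure(list(Z = Z, column_labels = colnames(Z),
                 chemicals = chemicals$name),
            class = "exchangeability_spec")
}

as_Z <- function(Z) {
  if (inherits(Z, "exchangeability_spec")) Z$Z else as.matrix(Z)
}

#' Second-stage generalized least squares
#'
#' Regresses the first-stage coefficients on the exchangeability matrix
#' under working covariance \eqn{V + \tau^2 I}: with
#' \eqn{W = (V + \tau^2 I)^{-1}},
#' \deqn{\hat\pi = (Z^\top W Z)^{-1} Z^\top W \beta, \qquad
#'       \mathrm{cov}(\hat\pi) = (Z^\top W Z)^{-1}.}
#'
#' @param beta p-vector of first-stage coefficients.
#' @param V their p x p covariance.
#' @param Z exchangeability matrix (p x q) or an `exchangeability_spec`.
#' @param tau2 prior variance (number or `tau2_spec`).
#' @return list: `pi_hat` (q-vector), `cov_pi` (q x q), `W`.
#' @export
second_stage_gls <- function(beta, V, Z, tau2) {
  Z <- as_Z(Z)
  tau2 <- as_tau2(tau2)
  p <- length(beta)
  stopifnot(nrow(Z) == p, all(dim(V) == p))
  S <- V + diag(tau2, p)
  W <- tryCatch(chol2inv(chol(S)), error = function(e)
    stop_mixshrink("semibayes", "V + tau2*I is not invertible: ",
                   conditionMessage(e)))
  A <- crossprod(Z, W %*% Z)
  qa <- qr(A)
  if (qa$rank < ncol(Z)) {
    bad <- colnames(Z)[qa$pivot[seq.int(qa$rank + 1L, ncol(Z))]]
    stop_mixshrink("semibayes", "collinear exchangeability columns: ",
                   paste(bad, collapse = ", "))
  }
  cov_pi <- chol2inv(chol((A + t(A)) / 2))
  pi_hat <- drop(cov_pi %*% crossprod(Z, W %*% beta))
  names(pi_hat) <- colnames(Z)
  dimnames(cov_pi) <- list(colnames(Z), colnames(Z))
  list(pi_hat = pi_hat, cov_pi = cov_pi, W = W)
}

#' Semi-Bayesian shrinkage of first-stage coefficients
#'
#' The two-stage (hierarchical linear) estimator: each coefficient is
#' pulled toward its fitted exchangeability-group mean by an amount
#' governed by its first-stage precision and the prior variance
#' \eqn{\tau^2}. With \eqn{W = (V + \tau^2 I)^{-1}} and \eqn{\hat\pi} from
#' [second_stage_gls],
#' \deqn{\beta^* = \beta - V W (\beta - Z\hat\pi),}
#' \deqn{\mathrm{cov}(\beta^*) = V - V W V +
#'   V W Z (Z^\top W Z)^{-1} Z^\top W V.}
#' Imprecise coefficients (large first-stage variance) are shrunk hardest;
#' \eqn{\tau^2 \to \infty} returns the first-stage estimates, and an exact
#' first stage (V = 0) is left untouched.
#'
#' @param fit a `first_stage_fit`, or any list with `beta` and `V`.
#' @param Z exchangeability matrix or `exchangeability_spec`.
#' @param tau2 prior variance (number or [tau2_from_range] spec).
#' @return object of class `shrinkage_result`: `beta_star`, `se_star`,
#'   `ci95` (p x 2), `pi_hat`, `cov_pi`, `tau2_used`, plus the first-stage
#'   `beta` and `se` for reference.
#' @export
shrink <- function(fit, Z, tau2) {
  beta <- fit$beta
  V <- fit$V
  Z <- as_Z(Z)
  tau2 <- as_tau2(tau2)
  p <- length(beta)
  g <- second_stage_gls(beta, V, Z, tau2)
  W <- g$W
  VW <- V %*% W
  beta_star <- drop(beta - VW %*% (beta - Z %*% g$pi_hat))
  WZ <- W %*% Z
  cov_star <- V - VW %*% V + VW %*% Z %*% g$cov_pi %*% t(WZ) %*% V
  cov_star <- (cov_star + t(cov_star)) / 2
  se_star <- sqrt(pmax(diag(cov_star), 0))
  zq <- stats::qnorm(0.975)
  ci95 <- cbind(lower = beta_star - zq * se_star,
                upper = beta_star + zq * se_star)
  names(beta_star) <- names(se_star) <- rownames(ci95) <- names(beta)
  structure(list(beta_star = beta_star, se_star = se_star, ci95 = ci95,
                 cov_star = cov_star, pi_hat = g$pi_hat, cov_pi = g$cov_pi,
                 tau2_used = tau2, beta = beta,
                 se = sqrt(pmax(diag(V), 0))),
            class = "shrinkage_result")
}

#' @export
print.shrinkage_result <- function(x, ...) {
  cat(sprintf("<shrinkage_result> %d coefficients, tau2 = %.4g\n",
              length(x$beta_star), x$tau2_used))
  cat("  group means (pi_hat):\n")
  print(round(x$pi_hat, 3))
  invisible(x)
}

#' Empirical-Bayes estimation of the second-stage variance
#'
#' Instead of fixing \eqn{\tau^2} a priori, estimate it from the observed
#' coefficients by maximizing the marginal likelihood of
#' \eqn{\beta \sim N(Z\pi,\; V + \tau^2 I)}, profiling \eqn{\pi} out via
#' GLS at each \eqn{\tau^2}. The optimum is constrained to
#' \eqn{\tau^2 \ge 0}; 0 is returned when the boundary maximizes the
#' likelihood (coefficients no more dispersed than their sampling error).
#'
#' @param beta p-vector of first-stage coefficients.
#' @param V their covariance.
#' @param Z exchangeability matrix or spec.
#' @param upper upper bound of the search interval (default
#'   `100 * var(beta)` plus the largest first-stage variance).
#' @return estimated \eqn{\hat\tau^2} (a number, >= 0).
#' @export
empirical_bayes_tau2 <- function(beta, V, Z, upper = NULL) {
  Z <- as_Z(Z)
  p <- length(beta)
  if (p <= ncol(Z)) {
    stop_mixshrink("semibayes", "empirical Bayes needs p > q coefficients")
  }
  if (is.null(upper)) upper <- 100 * stats::var(beta) + max(diag(V)) + 1
  profile_nll <- function(tau2) {
    S <- V + diag(tau2, p)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    W <- chol2inv(ch)
    A <- crossprod(Z, W %*% Z)
    pi_hat <- solve(A, crossprod(Z, W %*% beta))
    r <- beta - drop(Z %*% pi_hat)
    sum(log(diag(ch))) + 0.5 * drop(crossprod(r, W %*% r))
  }
  opt <- stats::optimize(profile_nll, interval = c(0, upper))
  if (!is.finite(opt$objective)) {
    stop_mixshrink("semibayes", "empirical-Bayes optimization failed to evaluate")
  }
  if (profile_nll(0) <= opt$objective + 1e-10) return(0)
  # guard against an optimum pinned at the search boundary
  if (opt$minimum > 0.99 * upper) {
    opt <- stats::optimize(profile_nll, interval = c(0, 100 * upper))
  }
  max(0, opt$minimum)
}
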