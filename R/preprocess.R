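#' Substitute censored concentrations by LOD/sqrt(2)
#'
#' Concentrations below the limit of detection are replaced by
#' \eqn{\mathrm{LOD}/\sqrt{2}}, the standard single-value substitution for
#' lognormal biomarker data; detected values pass through unchanged.
#'
#' @param value numeric concentration(s).
#' @param lod numeric limit(s) of detection, recycled against `value`.
#' @param censored logical flag(s): `TRUE` where the value is below the LOD.
#' @return numeric vector with censored entries replaced by `lod / sqrt(2)`.
#' @examples
#' substitute_below_lod(c(5.6, NA), lod = c(1, 1), censored = c(FALSE, TRUE))
#' @export
substitute_below_lod <- function(value, lod, censored) {
  censored <- as.logical(censored)
  n <- max(length(value), length(lod), length(censored))
  value <- rep_len(value, n)
  lod <- rep_len(lod, n)
  censored <- rep_len(censored, n)
  if (any(censored & (is.na(lod) | lod <= 0))) {
    stop_mixshrink("preprocess", "censored value with missing or nonpositive LOD")
  }
  ifelse(censored, lod / sqrt(2), value)
}

#' Classify a chemical by its detection frequency
#'
#' Chemicals detected in at least 80% of samples are analyzed as continuous
#' (log10, 2-SD rescaled); those detected in at least 20% but under 80% as
#' dichotomous (detectable vs. nondetectable); those under 20% are excluded.
#'
#' @param freq detection frequency (fraction in \[0, 1\]), vectorized.
#' @return character vector: `"continuous"`, `"dichotomous"` or `"excluded"`.
#' @examples
#' classify_by_detection(c(0.82, 0.49, 0.19))
#' @export
classify_by_detection <- function(freq) {
  if (any(freq < 0 | freq > 1, na.rm = TRUE)) {
    stop_mixshrink("preprocess", "detection frequency must be in [0, 1]")
  }
  out <- ifelse(freq >= 0.80, "continuous",
                ifelse(freq >= 0.20, "dichotomous", "excluded"))
  as.character(out)
}

#' Normalize a concentration by creatinine or serum lipid
#'
#' Urinary analytes (\eqn{\mu}g/L) are divided by urinary creatinine (g/L)
#' to give \eqn{\mu}g/g creatinine; serum analytes (ng/mL) are divided by
#' total serum lipid (g/L) and multiplied by 1000 (mL/L) to give ng/g lipid.
#' `basis = "none"` is the identity (PFAS are reported per liter of serum).
#'
#' @param value concentration: \eqn{\mu}g/L urine for creatinine, ng/mL
#'   serum for lipid.
#' @param basis_value creatinine (g/L) or total lipid (g/L); ignored for
#'   `basis = "none"`.
#' @param basis one of `"creatinine"`, `"lipid"`, `"none"`.
#' @return normalized concentration in the panel's reporting units.
#' @examples
#' normalize_concentration(2, 1, "creatinine")   # 2 ug/g creatinine
#' normalize_concentration(10, 5, "lipid")       # 2000 ng/g lipid
#' @export
normalize_concentration <- function(value, basis_value = NULL,
                                    basis = c("creatinine", "lipid", "none")) {
  basis <- match.arg(basis)
  if (basis == "none") return(value)
  if (is.null(basis_value) || any(!is.finite(basis_value)) ||
      any(basis_value <= 0)) {
    stop_mixshrink("preprocess", "normalization basis must be positive")
  }
  switch(basis,
    creatinine = value / basis_value,          # ug/L over g/L -> ug/g
    lipid = value * 1000 / basis_value         # ng/mL * mL/L over g/L -> ng/g
  )
}

#' Average repeated samples on the log10 scale
#'
#' When a subject provides more than one sample, concentrations are
#' log10-transformed and then averaged, so the summary respects the
#' multiplicative scale of biomarker data.
#'
#' @param samples positive concentrations from one subject.
#' @return mean of `log10(samples)` (a log10-scale value).
#' @examples
#' average_repeats(c(10, 1000))  # 2
#' @export
average_repeats <- function(samples) {
  if (length(samples) == 0L) {
    stop_mixshrink("preprocess", "no samples to average")
  }
  if (any(!is.finite(samples) | samples <= 0)) {
    stop_mixshrink("preprocess", "samples must be positive")
  }
  mean(log10(samples))
}

#' Rescale a continuous exposure by twice its standard deviation
#'
#' Dividing a continuous predictor by 2 SD gives it SD 0.5, the SD of a
#' balanced binary predictor, so its regression coefficient (per 2-SD
#' increase) is directly comparable to a detected-vs-nondetected contrast.
#' Uses the sample SD (n - 1 denominator).
#'
#' @param values numeric vector with positive SD.
#' @return `values / (2 * sd(values))`.
#' @export
rescale_2sd <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s <= 0) {
    stop_mixshrink("preprocess", "cannot 2-SD rescale a constant vector")
  }
  values / (2 * s)
}

#' Code a chemical as detected vs. nondetectable
#'
#' @param values concentrations (unused except for length; kept for a
#'   uniform coding interface).
#' @param censored logical censoring flags.
#' @return integer 0/1 vector: 1 = detected, 0 = below the LOD.
#' @export
dichotomize <- function(values, censored) {
  as.integer(!as.logical(rep_len(censored, length(values))))
}

#' Mark one of each highly correlated chemical pair as excluded
#'
#' Pearson correlations are computed between log10 concentrations, among
#' subjects where both chemicals are detected. For each pair exceeding
#' `r_threshold`, the chemical with the lower median concentration is
#' excluded. Pairs are processed in deterministic order: descending |r|,
#' ties broken by chemical name; a pair is skipped if one member was
#' already excluded by an earlier, stronger pair.
#'
#' @param panel an [exposure_panel].
#' @param r_threshold exclusion threshold on Pearson r, in (0, 1).
#' @param min_pairs minimum number of jointly detected subjects required to
#'   evaluate a pair (pairs with fewer are left alone).
#' @return the panel with `coding` set to `"excluded"` for dropped
#'   chemicals and an `exclusion_reason` entry recording the partner.
#' @export
drop_correlated <- function(panel, r_threshold = 0.95, min_pairs = 10L) {
  stopifnot(inherits(panel, "exposure_panel"))
  if (r_threshold <= 0 || r_threshold >= 1) {
    stop_mixshrink("preprocess", "r_threshold must be in (0, 1)")
  }
  active <- which(panel$coding != "excluded")
  if (length(active) < 2L) return(panel)

  logv <- log10(panel$values[, active, drop = FALSE])
  det <- !panel$censored[, active, drop = FALSE]
  p <- length(active)
  pairs <- NULL
  for (i in seq_len(p - 1L)) {
    for (j in seq(i + 1L, p)) {
      both <- det[, i] & det[, j]
      if (sum(both) < min_pairs) next
      r <- suppressWarnings(stats::cor(logv[both, i], logv[both, j]))
      if (is.finite(r) && abs(r) > r_threshold) {
        pairs <- rbind(pairs, data.frame(i = active[i], j = active[j], r = r))
      }
    }
  }
  if (is.null(pairs)) return(panel)

  nm <- panel$chemicals$name
  ord <- order(-abs(pairs$r), pmin(nm[pairs$i], nm[pairs$j]),
               pmax(nm[pairs$i], nm[pairs$j]))
  pairs <- pairs[ord, , drop = FALSE]

  med <- apply(panel$values, 2, stats::median)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (panel$coding[i] == "excluded" || panel$coding[j] == "excluded") next
    drop <- if (med[i] >= med[j]) j else i
    keep <- if (drop == j) i else j
    panel$coding[drop] <- "excluded"
    panel$exclusion_reason[drop] <-
      sprintf("correlation r=%.3f with %s", pairs$r[k], nm[keep])
  }
  panel
}

#' Preprocess an exposure panel into analysis coding
#'
#' Runs the full exposure-side pipeline: LOD/\eqn{\sqrt 2} substitution,
#' detection-frequency classification (>= 80% continuous, \[20%, 80%)
#' dichotomous, < 20% excluded), correlation-based exclusion (r >
#' `r_threshold`, keep the higher median), and construction of the coded
#' analysis matrix: continuous chemicals log10-transformed and divided by
#' twice their SD; dichotomous chemicals coded detected (1) vs.
#' nondetectable (0).
#'
#' @param panel an [exposure_panel].
#' @param r_threshold Pearson-r exclusion threshold (default 0.95).
#' @param substitute logical; apply LOD substitution (disable when the
#'   values were already substituted upstream).
#' @return a list of class `preprocessed_panel`:
#'   \item{panel}{the input panel with `coding` and substituted values,}
#'   \item{X}{n x p_analyzed coded matrix (columns named by chemical),}
#'   \item{coding}{named coding vector over all chemicals,}
#'   \item{report}{per-chemical data.frame: detection %, coding,
#'     exclusion reason.}
#' @export
preprocess_panel <- function(panel, r_threshold = 0.95, substitute = TRUE) {
  stopifnot(inherits(panel, "exposure_panel"))
  if (substitute) {
    for (j in seq_along(panel$lod)) {
      panel$values[, j] <- substitute_below_lod(
        panel$values[, j], panel$lod[j], panel$censored[, j])
    }
  }
  freq <- colMeans(!panel$censored)
  panel$coding <- classify_by_detection(freq)
  panel$exclusion_reason <- ifelse(panel$coding == "excluded",
                                   "detection < 20%", "")
  panel <- drop_correlated(panel, r_threshold = r_threshold)

  keep <- which(panel$coding != "excluded")
  X <- matrix(NA_real_, nrow = length(panel$subjects), ncol = length(keep),
              dimnames = list(panel$subjects, panel$chemicals$name[keep]))
  for (k in seq_along(keep)) {
    j <- keep[k]
    X[, k] <- if (panel$coding[j] == "continuous") {
      rescale_2sd(log10(panel$values[, j]))
    } else {
      dichotomize(panel$values[, j], panel$censored[, j])
    }
  }
  coding <- stats::setNames(panel$coding, panel$chemicals$name)
  report <- data.frame(
    name = panel$chemicals$name,
    chem_class = panel$chemicals$chem_class,
    pct_detect = 100 * freq,
    coding = panel$coding,
    exclusion_reason = panel$exclusion_reason,
    stringsAsFactors = FALSE
  )
  structure(list(panel = panel, X = X, coding = coding, report = report),
            class = "preprocessed_panel")
}
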