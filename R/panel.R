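#' Construct an exposure panel
#'
#' The central exposure container: a subjects x chemicals concentration
#' matrix together with censoring flags, per-chemical limits of detection,
#' chemical metadata and (after preprocessing) the analysis coding.
#'
#' @param values numeric n x p matrix of concentrations (reporting units of
#'   each chemical). Censored cells may hold the raw draw or the
#'   substituted value; the `censored` flags are authoritative.
#' @param censored logical n x p matrix, `TRUE` below the LOD.
#' @param lod numeric length-p vector of limits of detection.
#' @param chemicals chemical metadata data.frame (see [validate_chemicals]).
#' @param subjects character subject identifiers (rownames of `values`).
#' @param coding optional per-chemical coding
#'   (`"continuous"`/`"dichotomous"`/`"excluded"`).
#' @return an object of class `exposure_panel`.
#' @export
exposure_panel <- function(values, censored, lod, chemicals,
                           subjects = rownames(values), coding = NULL) {
  validate_chemicals(chemicals)
  p <- nrow(chemicals)
  if (!is.matrix(values) || ncol(values) != p) {
    stop_mixshrink("panel", "values must be an n x p matrix matching chemicals")
  }
  if (!identical(dim(values), dim(censored))) {
    stop_mixshrink("panel", "values and censored must have identical shape")
  }
  if (length(lod) != p) {
    stop_mixshrink("panel", "lod must have one entry per chemical")
  }
  if (is.null(subjects)) subjects <- sprintf("S%04d", seq_len(nrow(values)))
  colnames(values) <- colnames(censored) <- chemicals$name
  rownames(values) <- rownames(censored) <- subjects
  if (is.null(coding)) coding <- rep(NA_character_, p)
  structure(
    list(values = values, censored = matrix(as.logical(censored),
                                            nrow = nrow(values),
                                            dimnames = dimnames(values)),
         lod = stats::setNames(as.numeric(lod), chemicals$name),
         chemicals = chemicals, subjects = subjects, coding = coding,
         exclusion_reason = rep("", p)),
    class = "exposure_panel"
  )
}

#' @export
print.exposure_panel <- function(x, ...) {
  cat(sprintf("<exposure_panel> %d subjects x %d chemicals\n",
              length(x$subjects), nrow(x$chemicals)))
  cat(sprintf("  detection: %.0f%%-%.0f%% (median %.0f%%)\n",
              100 * min(colMeans(!x$censored)),
              100 * max(colMeans(!x$censored)),
              100 * stats::median(colMeans(!x$censored))))
  if (!all(is.na(x$coding))) {
    cat("  coding:", paste(names(table(x$coding)), table(x$coding),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
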