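#' Biomarker panel metadata
#'
#' A chemical table records, for each biomarker, its chemical class, the
#' biological matrix it is measured in, the unit and dilution-normalization
#' basis, whether the compound is persistent (long biological half-life,
#' measured in serum) or nonpersistent (measured in urine), and marginal
#' summaries used by the synthetic cohort generator: geometric mean (GM),
#' geometric standard deviation (GSD), and the percent of samples above the
#' limit of detection.
#'
#' Two panels ship with the package as plain-text fixtures:
#' \describe{
#'   \item{`"table1"`}{the 52-chemical analysis panel with published
#'     univariate statistics (GM, GSD, percent detected, percentiles and a
#'     national-survey reference median).}
#'   \item{`"panel70"`}{a 70-chemical measurement panel used to exercise the
#'     exclusion bookkeeping (16 infrequently detected chemicals plus two
#'     chemicals excluded by the correlation rule). The 18 non-analyzed rows
#'     carry synthetic GM/GSD/detection values because no published
#'     univariate statistics exist for them; the file is marked synthetic.}
#' }
#'
#' @param panel `"table1"` or `"panel70"`.
#' @return a `data.frame` with one row per chemical and columns
#'   `name`, `chem_class`, `metabolite_group`, `matrix`, `unit`,
#'   `normalization`, `persistent`, `pct_detect`, `gm`, `gsd` (plus
#'   percentile columns for the table1 panel).
#' @examples
#' chems <- home_chemicals()
#' table(chems$chem_class)
#' @export
home_chemicals <- function(panel = c("table1", "panel70")) {
  panel <- match.arg(panel)
  file <- switch(panel,
    table1 = "table1_chemicals.csv",
    panel70 = "panel70_synthetic.csv"
  )
  path <- system.file("extdata", file, package = "mixshrink", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_chemicals(df)
  df
}

CHEM_CLASSES <- c("phthalate", "phenol", "PCB", "OC_pesticide", "BFR", "PFAS")

#' Validate a chemical metadata table
#'
#' Checks the structural invariants every panel must satisfy: known chemical
#' classes, urine \eqn{\Leftrightarrow} nonpersistent, positive GM, GSD > 1,
#' detection percentage in \[0, 100\], and the matrix-specific normalization
#' convention (urine chemicals creatinine-normalized; serum PCBs, OC
#' pesticides and BFRs lipid-normalized; PFAS reported unnormalized in
#' \eqn{\mu}g/L).
#'
#' @param chems data.frame of chemical metadata.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_chemicals <- function(chems) {
  need <- c("name", "chem_class", "metabolite_group", "matrix", "unit",
            "normalization", "persistent", "pct_detect", "gm", "gsd")
  missing_cols <- setdiff(need, names(chems))
  if (length(missing_cols)) {
    stop_mixshrink("chemicals", "missing columns: ",
                   paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(chems$name)) {
    stop_mixshrink("chemicals", "duplicate chemical names")
  }
  bad_class <- setdiff(unique(chems$chem_class), CHEM_CLASSES)
  if (length(bad_class)) {
    stop_mixshrink("chemicals", "unknown chemical class: ",
                   paste(bad_class, collapse = ", "))
  }
  if (!all(chems$matrix %in% c("urine", "serum"))) {
    stop_mixshrink("chemicals", "matrix must be 'urine' or 'serum'")
  }
  # persistent chemicals are measured in serum, nonpersistent in urine
  if (!all((chems$matrix == "serum") == chems$persistent)) {
    stop_mixshrink("chemicals",
                   "persistent flag must equal (matrix == 'serum')")
  }
  if (!all(chems$gm > 0)) stop_mixshrink("chemicals", "gm must be > 0")
  if (!all(chems$gsd > 1)) stop_mixshrink("chemicals", "gsd must be > 1")
  if (!all(chems$pct_detect >= 0 & chems$pct_detect <= 100)) {
    stop_mixshrink("chemicals", "pct_detect must be in [0, 100]")
  }
  urine_ok <- chems$normalization[chems$matrix == "urine"] == "creatinine"
  if (!all(urine_ok)) {
    stop_mixshrink("chemicals", "urine chemicals must be creatinine-normalized")
  }
  serum <- chems[chems$matrix == "serum", ]
  lipid_classes <- c("PCB", "OC_pesticide", "BFR")
  if (!all(serum$normalization[serum$chem_class %in% lipid_classes] == "lipid")) {
    stop_mixshrink("chemicals", "serum PCBs/OC pesticides/BFRs must be lipid-normalized")
  }
  if (!all(serum$normalization[serum$chem_class == "PFAS"] == "none")) {
    stop_mixshrink("chemicals", "PFAS are reported unnormalized (ug/L)")
  }
  invisible(chems)
}
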