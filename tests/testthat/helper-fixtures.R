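# Small panels and builders shared across the suite. Everything is built
# in code; no binary fixtures.

# a compact cross-class panel: one DBP and one DEHP metabolite, the phenol,
# two PCBs (one dichotomous), an OC pesticide, a BFR and a PFAS
small_panel <- function() {
  chems <- home_chemicals("table1")
  keep <- c("MBP", "MEHP", "BPA", "PCB-153", "PCB-178", "trans-Nonachlor",
            "PBDE-47", "PFOA")
  chems[match(keep, chems$name), , drop = FALSE]
}

small_config <- function(seed, n_subjects = 175, ...) {
  cohort_config(n_subjects = n_subjects, chemicals = small_panel(),
                seed = seed, ...)
}

# minimal valid serum-PCB metadata for toy panels
toy_chemicals <- function(names, gm = rep(1, length(names))) {
  data.frame(name = names, chem_class = "PCB", metabolite_group = "none",
             matrix = "serum", unit = "ng/g lipid", normalization = "lipid",
             persistent = TRUE, pct_detect = 100, gm = gm,
             gsd = rep(2, length(names)), stringsAsFactors = FALSE)
}

# panel whose chemicals are exact positive multiples of one lognormal draw
# (pairwise r = 1 on the log scale), with chosen medians
toy_correlated_panel <- function(medians, n = 60, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  values <- vapply(medians, function(m) m * 10^(0.3 * z), numeric(n))
  chems <- toy_chemicals(sprintf("CH%d", seq_along(medians)), gm = medians)
  exposure_panel(values, matrix(FALSE, n, length(medians)),
                 lod = rep(0.001, length(medians)), chemicals = chems)
}

expect_equal_num <- function(x, y, tol) {
  expect_true(max(abs(x - y)) < tol,
              label = sprintf("max|diff| = %.3g < %.3g", max(abs(x - y)), tol))
}
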