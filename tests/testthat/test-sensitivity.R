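test_that("IPW weights are 1 when completion is unrelated to covariates or complete", {
  coh <- simulate_cohort(small_config(seed = 31, n_subjects = 2000))
  # all complete -> exactly 1
  all_done <- rep(TRUE, 2000)
  expect_equal(unname(ipw_weights(coh$covariates, all_done)),
               rep(1, 2000))
  # completion independent of covariates -> weights near 1, mean 1
  set.seed(3)
  done <- stats::runif(2000) < 0.6
  w <- ipw_weights(coh$covariates, done)
  expect_equal(mean(w[done]), 1, tolerance = 0.02)
  expect_true(all(abs(w[done] - 1) < 0.6))
})

test_that("IPW restores the baseline covariate distribution under informative dropout", {
  cfg <- small_config(seed = 32, n_subjects = 4000,
                      dropout = list(enabled = TRUE, completion_target = 0.57,
                                     coefficients = c(home_score = 0.15)))
  coh <- simulate_cohort(cfg)
  w <- ipw_weights(coh$covariates, coh$completed)
  hs <- coh$covariates$home_score
  done <- coh$completed
  full_mean <- mean(hs)
  naive <- mean(hs[done])
  weighted <- stats::weighted.mean(hs[done], w[done])
  expect_gt(abs(naive - full_mean), 0.5)       # dropout really biased it
  expect_lt(abs(weighted - full_mean), 0.25)   # reweighting undoes it
})

test_that("sensitivity suite: IPW equals main without dropout; smaller tau2 shrinks harder", {
  coh <- simulate_cohort(small_config(seed = 33, n_subjects = 175))
  rep <- run_sensitivity_suite(coh)
  tab <- rep$table
  expect_setequal(unique(tab$scenario),
                  c("main", "tau2_small", "empirical_bayes", "ipw",
                    "single_pollutant"))
  # identical chemical list in every scenario
  bychem <- split(tab$chemical, tab$scenario)
  for (s in names(bychem)) expect_setequal(bychem[[s]], colnames(coh$prep$X))

  main <- tab[tab$scenario == "main", ]
  ipw <- tab[tab$scenario == "ipw", ]
  expect_equal(main$beta, ipw$beta[match(main$chemical, ipw$chemical)],
               tolerance = 1e-8)

  # mean distance to the fitted group means under tau2(10) vs tau2(20)
  fit <- rep$first_stage
  zs <- rep$exchangeability
  d <- sapply(c(20, 10), function(rg) {
    sr <- shrink(fit, zs, tau2_from_range(rg))
    mean(abs(sr$beta_star - drop(zs$Z %*% sr$pi_hat)))
  })
  expect_lte(d[2], d[1])
  # and the suite's own tables agree with direct shrink calls
  sr20 <- shrink(fit, zs, tau2_from_range(20))
  expect_equal(main$beta, unname(sr20$beta_star[main$chemical]))
})

test_that("single-pollutant and mixture fits agree when exposures are independent", {
  chems <- small_panel()
  cfg <- cohort_config(n_subjects = 3000, chemicals = chems,
                       within_class_correlation = c(phthalate = 0, phenol = 0,
                                                    PCB = 0, OC_pesticide = 0,
                                                    BFR = 0, PFAS = 0),
                       cross_class_correlation = 0,
                       true_betas = c("PCB-153" = 3), seed = 34)
  coh <- simulate_cohort(cfg)
  full <- fit_repeated_model(coh$outcomes, coh$prep$X, coh$covariates)
  single <- single_pollutant_fit(coh, "PCB-153")
  expect_equal(unname(full$beta["PCB-153"]), unname(single$beta),
               tolerance = 3 * single$se)
  expect_equal(unname(single$beta), 3, tolerance = 3 * single$se)

  # under strong within-class correlation the two disagree (co-pollutant
  # confounding): the single-pollutant fit absorbs the correlated partner
  cfg2 <- cohort_config(n_subjects = 3000, chemicals = chems,
                        within_class_correlation = c(phthalate = 0.5,
                                                     phenol = 0.1, PCB = 0.9,
                                                     OC_pesticide = 0.4,
                                                     BFR = 0.5, PFAS = 0.4),
                        true_betas = c("PCB-153" = 3, "PCB-178" = 3),
                        seed = 35)
  coh2 <- simulate_cohort(cfg2)
  single2 <- single_pollutant_fit(coh2, "PCB-153")
  # the marginal slope picks up the partner's effect
  expect_gt(unname(single2$beta), 3 + 3 * single2$se)
})

test_that("sex-interaction model recovers sex-specific effects and swaps under relabeling", {
  # girls' effect 5.6, boys' 0.3 (the exploratory analysis's headline pair)
  cfg <- small_config(seed = 36, n_subjects = 3000, true_betas = 0,
                      confounder_effects = c())
  coh <- simulate_cohort(cfg)
  girl <- coh$covariates$child_sex == "girl"
  expo <- coh$prep$X[, "trans-Nonachlor"]
  extra <- ifelse(girl, 5.6, 0.3) * expo
  bump <- extra[match(coh$outcomes$subject_id, coh$covariates$subject_id)]
  coh$outcomes$score <- coh$outcomes$score + bump

  res <- sex_interaction(coh, "trans-Nonachlor")
  expect_equal(res$beta_girls, 5.6, tolerance = 3 * 0.35)
  expect_equal(res$beta_boys, 0.3, tolerance = 3 * 0.35)
  expect_lt(res$interaction_p, 0.01)
  expect_true(res$display)

  # relabeling symmetry
  coh2 <- coh
  coh2$covariates$child_sex <- ifelse(girl, "boy", "girl")
  res2 <- sex_interaction(coh2, "trans-Nonachlor")
  expect_equal(res2$beta_girls, res$beta_boys, tolerance = 1e-6)
  expect_equal(res2$beta_boys, res$beta_girls, tolerance = 1e-6)
  expect_equal(res2$interaction_p, res$interaction_p, tolerance = 1e-6)

  coh3 <- coh
  coh3$covariates$child_sex <- "girl"
  expect_error(sex_interaction(coh3, "trans-Nonachlor"), "both sexes")
})

test_that("null interaction p-values reject at about the display rate", {
  reps <- 100
  pv <- numeric(reps)
  for (r in seq_len(reps)) {
    coh <- simulate_cohort(small_config(seed = 7000 + r, n_subjects = 150,
                                        true_betas = 0))
    pv[r] <- sex_interaction(coh, "PFOA")$interaction_p
  }
  rate <- mean(pv < 0.10)
  expect_lt(abs(rate - 0.10), 3 * sqrt(0.1 * 0.9 / reps) + 0.02)
})

test_that("IPW reduces attrition bias when dropout depends on an outcome-associated confounder", {
  # exposures load on the latent disadvantage factor, dropout selects on a
  # disadvantage-linked covariate, and the unadjusted exposure slope is the
  # estimand: attrition bias is the gap between the completer estimate and
  # the full-cohort estimate, which IPW is designed to close. Scaled to 60
  # replicates on the 8-chemical panel.
  reps <- 60
  err_u <- err_w <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- small_config(seed = 8000 + r, n_subjects = 500,
                        true_betas = c("PFOA" = 3),
                        exposure_ses_loading = 0.8,
                        dropout = list(enabled = TRUE,
                                       completion_target = 0.5,
                                       coefficients = c(home_score = 0.15,
                                                        depress = -0.04)))
    coh <- simulate_cohort(cfg)
    w <- ipw_weights(coh$covariates, coh$completed)
    X1 <- coh$prep$X[, "PFOA", drop = FALSE]
    f_full <- fit_repeated_model(coh$outcomes_full, X1, covariates = NULL)
    f_u <- fit_repeated_model(coh$outcomes, X1, covariates = NULL)
    f_w <- fit_repeated_model(coh$outcomes, X1, covariates = NULL,
                              weights = w)
    err_u[r] <- f_u$beta[[1]] - f_full$beta[[1]]
    err_w[r] <- f_w$beta[[1]] - f_full$beta[[1]]
  }
  expect_lt(abs(mean(err_w)), abs(mean(err_u)))
  expect_lt(sd(err_w) / sqrt(reps), 0.15)  # MC error small enough to mean much
})
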