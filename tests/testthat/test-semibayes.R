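test_that("prior variance derives from the assumed coefficient range", {
  expect_equal(round(tau2_from_range(20, 0.95)$value, 2), 26.03)
  expect_equal(round(tau2_from_range(10, 0.95)$value, 3), 6.508)
  # halving the range quarters the variance
  expect_equal(tau2_from_range(10)$value, tau2_from_range(20)$value / 4)
  # monotone decreasing in coverage (z grows without bound)
  vals <- vapply(c(0.5, 0.8, 0.95, 0.999, 1 - 1e-12),
                 function(cv) tau2_from_range(20, cv)$value, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 2)
  expect_error(tau2_from_range(-1), "prior_range")
  expect_error(tau2_from_range(20, 1), "coverage")
})

test_that("exchangeability matrix encodes the published grouping rules", {
  chems <- home_chemicals("table1")
  zs <- build_exchangeability(chems)
  # the persistent indicator equals the sum of the four serum-class
  # indicators in this chemical universe (serum <=> one of PCB/OC/BFR/PFAS),
  # so it is dropped as linearly dependent: same column space, rank 7
  expect_equal(zs$column_labels,
               c("intercept", "DBP_metabolites", "DEHP_metabolites", "BFR",
                 "PFAS", "PCB", "OC_pesticide"))
  expect_equal(dim(zs$Z), c(52L, 7L))
  expect_true(all(zs$Z %in% c(0, 1)))
  expect_true(all(zs$Z[, "intercept"] == 1))
  expect_equal(qr(zs$Z)$rank, 7L)
  persistent <- as.numeric(chems$matrix == "serum")
  expect_equal(unname(rowSums(zs$Z[, c("BFR", "PFAS", "PCB",
                                       "OC_pesticide")])), persistent)
  expect_equal(qr(cbind(zs$Z, persistent))$rank, 7L)  # adds nothing
  # MEP is a DEP metabolite: no listed metabolite group, urine
  expect_equal(unname(zs$Z["MEP", ]), c(1, 0, 0, 0, 0, 0, 0))
  # PCB-153: serum PCB (persistent via its class column)
  expect_equal(unname(zs$Z["PCB-153", ]), c(1, 0, 0, 0, 0, 1, 0))
  # MEHP: DEHP metabolite, urine (nonpersistent)
  expect_equal(unname(zs$Z["MEHP", ]), c(1, 0, 1, 0, 0, 0, 0))
  # MBP/MiBP are the DBP metabolites
  expect_equal(rownames(zs$Z)[zs$Z[, "DBP_metabolites"] == 1],
               c("MBP", "MiBP"))
  bad <- chems
  bad$chem_class[1] <- "mystery"
  expect_error(build_exchangeability(bad), "unknown chemical class")
})

test_that("second-stage GLS reduces to known closed forms", {
  # intercept only, V = vI: equal weights -> arithmetic mean
  beta <- c(1, 4, 7)
  g <- second_stage_gls(beta, diag(2, 3), matrix(1, 3, 1), tau2 = 3)
  expect_equal(unname(g$pi_hat), mean(beta))
  # saturated second stage (square invertible Z): Z pi = beta exactly
  Zsq <- rbind(c(1, 0), c(1, 1))
  g2 <- second_stage_gls(c(2, 5), diag(1, 2), Zsq, tau2 = 2)
  expect_equal(drop(Zsq %*% g2$pi_hat), c(2, 5))
  # hand-worked GLS: beta=(1,3), V=I, tau2=1 -> W = I/2, pi = 2, cov = 1
  g3 <- second_stage_gls(c(1, 3), diag(1, 2), matrix(1, 2, 1), tau2 = 1)
  expect_equal(unname(g3$pi_hat), 2)
  expect_equal(unname(g3$cov_pi[1, 1]), 1)
  # collinear second-stage columns are named
  Zbad <- cbind(intercept = c(1, 1, 1), dup = c(1, 1, 1))
  expect_error(second_stage_gls(beta, diag(1, 3), Zbad, 1),
               "collinear.*dup")
})

test_that("shrinkage limits behave: tau2 -> Inf, V -> 0, and the scalar case", {
  fit <- list(beta = c(a = 1, b = 3), V = diag(1, 2))
  Z <- matrix(1, 2, 1, dimnames = list(c("a", "b"), "intercept"))
  # conjugate-normal scalar oracle: shrink factor 1/2 toward mean 2
  sr <- shrink(fit, Z, tau2 = 1)
  expect_equal(unname(sr$beta_star), c(1.5, 2.5))
  # tau2 huge: no shrinkage
  sr_inf <- shrink(fit, Z, tau2 = 1e12)
  expect_equal(unname(sr_inf$beta_star), c(1, 3), tolerance = 1e-9)
  expect_equal(unname(sr_inf$se_star), c(1, 1), tolerance = 1e-5)
  # exact first stage: V = 0 leaves beta untouched whatever tau2
  fit0 <- list(beta = c(a = 1, b = 3), V = matrix(0, 2, 2))
  expect_equal(unname(shrink(fit0, Z, 0.5)$beta_star), c(1, 3))
  expect_equal(unname(shrink(fit0, Z, 0.5)$se_star), c(0, 0))
})

test_that("shrink matches the scalar conjugate-normal oracle on random diagonal instances", {
  set.seed(88)
  worst <- 0
  for (r in 1:1000) {
    p <- sample(2:20, 1)
    v <- stats::runif(p, 0.05, 4)
    beta <- stats::rnorm(p, 0, 3)
    tau2 <- stats::runif(1, 0.1, 30)
    Z <- matrix(1, p, 1)
    sr <- shrink(list(beta = beta, V = diag(v, p)), Z, tau2)
    w <- 1 / (v + tau2)
    bbar <- sum(w * beta) / sum(w)                    # GLS-weighted mean
    oracle <- (tau2 * beta + v * bbar) / (v + tau2)   # conjugate-normal
    worst <- max(worst, max(abs(sr$beta_star - oracle)))
  }
  expect_lt(worst, 1e-10)
})

test_that("shrinkage never inflates variance and interpolates toward the group mean", {
  set.seed(89)
  for (r in 1:50) {
    p <- sample(3:15, 1)
    v <- stats::runif(p, 0.05, 4)
    beta <- stats::rnorm(p, 0, 3)
    tau2 <- stats::runif(1, 0.1, 30)
    Z <- matrix(1, p, 1)
    sr <- shrink(list(beta = beta, V = diag(v, p)), Z, tau2)
    expect_true(all(sr$se_star <= sqrt(v) + 1e-10))
    gm <- drop(Z %*% sr$pi_hat)
    # componentwise between the first-stage beta and the fitted group mean
    expect_true(all(pmin(beta, gm) - 1e-10 <= sr$beta_star &
                    sr$beta_star <= pmax(beta, gm) + 1e-10))
  }
  # a correlated-V instance also cannot inflate the SEs
  V <- crossprod(matrix(stats::rnorm(25), 5)) / 5 + diag(0.1, 5)
  sr <- shrink(list(beta = stats::rnorm(5), V = V),
               matrix(1, 5, 1), tau2 = 2)
  expect_true(all(sr$se_star <= sqrt(diag(V)) + 1e-10))
})

test_that("distance from the group mean is nondecreasing in tau2 (homoskedastic first stage)", {
  # with equal first-stage variances the GLS group mean does not move with
  # tau2 and the scalar shrink factor tau2/(v + tau2) is increasing; with
  # unequal variances the moving weighted mean can cross a coefficient and
  # the distance momentarily dips, so the property holds as stated only in
  # the homoskedastic case
  set.seed(90)
  for (r in 1:20) {
    p <- sample(3:12, 1)
    v <- stats::runif(1, 0.05, 4)
    beta <- stats::rnorm(p, 0, 3)
    Z <- matrix(1, p, 1)
    grid <- c(0.1, 0.5, 1, 5, 25, 100)
    dist <- sapply(grid, function(t2) {
      sr <- shrink(list(beta = beta, V = diag(v, p)), Z, t2)
      abs(sr$beta_star - drop(Z %*% sr$pi_hat))
    })
    expect_true(all(diff(t(dist)) >= -1e-9))
  }
})

test_that("empirical-Bayes tau2 recovers a known generating variance", {
  set.seed(91)
  p <- 200
  tau2_true <- 4
  Z <- matrix(1, p, 1)
  v <- rep(1, p)
  beta <- stats::rnorm(p, 1.5, sqrt(v + tau2_true))
  t2 <- empirical_bayes_tau2(beta, diag(v, p), Z)
  # method-of-moments oracle for the same draw
  mom <- mean((beta - mean(beta))^2) - mean(v)
  expect_equal(t2, mom, tolerance = 0.35)
  expect_equal(t2, tau2_true, tolerance = 1)

  # boundary: beta exactly on the second-stage plane
  beta0 <- drop(Z %*% 2.5)
  expect_equal(empirical_bayes_tau2(beta0, diag(1, p), Z), 0)

  # scale equivariance: (c*beta, c^2*V) multiplies tau2-hat by c^2
  t2c <- empirical_bayes_tau2(3 * beta, diag(9 * v, p), Z)
  expect_equal(t2c, 9 * t2, tolerance = 0.05 * 9 * max(t2, 1))
  expect_error(empirical_bayes_tau2(c(1, 2), diag(1, 2),
                                    cbind(1, c(0, 1))), "p > q")
})
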