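test_that("covariance kernel matches frozen values and structural identities", {
  # no shared time yet, no constant genetic term: covariance zero
  expect_equal(cov_cohab(0, 18, kinship2 = 1, betaC = 1.41, lambdaC = 0.03),
               0)
  # constant-A (AE) case: flat in age
  expect_equal(cov_cohab(c(0, 18, 70), 18, kinship2 = 1, sigmaA2 = 0.52),
               rep(0.52, 3))
  # frozen CE value at t = 18 (computed independently)
  expect_equal(cov_cohab(18, 18, kinship2 = 1, betaC = 1.41, lambdaC = 0.03),
               0.5883249642, tolerance = 1e-9)
  # the MZ:DZ covariance ratio equals the MZ multiplier while cohabiting
  for (t in c(1, 5, 12, 18)) {
    mz <- cov_cohab(t, 18, 1, betaC = 1.41, lambdaC = 0.03, nuC = 0.005)
    dz <- cov_cohab(t, 18, 0.5, betaC = 1, lambdaC = 0.03, nuC = 0.005)
    expect_equal(mz / dz, 1.41)
  }
  # spouse pairs carry no genetic covariance in any variant
  expect_equal(cov_cohab(30, Inf, kinship2 = 0, sigmaA2 = 0.52,
                         betaA = 0, lambdaA = 0.03), 0)
})

test_that("covariance kernel is continuous at t0 for random parameters", {
  set.seed(501)
  for (i in 1:20) {
    t0 <- runif(1, 3, 40)
    args <- list(kinship2 = sample(c(1, 0.5), 1),
                 sigmaA2 = runif(1, 0, 0.5), betaA = runif(1, 0, 1),
                 lambdaA = runif(1, 0, 0.1), nuA = runif(1, 0, 0.05),
                 betaC = runif(1, 0, 1.5), lambdaC = runif(1, 0, 0.1),
                 nuC = runif(1, 0, 0.05))
    lo <- do.call(cov_cohab, c(list(t = t0 - 1e-10, t0 = t0), args))
    hi <- do.call(cov_cohab, c(list(t = t0 + 1e-10, t0 = t0), args))
    expect_lt(abs(lo - hi), 1e-10)
  }
})

test_that("variance-model variants encode their constraint sets", {
  pd <- data.frame(relationship = c("MZ", "DZ", "SIB", "PO", "SPOUSE"),
                   t = rep(10, 5), t0 = c(18, 18, 15, 18, Inf),
                   kinship2 = c(1, 0.5, 0.5, 0.5, 0))
  # AE: pure kinship scaling, no age dependence
  m <- variance_model("AE")
  expect_equal(m$kval(pd, c(sigmaA2 = 0.4)), 0.4 * pd$kinship2)
  # cohab-AE: spouses at zero via kinship
  m2 <- variance_model("COHAB_AE")
  v2 <- m2$kval(pd, c(lambdaA = 0.03, nuA = 0.01))
  expect_equal(v2[5], 0)
  expect_equal(v2[1] / v2[2], 2)
  # CE: beta_C fixed at 1 for DZ/SIB/SPOUSE, free for MZ and PO
  m3 <- variance_model("COHAB_CE")
  v3 <- m3$kval(pd, c(bC_MZ = 1.41, bC_PO = 0.49, lambdaC = 0.03, nuC = 0.005))
  k10 <- 1 - exp(-0.3)
  expect_equal(v3, c(1.41, 1, 1, 0.49, 1) * k10)
  # CE+A adds the constant genetic term
  m4 <- variance_model("COHAB_CE_PLUS_A")
  v4 <- m4$kval(pd, c(sigmaA2 = 0.13, bC_MZ = 1.41, bC_PO = 0.49,
                      lambdaC = 0.03, nuC = 0.005))
  expect_equal(v4 - v3, 0.13 * pd$kinship2)
})

test_that("CE fit recovers multipliers and nesting holds on simulated data", {
  set.seed(502)
  cfg <- pairs_cohort_config(c(MZ = 800, DZ = 400, SIB = 400, PO = 800,
                               SPOUSE = 400), ce_truth())
  sim <- simulate_cohort(cfg, seed = 52)
  accel <- adjust_covariates(age_acceleration(sim$phenotypes))
  fit <- fit_variance_model(accel, sim$pairs, "COHAB_CE", n_starts = 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$derived$ratio_mz_dzsib - 1.41), 4 * fit$se["bC_MZ"])
  expect_lt(abs(fit$estimates["bC_PO"] - 1 / 2.03), 4 * fit$se["bC_PO"])
  # CE+A nests CE
  fit_a <- fit_variance_model(accel, sim$pairs, "COHAB_CE_PLUS_A",
                              n_starts = 2)
  expect_gte(fit_a$loglik, fit$loglik - 0.05)
  # every assembled family covariance matrix at the optimum is PD
  md <- make_model_data(accel, sim$pairs)
  expect_identical(psd_violations(md, fit), 0L)
  # refusal on structurally impossible requests
  expect_error(fit_variance_model(accel,
                                  sim$pairs[sim$pairs$relationship != "MZ", ],
                                  "COHAB_CE"),
               "requires MZ")
  sponly <- pairs_cohort_config(c(SPOUSE = 20), ce_truth())
  simsp <- simulate_cohort(sponly, seed = 53)
  accsp <- adjust_covariates(age_acceleration(simsp$phenotypes))
  expect_error(fit_variance_model(accsp, simsp$pairs, "AE"),
               "genetically related")
})

test_that("AIC comparison ranks, ties and nested tests behave", {
  f1 <- structure(list(model_name = "a", loglik = -100, n_params = 3,
                       aic = 206, converged = TRUE, fingerprint = c(1, 2, 3)),
                  class = "epicohab_fit")
  f2 <- structure(list(model_name = "b", loglik = -99, n_params = 5,
                       aic = 208, converged = TRUE, fingerprint = c(1, 2, 3)),
                  class = "epicohab_fit")
  tab <- compare_variants(list(a = f1, b = f2),
                          nested = list(c("a", "b")))
  expect_equal(tab$model, c("a", "b"))
  expect_equal(tab$aic, c(206, 208))
  expect_equal(tab$delta_aic, c(0, 2))
  lt <- attr(tab, "lrt")
  expect_equal(lt$statistic, 2)
  expect_equal(lt$df, 2)
  # identical fit twice: delta AIC 0, fewer parameters ranked first
  f3 <- f1; f3$model_name <- "a_dup"; f3$n_params <- 4; f3$aic <- 208
  tab2 <- compare_variants(list(big = f3, small = f1))
  expect_equal(tab2$model, c("small", "big"))
  # different data refused
  f4 <- f2; f4$fingerprint <- c(9, 9, 9)
  expect_error(compare_variants(list(a = f1, d = f4)), "different data")
})

test_that("variance-proportion curves partition unit variance sensibly", {
  fit <- structure(list(
    model = variance_model("COHAB_CE"),
    estimates = c(bC_MZ = 1.41, bC_PO = 0.49, lambdaC = 0.03, nuC = 0.005,
                  var_a = 1.02, var_b = 0.98),
    se = c(bC_MZ = 0.1, bC_PO = 0.1, lambdaC = 0.005, nuC = 0.002,
           var_a = 0.05, var_b = 0.04)), class = "epicohab_fit")
  pc <- variance_proportion_curves(fit, ages = c(0, 18, 60))
  expect_true(all(pc$A == 0))                       # CE has no genetic share
  expect_true(all(pc$C >= 0 & pc$C <= 1 & pc$E >= 0 & pc$E <= 1))
  mz18 <- pc[pc$group == "MZ" & pc$age == 18, ]
  expect_equal(mz18$C, 1.41 * (1 - exp(-0.03 * 18)))
  expect_equal(mz18$C + mz18$E, 1)
  dz18 <- pc[pc$group == "DZSIB" & pc$age == 18, ]
  expect_equal(mz18$C / dz18$C, 1.41)
  expect_gt(attr(pc, "reference_variance"), 0)
  # AE curves are flat in age
  fit_ae <- structure(list(model = variance_model("AE"),
                           estimates = c(sigmaA2 = 0.52, var_a = 1),
                           se = c(sigmaA2 = 0.02, var_a = 0.05)),
                      class = "epicohab_fit")
  pa <- variance_proportion_curves(fit_ae, ages = c(0, 40, 80))
  expect_equal(unique(pa$A[pa$group == "MZ"]), 0.52)
  expect_equal(unique(pa$A[pa$group == "SPOUSE"]), 0)
})
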