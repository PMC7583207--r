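test_that("correlation kernel matches frozen values and boundary behaviour", {
  # at the start of cohabitation the correlation is theta - 1
  expect_equal(rho_cohab(0, 18, theta = 1, lambda = 0.5, nu = 0.1), 0)
  expect_equal(rho_cohab(0, 18, theta = 1.3, lambda = 2, nu = 0), 0.3)
  # frozen values computed independently at high precision
  expect_equal(rho_cohab(18, 18, 1, 0.041, 0.005), 0.5219309017,
               tolerance = 1e-9)
  expect_equal(rho_cohab(68, 18, 1, 0.041, 0.01),
               0.5219309017 * exp(-0.5), tolerance = 1e-9)
  expect_equal(0.5219309017 * exp(-0.5), 0.3165670942, tolerance = 1e-9)
})

test_that("correlation kernel is continuous at t0 and monotone per regime", {
  set.seed(301)
  for (i in 1:20) {
    th <- runif(1, 0.5, 1.5); la <- runif(1, 0.005, 0.1)
    nu <- runif(1, 0, 0.05); t0 <- runif(1, 5, 40)
    eps <- 1e-9
    expect_lt(abs(rho_cohab(t0 - eps, t0, th, la, nu) -
                    rho_cohab(t0 + eps, t0, th, la, nu)), 1e-7)
    # nondecreasing while cohabiting, decreasing after separation (nu > 0)
    tt <- seq(0, t0, length.out = 50)
    expect_true(all(diff(rho_cohab(tt, t0, th, la, nu)) >= 0))
    if (nu > 1e-6 && th > exp(-la * t0)) {
      ts <- seq(t0 + 0.1, t0 + 60, length.out = 50)
      expect_true(all(diff(rho_cohab(ts, t0, th, la, nu)) < 0))
    }
    # with nu = 0 the separated-regime correlation is constant
    expect_equal(rho_cohab(t0 + 30, t0, th, la, 0),
                 th - exp(-la * t0))
  }
})

test_that("within-study pair correlations recover generating values", {
  set.seed(302)
  cohort <- toy_pairs_cohort(1000, "MZ", age_a = 13.8, rho = 0.69, var = 7)
  tab <- fit_pair_correlations(cohort$pheno, cohort$pairs)
  se <- (1 - 0.69^2) / sqrt(1000)
  expect_lt(abs(tab$rho - 0.69), 3 * se)
  expect_lt(tab$p, 1e-6)
  expect_equal(tab$n_pairs, 1000L)
  expect_equal(tab$mean_age, 13.8)
  expect_true(tab$ci_lo < tab$rho & tab$rho < tab$ci_hi)
})

test_that("degenerate and null pair data are reported sanely", {
  set.seed(303)
  # duplicated members: correlation pinned at the reporting bound
  n <- 50
  fam <- paste0("s1_f", 1:n)
  z <- rnorm(n)
  ph <- data.frame(study_id = "s1", family_id = rep(fam, 2),
                   individual_id = c(paste0(fam, "_1"), paste0(fam, "_2")),
                   sex = "female", chronological_age = 10, dnam_age = 0,
                   analysis_residual = c(z, z))
  pr <- data.frame(family_id = fam, id_a = paste0(fam, "_1"),
                   id_b = paste0(fam, "_2"), relationship = "MZ")
  tab <- fit_pair_correlations(ph, pr)
  expect_gte(tab$rho, 0.99 - 1e-6)
  expect_true(tab$boundary)
  # independent members: estimate near zero
  c0 <- toy_pairs_cohort(1000, "DZ", age_a = 40, rho = 0)
  t0 <- fit_pair_correlations(c0$pheno, c0$pairs)
  expect_lt(abs(t0$rho), 0.08)
  # too few pairs: suppressed with a warning
  c2 <- toy_pairs_cohort(2, "SIB", age_a = 10, age_b = 12, rho = 0.3)
  expect_warning(out <- fit_pair_correlations(c2$pheno, c2$pairs),
                 "suppressed")
  expect_null(out)
})

test_that("MZ-versus-DZ comparison has power at the adolescent design size", {
  set.seed(304)
  rej05 <- 0
  nrep <- 25
  for (r in seq_len(nrep)) {
    mz <- toy_pairs_cohort(67, "MZ", age_a = 13.8, rho = 0.69)
    dz <- toy_pairs_cohort(111, "DZ", age_a = 13.2, rho = 0.35)
    dz$pheno$individual_id <- sub("f", "g", dz$pheno$individual_id)
    dz$pheno$family_id <- sub("f", "g", dz$pheno$family_id)
    dz$pairs$family_id <- sub("f", "g", dz$pairs$family_id)
    dz$pairs$id_a <- sub("f", "g", dz$pairs$id_a)
    dz$pairs$id_b <- sub("f", "g", dz$pairs$id_b)
    ph <- rbind(mz$pheno, dz$pheno); pr <- rbind(mz$pairs, dz$pairs)
    p <- test_mz_vs_dz(ph, pr)$p_value
    rej05 <- rej05 + (p < 0.05)
  }
  expect_gte(rej05 / nrep, 0.8)
  # missing zygosity group: not-applicable marker
  mz <- toy_pairs_cohort(10, "MZ", age_a = 5, rho = 0.3)
  expect_true(is.na(test_mz_vs_dz(mz$pheno, mz$pairs)$p_value))
})

test_that("lifespan model nesting and degenerate-age behaviour are correct", {
  set.seed(305)
  cfg <- pairs_cohort_config(c(MZ = 150, DZ = 80, SIB = 80, PO = 150),
                             correlation_truth(), sex_effect = 0)
  sim <- simulate_cohort(cfg, seed = 31)
  accel <- adjust_covariates(age_acceleration(sim$phenotypes))
  f1 <- fit_lifespan_model(accel, sim$pairs, theta = "one", n_starts = 2)
  ff <- fit_lifespan_model(accel, sim$pairs, theta = "free", n_starts = 2)
  expect_gte(ff$loglik, f1$loglik - 0.05)   # nesting
  expect_gte(lrt(f1, ff)$p_value, 0)
  # all pairs at t = 0 with theta = 1: predicted correlation is zero
  # everywhere and the fit equals the independence log-likelihood
  nb <- pairs_cohort_config(c(MZ = 80, DZ = 80), correlation_truth(),
                            age = age_fixed(0), sex_effect = 0)
  simnb <- simulate_cohort(nb, seed = 32)
  accnb <- adjust_covariates(
    suppressWarnings(age_acceleration(simnb$phenotypes)))
  fnb <- fit_lifespan_model(accnb, simnb$pairs,
                            groups = list(MZ = "MZ", DZSIB = "DZ"),
                            theta = "one", n_starts = 2)
  y <- accnb$analysis_residual
  vhat <- unname(fnb$estimates[grep("^var_", names(fnb$estimates))])
  ll_indep <- sum(dnorm(y, 0, sqrt(vhat), log = TRUE))
  expect_equal(fnb$loglik, ll_indep, tolerance = 1e-6)
  pred <- predict_lifespan_rho(fnb, ages = 0)
  expect_equal(pred$rho[pred$age == 0], rep(0, nrow(pred[pred$age == 0, ])),
               tolerance = 1e-6)
})

test_that("lifespan rate recovery is consistent as pairs per group grow", {
  set.seed(306)
  fits <- lapply(c(250, 1000), function(n) {
    cfg <- pairs_cohort_config(c(MZ = n, DZ = n / 2, SIB = n / 2, PO = n),
                               correlation_truth(), sex_effect = 0)
    sim <- simulate_cohort(cfg, seed = 1000 + n)
    accel <- adjust_covariates(age_acceleration(sim$phenotypes))
    fit_lifespan_model(accel, sim$pairs, theta = "one", n_starts = 2)
  })
  for (f in fits) {
    expect_lt(abs(f$estimates["lambda_MZ"] - 0.041), 4 * f$se["lambda_MZ"])
    expect_lt(abs(f$estimates["lambda_DZSIB"] - 0.026),
              4 * f$se["lambda_DZSIB"])
  }
  # information grows with sample size
  expect_lt(fits[[2]]$se["lambda_MZ"], fits[[1]]$se["lambda_MZ"])
})
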