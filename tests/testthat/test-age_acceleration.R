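test_that("acceleration residuals satisfy the OLS normal equations", {
  set.seed(101)
  # perfectly linear input: all residuals zero
  ph <- toy_pheno(6, dnam = NULL)
  ph$dnam_age <- 2 * ph$chronological_age + 5
  expect_equal(age_acceleration(ph)$raw_acceleration, rep(0, 6))

  # generic stratum: residuals orthogonal to 1 and to age
  ph <- toy_pheno(40, age = runif(40, 0, 80))
  a <- age_acceleration(ph)
  expect_lt(abs(sum(a$raw_acceleration)), 1e-8)
  expect_lt(abs(sum(a$raw_acceleration * a$chronological_age)), 1e-6)

  # 4-point closed-form oracle: beta = Sxy/Sxx computed by hand formulas
  ages <- c(0, 10, 20, 30); dn <- c(1, 9, 23, 27)
  beta <- sum((ages - mean(ages)) * (dn - mean(dn))) /
    sum((ages - mean(ages))^2)
  alpha <- mean(dn) - beta * mean(ages)
  oracle <- dn - (alpha + beta * ages)
  ph4 <- toy_pheno(4, age = ages, dnam = dn)
  expect_equal(age_acceleration(ph4)$raw_acceleration, oracle)
})

test_that("residualization is idempotent and strata are respected", {
  set.seed(102)
  ph <- rbind(toy_pheno(25, study = "a", age = runif(25, 0, 50)),
              toy_pheno(25, study = "b", age = runif(25, 30, 90)))
  a1 <- age_acceleration(ph)
  ph2 <- a1
  ph2$dnam_age <- a1$raw_acceleration
  a2 <- age_acceleration(ph2)
  expect_equal(a2$raw_acceleration, a1$raw_acceleration, tolerance = 1e-10)
  # per-stratum zero means
  expect_equal(as.numeric(tapply(a1$raw_acceleration, a1$study_id, mean)),
               c(0, 0), tolerance = 1e-10)
})

test_that("constant-age strata fall back to centering with a warning", {
  ph <- toy_pheno(5, age = rep(18, 5), dnam = c(20, 22, 24, 26, 28))
  expect_warning(a <- age_acceleration(ph), "single age value")
  expect_equal(a$raw_acceleration, c(-4, -2, 0, 2, 4))
})

test_that("multi-tissue standardization averages per-tissue z-scores", {
  # two tissues measured on the same 3 children
  ph <- data.frame(study_id = "s", family_id = c(1, 2, 3, 1, 2, 3),
                   individual_id = rep(c("i1", "i2", "i3"), 2),
                   sex = "female", chronological_age = 0,
                   dnam_age = c(1, 2, 3, 10, 20, 30),
                   tissue = rep(c("cord", "placenta"), each = 3))
  out <- standardize_multitissue(ph)
  # oracle: base::scale on each tissue, then per-individual mean
  z <- c(scale(c(1, 2, 3)) + scale(c(10, 20, 30))) / 2
  expect_equal(out$dnam_age, z)
  expect_equal(nrow(out), 3L)
  expect_equal(out$tissue, rep(2L, 3))
  # single tissue: output is the plain z-score, mean 0 variance 1
  ph1 <- ph[1:3, ]
  out1 <- standardize_multitissue(ph1)
  expect_equal(mean(out1$dnam_age), 0)
  expect_equal(var(out1$dnam_age), 1)
  # zero-variance tissue is rejected
  ph$dnam_age[4:6] <- 7
  expect_error(standardize_multitissue(ph), "zero DNAm-age variance")
})

test_that("covariate adjustment removes planted effects, never inflates variance", {
  set.seed(103)
  n <- 400
  ph <- toy_pheno(n, age = runif(n, 0, 80),
                  sex = sample(c("female", "male"), n, replace = TRUE))
  ph$dnam_age <- ph$chronological_age + 2 * (ph$sex == "male") + rnorm(n, 0, 2)
  a <- adjust_covariates(age_acceleration(ph))
  gm <- tapply(a$analysis_residual, a$sex, mean)
  se <- sqrt(sum(tapply(a$analysis_residual, a$sex, var) /
                   table(a$sex)))
  expect_lt(abs(gm["male"] - gm["female"]), 2 * se)
  expect_lte(var(a$analysis_residual), var(a$raw_acceleration) + 1e-12)
  # residuals orthogonal to the sex column
  expect_lt(abs(cor(a$analysis_residual, as.numeric(a$sex == "male"))), 1e-10)
})

test_that("collinear cell fractions are dropped automatically", {
  set.seed(104)
  n <- 60
  ph <- toy_pheno(n, age = runif(n, 20, 70))
  ph$cell_a <- runif(n, 0.2, 0.6)
  ph$cell_b <- runif(n, 0.1, 0.3)
  ph$cell_c <- 1 - ph$cell_a - ph$cell_b  # sums to 1 with the intercept
  a <- age_acceleration(ph)
  expect_message(adj <- adjust_covariates(a, cells = TRUE), "collinear")
  expect_lt(abs(cor(adj$analysis_residual, ph$cell_a)), 1e-10)
  expect_lt(abs(cor(adj$analysis_residual, ph$cell_b)), 1e-10)
})

test_that("descriptives match hand-computed Pearson and deviation values", {
  # 5-row toy table, textbook Pearson formula as oracle
  ages <- 1:5; dn <- c(2, 1, 5, 4, 8)
  r_oracle <- sum((ages - mean(ages)) * (dn - mean(dn))) /
    sqrt(sum((ages - mean(ages))^2) * sum((dn - mean(dn))^2))
  ph <- toy_pheno(5, age = ages, dnam = dn)
  d <- cohort_descriptives(ph)
  expect_equal(d$cor_age_dnam, r_oracle)
  # identity DNAm age: r = 1, zero deviation
  ph2 <- toy_pheno(10, age = 1:10, dnam = 1:10)
  d2 <- cohort_descriptives(ph2)
  expect_equal(d2$cor_age_dnam, 1)
  expect_equal(d2$abs_dev_mean, 0)
  # age-independent DNAm age: r near 0 for large n
  set.seed(105)
  ph3 <- toy_pheno(4000, age = runif(4000, 0, 90), dnam = rnorm(4000))
  expect_lt(abs(cohort_descriptives(ph3)$cor_age_dnam), 0.05)
})

test_that("variance-by-age bins respect the minimum count", {
  set.seed(106)
  ph <- toy_pheno(120, age = c(runif(117, 0, 30), 95, 96, 97))
  v <- acceleration_variance_by_age(ph, width = 10, min_n = 5)
  expect_true(all(v$n >= 5))
  expect_false(any(v$age_lo == 90))  # 3 observations only, suppressed
})
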