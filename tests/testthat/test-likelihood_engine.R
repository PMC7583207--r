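test_that("family log-likelihood matches closed forms and the cofactor oracle", {
  # singleton at the mean with unit variance
  expect_equal(family_loglik(0, matrix(1)), -0.5 * log(2 * pi))
  # independent pair factorizes into univariate terms
  y <- c(0.7, -1.2); v <- c(1.3, 0.8)
  expect_equal(family_loglik(y, diag(v)),
               sum(dnorm(y, 0, sqrt(v), log = TRUE)))
  # 3-member family against the cofactor-expansion oracle
  S <- matrix(c(1.0, 0.4, 0.2,
                0.4, 1.5, 0.3,
                0.2, 0.3, 0.9), 3, 3)
  y3 <- c(0.5, -0.3, 1.1)
  expect_equal(family_loglik(y3, S), loglik3_cofactor(y3, S),
               tolerance = 1e-10)
  # non-PD covariance is rejected as -Inf, not an error
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_identical(family_loglik(c(0, 0), bad), -Inf)
  expect_error(family_loglik(c(NA, 0), diag(2)), "non-finite")
})

test_that("family log-likelihood is permutation invariant", {
  set.seed(201)
  S <- crossprod(matrix(rnorm(16), 4, 4)) + diag(4)
  y <- rnorm(4)
  for (i in 1:5) {
    p <- sample(4)
    expect_equal(family_loglik(y[p], S[p, p]), family_loglik(y, S))
  }
})

test_that("dataset log-likelihood is additive over disjoint family sets", {
  set.seed(202)
  c1 <- toy_pairs_cohort(30, "MZ", age_a = 10, rho = 0.5, study = "a")
  c2 <- toy_pairs_cohort(30, "DZ", age_a = 10, rho = 0.2, study = "a")
  c2$pheno$individual_id <- sub("_f", "_g", c2$pheno$individual_id)
  c2$pheno$family_id <- sub("_f", "_g", c2$pheno$family_id)
  c2$pairs$id_a <- sub("_f", "_g", c2$pairs$id_a)
  c2$pairs$id_b <- sub("_f", "_g", c2$pairs$id_b)
  c2$pairs$family_id <- sub("_f", "_g", c2$pairs$family_id)
  joint_ph <- rbind(c1$pheno, c2$pheno)
  joint_pr <- rbind(c1$pairs, c2$pairs)
  m <- pair_correlation_model(list(MZ = "MZ", DZ = "DZ"))
  par <- c(atanh(0.4), atanh(0.15), log(1.2))
  md_j <- make_model_data(joint_ph, joint_pr)
  llj <- -epicohab:::.negll(par, md_j, m, want_grad = FALSE)$value
  md_1 <- make_model_data(c1$pheno, c1$pairs)
  md_2 <- make_model_data(c2$pheno, c2$pairs)
  m1 <- pair_correlation_model(list(MZ = "MZ"))
  m2 <- pair_correlation_model(list(DZ = "DZ"))
  ll1 <- -epicohab:::.negll(c(atanh(0.4), log(1.2)), md_1, m1,
                            want_grad = FALSE)$value
  ll2 <- -epicohab:::.negll(c(atanh(0.15), log(1.2)), md_2, m2,
                            want_grad = FALSE)$value
  expect_equal(llj, ll1 + ll2, tolerance = 1e-9)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(203)
  cfg <- pairs_cohort_config(c(MZ = 40, DZ = 30, SIB = 30, PO = 40,
                               SPOUSE = 30), ce_truth(), sex_effect = 0)
  sim <- simulate_cohort(cfg, seed = 99)
  accel <- adjust_covariates(age_acceleration(sim$phenotypes))
  md <- make_model_data(accel, sim$pairs)
  models <- list(
    variance_model("AE"), variance_model("COHAB_AE"),
    variance_model("COHAB_ACE"), variance_model("COHAB_CE"),
    variance_model("COHAB_CE_PLUS_A"),
    lifespan_correlation_model(theta = "free"),
    pair_correlation_model(list(MZ = "MZ", OTH = c("DZ", "SIB", "PO",
                                                   "SPOUSE"))))
  for (m in models) {
    p <- c(mapply(epicohab:::.tr_from_nat, m$kpar$init, m$kpar$transform),
           log(1.1))
    p <- p + runif(length(p), -0.1, 0.1)
    g <- epicohab:::.negll(p, md, m)$grad
    gn <- num_grad(function(q) epicohab:::.negll(q, md, m,
                                                 want_grad = FALSE)$value, p)
    expect_equal(g, gn, tolerance = 1e-5)
  }
})

test_that("pair-correlation MLE matches a grid-search oracle to 1e-3", {
  set.seed(204)
  cohort <- toy_pairs_cohort(150, "MZ", age_a = 18, rho = 0.55, var = 2.3)
  md <- make_model_data(cohort$pheno, cohort$pairs)
  m <- pair_correlation_model(list(MZ = "MZ"))
  fit <- ml_fit(md, m, n_starts = 3)
  # oracle: profile the bivariate normal likelihood over a rho grid,
  # maximizing the variance analytically is avoided - grid over both
  y1 <- cohort$pheno$analysis_residual[1:150]
  y2 <- cohort$pheno$analysis_residual[151:300]
  grid_ll <- function(r, v) {
    D <- v^2 * (1 - r^2)
    -0.5 * sum(2 * log(2 * pi) + log(D) +
                 (v * y1^2 - 2 * r * v * y1 * y2 + v * y2^2) / D)
  }
  rhos <- seq(-0.99, 0.99, by = 1e-3)
  vhat <- fit$estimates["var_s1"]
  prof <- vapply(rhos, grid_ll, 0, v = vhat)
  expect_lt(abs(rhos[which.max(prof)] - fit$estimates["rho_MZ"]), 1e-3 + 1e-9)
  # refitting from the solution changes the log-likelihood negligibly
  fit2 <- ml_fit(md, m, n_starts = 1)
  expect_lt(abs(fit2$loglik - fit$loglik), 1e-6)
})

test_that("AIC identity and convergence diagnostics hold", {
  set.seed(205)
  cohort <- toy_pairs_cohort(60, "MZ", age_a = 5, rho = 0.4)
  md <- make_model_data(cohort$pheno, cohort$pairs)
  fit <- ml_fit(md, pair_correlation_model(list(MZ = "MZ")))
  expect_identical(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-4 * max(1, abs(fit$loglik)))
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(js$loglik, fit$loglik)
  expect_equal(js$estimates$rho_MZ, unname(fit$estimates["rho_MZ"]))
})

test_that("likelihood-ratio test computes the chi-square tail correctly", {
  f0 <- structure(list(loglik = -100, n_params = 3, fingerprint = c(1, 2, 3)),
                  class = "epicohab_fit")
  f1 <- structure(list(loglik = -100, n_params = 4, fingerprint = c(1, 2, 3)),
                  class = "epicohab_fit")
  r <- lrt(f0, f1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # the classical 5% critical value
  f2 <- structure(list(loglik = -100 + 3.841 / 2, n_params = 4,
                       fingerprint = c(1, 2, 3)), class = "epicohab_fit")
  expect_equal(round(lrt(f0, f2)$p_value, 3), 0.050)
  # misuse is caught
  fbad <- structure(list(loglik = -120, n_params = 4,
                         fingerprint = c(1, 2, 3)), class = "epicohab_fit")
  expect_error(lrt(f0, fbad), "below null")
  fother <- structure(list(loglik = -90, n_params = 4, fingerprint = c(9, 9, 9)),
                      class = "epicohab_fit")
  expect_error(lrt(f0, fother), "different data")
  expect_error(lrt(f1, f0), "df must be")
})
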