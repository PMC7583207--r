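## Cohabitation-dependent variance-components models: the pairwise
## covariance kernel, the five fitted variants (AE, cohabitation AE, ACE,
## CE, CE plus constant A), AIC comparison and variance-proportion curves.
##
## Kernels are parameterized on the correlation scale (variance fractions
## of the unit study variance); family covariances are k * sigma_i * sigma_j.

.kern <- function(t, t0, lambda, nu) {
  ifelse(t <= t0,
         1 - exp(-lambda * t),
         (1 - exp(-lambda * t0)) * exp(-nu * (t - t0)))
}
.kern_dlambda <- function(t, t0, lambda, nu) {
  ifelse(t <= t0,
         t * exp(-lambda * t),
         t0 * exp(-lambda * t0) * exp(-nu * (t - t0)))
}
.kern_dnu <- function(t, t0, lambda, nu) {
  ifelse(t <= t0, 0,
         -(t - t0) * (1 - exp(-lambda * t0)) * exp(-nu * (t - t0)))
}

#' Cohabitation-dependent pairwise covariance kernel
#'
#' Covariance (as a fraction of the unit study variance) between two
#' relatives: a constant additive-genetic term `alpha * sigmaA2`, a
#' cohabitation-dependent genetic term `betaA * (1 - exp(-lambdaA t))` and
#' a cohabitation-dependent shared-environment term
#' `betaC * (1 - exp(-lambdaC t))` while living together; after separation
#' the two kernel terms decay at rates `nuA`, `nuC`. Continuous at
#' `t = t0`.
#'
#' @param t,t0 Cohabitation clock (years), vectorized.
#' @param kinship2 Doubled kinship coefficient of the pair.
#' @param sigmaA2 Constant additive-genetic variance component.
#' @param betaA Genetic kernel multiplier (conventionally `kinship2`).
#' @param lambdaA,nuA Genetic rise/decay rates per year.
#' @param betaC Shared-environment multiplier for the pair's group.
#' @param lambdaC,nuC Shared-environment rise/decay rates per year.
#' @param alpha Multiplier on `sigmaA2`; defaults to `kinship2`.
#' @return Covariance values.
#' @examples
#' cov_cohab(18, 18, kinship2 = 1, betaC = 1.41, lambdaC = 0.03)
#' @export
cov_cohab <- function(t, t0, kinship2, sigmaA2 = 0, betaA = 0,
                      lambdaA = 0, nuA = 0, betaC = 0, lambdaC = 0,
                      nuC = 0, alpha = kinship2) {
  alpha * sigmaA2 +
    betaA * .kern(t, t0, lambdaA, nuA) +
    betaC * .kern(t, t0, lambdaC, nuC)
}

#' Recognised variance-model variants
#' @return Character vector of variant codes.
#' @export
variance_variants <- function() {
  c("AE", "COHAB_AE", "COHAB_ACE", "COHAB_CE", "COHAB_CE_PLUS_A")
}

# per-pair shared-environment multiplier under the CE-style constraint:
# free for MZ and PO, fixed at 1 for DZ, siblings and spouses
.bC_of <- function(relationship, bC_MZ, bC_PO) {
  out <- rep(1, length(relationship))
  out[relationship == "MZ"] <- bC_MZ
  out[relationship == "PO"] <- bC_PO
  out
}

#' Variance-components model object
#'
#' Builds the model object for one of the five variants, encoding the
#' published constraint sets:
#' * `AE`: constant genetic effects; covariance `kinship2 * sigmaA2`.
#' * `COHAB_AE`: cohabitation-dependent genetic effects;
#'   `kinship2 * (1 - exp(-lambdaA t))`, shared rates over non-spouse
#'   pairs (spouses have zero genetic covariance via kinship).
#' * `COHAB_ACE`: cohabitation-dependent genetic and shared-environment
#'   effects; `betaC = 1` for all pairs.
#' * `COHAB_CE`: shared environment only; `betaC = 1` for DZ, sibling and
#'   spouse pairs, free for MZ and parent--offspring pairs.
#' * `COHAB_CE_PLUS_A`: the CE model plus a constant additive genetic
#'   component `kinship2 * sigmaA2`.
#'
#' @param variant One of [variance_variants()].
#' @param init Named list of starting values.
#' @return Model object for [ml_fit()].
#' @export
variance_model <- function(variant = variance_variants(),
                           init = list(sigmaA2 = 0.1, lambda = 0.03,
                                       nu = 0.01, bC_MZ = 1.2, bC_PO = 0.7)) {
  variant <- match.arg(variant)
  mk <- function(name, transform, iv) {
    data.frame(name = name, transform = transform, init = iv,
               stringsAsFactors = FALSE)
  }
  kpar <- switch(variant,
    AE = mk("sigmaA2", "log", init$sigmaA2),
    COHAB_AE = rbind(mk("lambdaA", "log", init$lambda),
                     mk("nuA", "log", init$nu)),
    COHAB_ACE = rbind(mk("lambdaA", "log", init$lambda),
                      mk("nuA", "log", init$nu),
                      mk("lambdaC", "log", init$lambda),
                      mk("nuC", "log", init$nu)),
    COHAB_CE = rbind(mk("bC_MZ", "log", init$bC_MZ),
                     mk("bC_PO", "log", init$bC_PO),
                     mk("lambdaC", "log", init$lambda),
                     mk("nuC", "log", init$nu)),
    COHAB_CE_PLUS_A = rbind(mk("sigmaA2", "log", init$sigmaA2),
                            mk("bC_MZ", "log", init$bC_MZ),
                            mk("bC_PO", "log", init$bC_PO),
                            mk("lambdaC", "log", init$lambda),
                            mk("nuC", "log", init$nu)))

  kval <- function(pd, kp) {
    switch(variant,
      AE = pd$kinship2 * kp[["sigmaA2"]],
      COHAB_AE = pd$kinship2 * .kern(pd$t, pd$t0, kp[["lambdaA"]], kp[["nuA"]]),
      COHAB_ACE = pd$kinship2 * .kern(pd$t, pd$t0, kp[["lambdaA"]], kp[["nuA"]]) +
        .kern(pd$t, pd$t0, kp[["lambdaC"]], kp[["nuC"]]),
      COHAB_CE = .bC_of(pd$relationship, kp[["bC_MZ"]], kp[["bC_PO"]]) *
        .kern(pd$t, pd$t0, kp[["lambdaC"]], kp[["nuC"]]),
      COHAB_CE_PLUS_A = pd$kinship2 * kp[["sigmaA2"]] +
        .bC_of(pd$relationship, kp[["bC_MZ"]], kp[["bC_PO"]]) *
        .kern(pd$t, pd$t0, kp[["lambdaC"]], kp[["nuC"]]))
  }

  kgrad <- function(pd, kp) {
    out <- matrix(0, nrow(pd), nrow(kpar))
    colnames(out) <- kpar$name
    if (variant == "AE") {
      out[, "sigmaA2"] <- pd$kinship2
    } else if (variant == "COHAB_AE") {
      out[, "lambdaA"] <- pd$kinship2 *
        .kern_dlambda(pd$t, pd$t0, kp[["lambdaA"]], kp[["nuA"]])
      out[, "nuA"] <- pd$kinship2 *
        .kern_dnu(pd$t, pd$t0, kp[["lambdaA"]], kp[["nuA"]])
    } else if (variant == "COHAB_ACE") {
      out[, "lambdaA"] <- pd$kinship2 *
        .kern_dlambda(pd$t, pd$t0, kp[["lambdaA"]], kp[["nuA"]])
      out[, "nuA"] <- pd$kinship2 *
        .kern_dnu(pd$t, pd$t0, kp[["lambdaA"]], kp[["nuA"]])
      out[, "lambdaC"] <- .kern_dlambda(pd$t, pd$t0, kp[["lambdaC"]], kp[["nuC"]])
      out[, "nuC"] <- .kern_dnu(pd$t, pd$t0, kp[["lambdaC"]], kp[["nuC"]])
    } else {
      bC <- .bC_of(pd$relationship, kp[["bC_MZ"]], kp[["bC_PO"]])
      K <- .kern(pd$t, pd$t0, kp[["lambdaC"]], kp[["nuC"]])
      out[, "bC_MZ"] <- ifelse(pd$relationship == "MZ", K, 0)
      out[, "bC_PO"] <- ifelse(pd$relationship == "PO", K, 0)
      out[, "lambdaC"] <- bC * .kern_dlambda(pd$t, pd$t0,
                                             kp[["lambdaC"]], kp[["nuC"]])
      out[, "nuC"] <- bC * .kern_dnu(pd$t, pd$t0, kp[["lambdaC"]], kp[["nuC"]])
      if (variant == "COHAB_CE_PLUS_A") out[, "sigmaA2"] <- pd$kinship2
    }
    out
  }

  list(name = variant, variant = variant, kpar = kpar,
       kval = kval, kgrad = kgrad)
}

#' Fit a variance-components model
#'
#' Maximum-likelihood fit of one variant over the pooled pairs/families
#' with free per-study variances. Derived quantities are attached:
#' under the CE-style variants, the MZ:(DZ,sibling) shared-environment
#' ratio (`bC_MZ`) and the (DZ,sibling):parent-offspring ratio
#' (`1/bC_PO`); under AE, the heritability `sigmaA2`; under CE+A, the
#' constant genetic share `sigmaA2`.
#'
#' @param pheno,pairs Pooled data.
#' @param variant One of [variance_variants()].
#' @param n_starts Optimizer starts.
#' @param hessian Compute standard errors (see [ml_fit()]).
#' @param ... Passed to [make_model_data()].
#' @return An `epicohab_fit` with a `derived` element.
#' @export
fit_variance_model <- function(pheno, pairs, variant = variance_variants(),
                               n_starts = 5, hessian = TRUE, ...) {
  variant <- match.arg(variant)
  present <- unique(pairs$relationship)
  if (variant %in% c("COHAB_CE", "COHAB_CE_PLUS_A")) {
    need <- c("MZ", "PO")
    if (!all(need %in% present)) {
      stop(variant, " requires MZ and PO pairs (free multipliers); missing: ",
           paste(setdiff(need, present), collapse = ", "), call. = FALSE)
    }
  }
  if (variant %in% c("AE", "COHAB_AE", "COHAB_ACE") &&
      !any(kinship2(present) > 0)) {
    stop(variant, " requires genetically related pairs", call. = FALSE)
  }
  md <- make_model_data(pheno, pairs, ...)
  fit <- ml_fit(md, variance_model(variant), n_starts = n_starts,
                hessian = hessian)

  der <- list()
  est <- fit$estimates
  if (variant %in% c("COHAB_CE", "COHAB_CE_PLUS_A")) {
    der$ratio_mz_dzsib <- unname(est["bC_MZ"])
    der$ratio_mz_dzsib_ci <- unname(fit$ci["bC_MZ", ])
    der$ratio_dzsib_po <- unname(1 / est["bC_PO"])
    der$ratio_dzsib_po_ci <- unname(rev(1 / fit$ci["bC_PO", ]))
  }
  if (variant == "AE") {
    der$heritability <- unname(est["sigmaA2"])
    der$heritability_ci <- unname(fit$ci["sigmaA2", ])
  }
  if (variant == "COHAB_CE_PLUS_A") {
    der$genetic_share <- unname(est["sigmaA2"])
    der$genetic_share_ci <- unname(fit$ci["sigmaA2", ])
  }
  fit$derived <- der
  fit
}

#' Rank variance-model fits by AIC
#'
#' @param fits Named list of `epicohab_fit`s on identical data.
#' @param nested Optional list of 2-vectors `c(null, alt)` of fit names
#'   declaring nestings; a likelihood-ratio test is reported for each.
#' @return Data frame sorted by AIC (ties broken by fewer parameters),
#'   with a `"lrt"` attribute holding the nested-test table.
#' @export
compare_variants <- function(fits, nested = NULL) {
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, `[[`, "", "model_name")
  }
  fp <- lapply(fits, `[[`, "fingerprint")
  for (i in seq_along(fp)[-1]) {
    if (!isTRUE(all.equal(fp[[1]], fp[[i]]))) {
      stop("fits were made on different data", call. = FALSE)
    }
  }
  tab <- data.frame(
    model = names(fits),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    n_params = as.integer(vapply(fits, function(f) as.numeric(f$n_params),
                                 0)),
    aic = vapply(fits, `[[`, 0, "aic"),
    converged = vapply(fits, `[[`, TRUE, "converged"))
  tab <- tab[order(tab$aic, tab$n_params), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  if (!is.null(nested)) {
    lt <- do.call(rbind, lapply(nested, function(nn) {
      r <- lrt(fits[[nn[1]]], fits[[nn[2]]])
      data.frame(null = nn[1], alt = nn[2], statistic = r$statistic,
                 df = r$df, p_value = r$p_value)
    }))
    attr(tab, "lrt") <- lt
  }
  tab
}

#' Variance-proportion curves by age and pair group
#'
#' For each pair group and age, the proportion of (unit study) variance
#' attributed to additive genetic (A) and shared environmental (C)
#' factors from the pairwise covariance contribution at that age; the
#' individual-specific environmental share is E = 1 - A - C. Shares
#' outside [0, 1] are clamped and flagged.
#'
#' @param fit A fit from [fit_variance_model()].
#' @param ages Age grid (years).
#' @param adult_age,marriage_age Cohabitation-clock conventions.
#' @return Data frame with columns `group`, `age`, `A`, `C`, `E`,
#'   `clamped`; the inverse-variance-weighted mean of the fitted study
#'   variances is attached as attribute `"reference_variance"`.
#' @export
variance_proportion_curves <- function(fit, ages = 0:90, adult_age = 18,
                                       marriage_age = 24) {
  variant <- fit$model$variant
  est <- fit$estimates
  gv <- function(n) if (n %in% names(est)) unname(est[n]) else 0
  groups <- c("MZ", "DZSIB", "PO", "SPOUSE")
  k2 <- c(MZ = 1, DZSIB = 0.5, PO = 0.5, SPOUSE = 0)
  out <- do.call(rbind, lapply(groups, function(g) {
    if (g == "SPOUSE") {
      t <- pmax(0, ages - marriage_age); t0 <- Inf
    } else {
      t <- ages; t0 <- adult_age
    }
    A <- C <- rep(0, length(ages))
    if (variant == "AE") A <- rep(k2[[g]] * gv("sigmaA2"), length(ages))
    if (variant == "COHAB_AE") {
      A <- k2[[g]] * .kern(t, t0, gv("lambdaA"), gv("nuA"))
    }
    if (variant == "COHAB_ACE") {
      A <- k2[[g]] * .kern(t, t0, gv("lambdaA"), gv("nuA"))
      C <- .kern(t, t0, gv("lambdaC"), gv("nuC"))
    }
    if (variant %in% c("COHAB_CE", "COHAB_CE_PLUS_A")) {
      bC <- switch(g, MZ = gv("bC_MZ"), PO = gv("bC_PO"), 1)
      C <- bC * .kern(t, t0, gv("lambdaC"), gv("nuC"))
      if (variant == "COHAB_CE_PLUS_A") {
        A <- rep(k2[[g]] * gv("sigmaA2"), length(ages))
      }
    }
    E <- 1 - A - C
    clamped <- A < 0 | A > 1 | C < 0 | C > 1 | E < 0 | E > 1
    data.frame(group = g, age = ages,
               A = pmin(1, pmax(0, A)), C = pmin(1, pmax(0, C)),
               E = pmin(1, pmax(0, E)), clamped = clamped)
  }))
  vs <- fit$estimates[grep("^var_", names(fit$estimates))]
  se <- fit$se[grep("^var_", names(fit$se))]
  w <- ifelse(is.na(se) | se <= 0, 1, 1 / se^2)
  attr(out, "reference_variance") <- sum(w * vs) / sum(w)
  out
}

#' Count non-positive-definite family covariance matrices at a fit
#'
#' Re-assembles every family covariance matrix from the fitted parameters
#' and counts Cholesky failures. At a valid optimum this must be zero.
#'
#' @param md Data from [make_model_data()].
#' @param fit The corresponding `epicohab_fit`.
#' @return Integer count of non-PD family blocks.
#' @export
psd_violations <- function(md, fit) {
  model <- fit$model
  kp <- fit$estimates[model$kpar$name]
  v <- fit$estimates[paste0("var_", md$studies)]
  rho <- model$kval(md$pd, kp)
  sdm <- sqrt(v[md$member_study])
  cc <- rho * sdm[md$pd$i] * sdm[md$pd$j]
  bad <- 0L
  for (p in md$pair_simple) {
    i <- md$pd$i[p]; j <- md$pd$j[p]
    if (v[md$member_study[i]] * v[md$member_study[j]] - cc[p]^2 <= 0) {
      bad <- bad + 1L
    }
  }
  for (bf in md$big) {
    m <- length(bf$mem)
    S <- diag(v[md$member_study[bf$mem]], m)
    S[cbind(bf$a, bf$b)] <- cc[bf$pr]
    S[cbind(bf$b, bf$a)] <- cc[bf$pr]
    if (is.null(tryCatch(chol(S), error = function(e) NULL))) bad <- bad + 1L
  }
  bad
}
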