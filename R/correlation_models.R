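## Familial correlation models: the cohabitation-dependent correlation
## kernel, within-study pair-type correlations (Table-2-style output) and
## the pooled lifespan correlation model.

#' Cohabitation-dependent familial correlation kernel
#'
#' The correlation between two relatives with cohabitation clock
#' `(t, t0)` is `theta - exp(-lambda * t)` while cohabiting (`t <= t0`)
#' and `(theta - exp(-lambda * t0)) * exp(-nu * (t - t0))` after
#' separation. The correlation when the pair starts living together
#' (`t = 0`) is `theta - 1`; `lambda` and `nu` are the rates (per year) at
#' which the correlation rises with time together and decays with time
#' apart. The kernel is continuous at `t = t0`.
#'
#' @param t,t0 Cohabitation clock, years (vectorized).
#' @param theta Offset parameter in `[0, 2]`.
#' @param lambda,nu Non-negative rates per year.
#' @return Correlation values (not clamped; clamping is a reporting
#'   concern only).
#' @examples
#' rho_cohab(18, 18, theta = 1, lambda = 0.041, nu = 0.005)
#' @export
rho_cohab <- function(t, t0, theta, lambda, nu) {
  ifelse(t <= t0,
         theta - exp(-lambda * t),
         (theta - exp(-lambda * t0)) * exp(-nu * (t - t0)))
}

#' Default pair-type grouping for pooled models
#'
#' MZ alone, DZ merged with full siblings, parent--offspring, spouses.
#' @return Named list mapping group labels to relationship types.
#' @export
default_pair_groups <- function() {
  list(MZ = "MZ", DZSIB = c("DZ", "SIB"), PO = "PO", SPOUSE = "SPOUSE")
}

# clamped chi-square p for internal nested comparisons on tiny studies:
# a free fit that lands fractionally below its null (flat small-sample
# surfaces) yields statistic 0 rather than an error
.p_lrt <- function(ll0, ll1, df) {
  stat <- 2 * (ll1 - ll0)
  if (stat < -0.5) {
    warning("free model converged below its null; p-value set conservatively",
            call. = FALSE)
  }
  stats::pchisq(max(0, stat), df, lower.tail = FALSE)
}

.group_lookup <- function(groups) {
  lk <- character()
  for (g in names(groups)) lk[groups[[g]]] <- g
  lk
}

## ---- model constructors ----------------------------------------------------

#' Free correlation-per-group model for within-study estimation
#'
#' One free correlation per pair group, with optional groups fixed at
#' given values (used for the rho = 0 null in tests against zero).
#'
#' @param groups Named list mapping group labels to relationship types.
#' @param fixed Named numeric vector of groups whose correlation is fixed.
#' @param init Starting correlation for free groups.
#' @return Model object for [ml_fit()].
#' @export
pair_correlation_model <- function(groups, fixed = numeric(), init = 0.2) {
  lk <- .group_lookup(groups)
  free <- setdiff(names(groups), names(fixed))
  kpar <- data.frame(name = if (length(free)) paste0("rho_", free)
                     else character(0),
                     transform = rep("tanh", length(free)),
                     init = rep(init, length(free)),
                     stringsAsFactors = FALSE)
  list(
    name = paste0("pair_corr[", paste(names(groups), collapse = ","), "]"),
    kpar = kpar,
    groups = groups,
    kval = function(pd, kp) {
      g <- lk[pd$relationship]
      val <- numeric(nrow(pd))
      for (f in free) val[g == f] <- kp[[paste0("rho_", f)]]
      for (f in names(fixed)) val[g == f] <- fixed[[f]]
      val
    },
    kgrad = function(pd, kp) {
      g <- lk[pd$relationship]
      out <- matrix(0, nrow(pd), nrow(kpar))
      for (k in seq_along(free)) out[g == free[k], k] <- 1
      out
    }
  )
}

#' Lifespan cohabitation-dependent correlation model
#'
#' Pooled model over all pairs: per-group offset `theta` (fixed at 1 or
#' free on `[0, 2]`), per-group or shared rise rate `lambda`, shared or
#' per-group decay rate `nu`.
#'
#' @param groups Named list mapping group labels to relationship types.
#' @param theta `"one"` (fixed at 1, the final-model convention) or
#'   `"free"`.
#' @param lambda `"per_group"` or `"shared"`.
#' @param nu `"shared"` or `"per_group"`.
#' @param init Named list of starting values (`theta`, `lambda`, `nu`).
#' @return Model object for [ml_fit()].
#' @export
lifespan_correlation_model <- function(groups = default_pair_groups(),
                                       theta = c("one", "free"),
                                       lambda = c("per_group", "shared"),
                                       nu = c("shared", "per_group"),
                                       init = list(theta = 1, lambda = 0.02,
                                                   nu = 0.01)) {
  theta <- match.arg(theta)
  lambda <- match.arg(lambda)
  nu <- match.arg(nu)
  lk <- .group_lookup(groups)
  gn <- names(groups)

  nm <- character(); tr <- character(); iv <- numeric()
  if (theta == "free") {
    nm <- c(nm, paste0("theta_", gn))
    tr <- c(tr, rep("logit02", length(gn)))
    iv <- c(iv, rep(init$theta, length(gn)))
  }
  lam_names <- if (lambda == "per_group") paste0("lambda_", gn) else "lambda"
  nm <- c(nm, lam_names); tr <- c(tr, rep("log", length(lam_names)))
  iv <- c(iv, rep(init$lambda, length(lam_names)))
  nu_names <- if (nu == "per_group") paste0("nu_", gn) else "nu"
  nm <- c(nm, nu_names); tr <- c(tr, rep("log", length(nu_names)))
  iv <- c(iv, rep(init$nu, length(nu_names)))

  kpar <- data.frame(name = nm, transform = tr, init = iv,
                     stringsAsFactors = FALSE)

  par_of <- function(kp, pd) {
    g <- lk[pd$relationship]
    th <- if (theta == "free") unname(kp[paste0("theta_", g)]) else
      rep(1, nrow(pd))
    la <- if (lambda == "per_group") unname(kp[paste0("lambda_", g)]) else
      rep(kp[["lambda"]], nrow(pd))
    nuv <- if (nu == "per_group") unname(kp[paste0("nu_", g)]) else
      rep(kp[["nu"]], nrow(pd))
    list(g = g, th = th, la = la, nu = nuv)
  }

  list(
    name = sprintf("lifespan_corr[theta=%s,lambda=%s,nu=%s]",
                   theta, lambda, nu),
    kpar = kpar, groups = groups,
    theta_mode = theta, lambda_mode = lambda, nu_mode = nu,
    kval = function(pd, kp) {
      p <- par_of(kp, pd)
      rho_cohab(pd$t, pd$t0, p$th, p$la, p$nu)
    },
    kgrad = function(pd, kp) {
      p <- par_of(kp, pd)
      coh <- pd$t <= pd$t0
      E <- ifelse(coh, 1, exp(-p$nu * (pd$t - pd$t0)))
      # d/dtheta, d/dlambda, d/dnu for each pair
      dth <- E
      dla <- ifelse(coh, pd$t * exp(-p$la * pd$t),
                    pd$t0 * exp(-p$la * pd$t0) * E)
      # separated spouses with finite t0 handled; t0 = Inf is always cohab
      dnu <- ifelse(coh, 0,
                    -(pd$t - pd$t0) * (p$th - exp(-p$la * pd$t0)) * E)
      out <- matrix(0, nrow(pd), nrow(kpar))
      colnames(out) <- kpar$name
      if (theta == "free") {
        for (g in gn) out[p$g == g, paste0("theta_", g)] <- dth[p$g == g]
      }
      if (lambda == "per_group") {
        for (g in gn) out[p$g == g, paste0("lambda_", g)] <- dla[p$g == g]
      } else out[, "lambda"] <- dla
      if (nu == "per_group") {
        for (g in gn) out[p$g == g, paste0("nu_", g)] <- dnu[p$g == g]
      } else out[, "nu"] <- dnu
      out
    }
  )
}

## ---- within-study correlations ---------------------------------------------

#' Within-study familial correlations by pair type
#'
#' For each study, estimates one correlation per relationship type (and a
#' pooled "MZ and DZ" twin correlation) by maximum likelihood under the
#' bivariate normal pair model with a free study variance. Confidence
#' intervals are Wald intervals on the atanh (Fisher z) scale; the p-value
#' against zero is a 1-df likelihood-ratio test; the MZ-versus-DZ p-value
#' compares a shared twin correlation against free ones.
#'
#' @param pheno Phenotype table with the analysis residual.
#' @param pairs Pairs table.
#' @param min_pairs Minimum pairs required to estimate a correlation
#'   (default 3); smaller groups are suppressed with a warning.
#' @param pool_mzdz Also report the pooled MZ+DZ twin correlation.
#' @param n_starts Optimizer starts per fit.
#' @param ... Passed to [make_model_data()].
#' @return Data frame with one row per study x pair type: `n_pairs`,
#'   `mean_age`, `rho`, `ci_lo`, `ci_hi`, `p`, `p_mz_vs_dz`, `boundary`.
#' @export
fit_pair_correlations <- function(pheno, pairs, min_pairs = 3,
                                  pool_mzdz = TRUE, n_starts = 3, ...) {
  out <- list()
  for (s in unique(pheno$study_id)) {
    ph <- pheno[pheno$study_id == s, , drop = FALSE]
    pr <- pairs[pairs$id_a %in% ph$individual_id &
                  pairs$id_b %in% ph$individual_id, , drop = FALSE]
    if (!nrow(pr)) next
    counts <- table(pr$relationship)
    types <- names(counts)[counts >= min_pairs]
    small <- names(counts)[counts < min_pairs]
    if (length(small)) {
      warning("study '", s, "': fewer than ", min_pairs, " pairs for ",
              paste(small, collapse = ", "), "; estimate suppressed",
              call. = FALSE)
    }
    if (!length(types)) next
    use <- pr$relationship %in% types
    md <- make_model_data(ph, pr[use, , drop = FALSE], ...)
    grp <- as.list(types); names(grp) <- types
    fit <- ml_fit(md, pair_correlation_model(grp), n_starts = n_starts)

    p_mzdz <- NA_real_
    if (all(c("MZ", "DZ") %in% types)) {
      tw <- pr$relationship %in% c("MZ", "DZ")
      mdt <- make_model_data(ph, pr[tw, , drop = FALSE], ...)
      f_free <- ml_fit(mdt, pair_correlation_model(list(MZ = "MZ", DZ = "DZ")),
                       n_starts = n_starts)
      f_shared <- ml_fit(mdt, pair_correlation_model(list(TWIN = c("MZ", "DZ"))),
                         n_starts = n_starts)
      p_mzdz <- .p_lrt(f_shared$loglik, f_free$loglik, 1)
    }

    for (ty in types) {
      pn <- paste0("rho_", ty)
      rho <- unname(fit$estimates[pn])
      fixed0 <- stats::setNames(0, ty)
      f0 <- ml_fit(md, pair_correlation_model(grp, fixed = fixed0),
                   n_starts = n_starts)
      pz <- .p_lrt(f0$loglik, fit$loglik, 1)
      prt <- pr[use & pr$relationship == ty, ]
      ma <- mean((ph$chronological_age[match(prt$id_a, ph$individual_id)] +
                    ph$chronological_age[match(prt$id_b, ph$individual_id)]) / 2)
      out[[length(out) + 1L]] <- data.frame(
        study_id = s, pair_type = ty, n_pairs = as.integer(counts[[ty]]),
        mean_age = ma,
        rho = max(-0.99, min(0.99, rho)),
        ci_lo = unname(fit$ci[pn, "lo"]), ci_hi = unname(fit$ci[pn, "hi"]),
        p = pz,
        p_mz_vs_dz = if (ty %in% c("MZ", "DZ")) p_mzdz else NA_real_,
        boundary = abs(rho) > 0.99)
    }

    if (pool_mzdz && all(c("MZ", "DZ") %in% types)) {
      tw <- pr$relationship %in% c("MZ", "DZ")
      mdt <- make_model_data(ph, pr[tw, , drop = FALSE], ...)
      fp <- ml_fit(mdt, pair_correlation_model(list(TWIN = c("MZ", "DZ"))),
                   n_starts = n_starts)
      f0 <- ml_fit(mdt, pair_correlation_model(list(TWIN = c("MZ", "DZ")),
                                               fixed = c(TWIN = 0)),
                   n_starts = 1)
      rho <- unname(fp$estimates["rho_TWIN"])
      prt <- pr[tw, ]
      ma <- mean((ph$chronological_age[match(prt$id_a, ph$individual_id)] +
                    ph$chronological_age[match(prt$id_b, ph$individual_id)]) / 2)
      out[[length(out) + 1L]] <- data.frame(
        study_id = s, pair_type = "MZ and DZ", n_pairs = sum(tw),
        mean_age = ma,
        rho = max(-0.99, min(0.99, rho)),
        ci_lo = unname(fp$ci["rho_TWIN", "lo"]),
        ci_hi = unname(fp$ci["rho_TWIN", "hi"]),
        p = .p_lrt(f0$loglik, fp$loglik, 1),
        p_mz_vs_dz = NA_real_,
        boundary = abs(rho) > 0.99)
    }
  }
  do.call(rbind, out)
}

#' Test equality of MZ and DZ correlations within a study
#'
#' 1-df likelihood-ratio test of a shared twin-pair correlation against
#' zygosity-specific correlations.
#'
#' @param pheno,pairs Study data (a single study's rows).
#' @param ... Passed to [make_model_data()].
#' @return List with `p_value`, `statistic`, `df`, or `NA` p-value if
#'   either zygosity group is absent.
#' @export
test_mz_vs_dz <- function(pheno, pairs, ...) {
  tw <- pairs[pairs$relationship %in% c("MZ", "DZ"), , drop = FALSE]
  if (!all(c("MZ", "DZ") %in% tw$relationship)) {
    return(list(p_value = NA_real_, statistic = NA_real_, df = 1L,
                note = "MZ or DZ pairs absent"))
  }
  md <- make_model_data(pheno, tw, ...)
  f_free <- ml_fit(md, pair_correlation_model(list(MZ = "MZ", DZ = "DZ")),
                   n_starts = 3)
  f_sh <- ml_fit(md, pair_correlation_model(list(TWIN = c("MZ", "DZ"))),
                 n_starts = 3)
  stat <- max(0, 2 * (f_free$loglik - f_sh$loglik))
  list(p_value = .p_lrt(f_sh$loglik, f_free$loglik, 1),
       statistic = stat, df = 1L)
}

## ---- lifespan model --------------------------------------------------------

#' Fit the pooled lifespan correlation model
#'
#' Joint maximum likelihood over all pairs (all studies pooled) with the
#' cohabitation-dependent correlation kernel and free per-study variances.
#' The model ladder of the analysis — theta free per group, theta fixed at
#' 1, group-specific versus shared rates, DZ and siblings merged — is
#' expressed through the `theta`, `lambda`, `nu` and `groups` arguments;
#' nested variants can be compared with [lrt()].
#'
#' @inheritParams lifespan_correlation_model
#' @param pheno,pairs Pooled data.
#' @param n_starts Number of optimizer starts.
#' @param hessian Compute standard errors (see [ml_fit()]).
#' @param ... Passed to [make_model_data()].
#' @return An `epicohab_fit`.
#' @export
fit_lifespan_model <- function(pheno, pairs, groups = default_pair_groups(),
                               theta = c("one", "free"),
                               lambda = c("per_group", "shared"),
                               nu = c("shared", "per_group"),
                               n_starts = 5, hessian = TRUE, ...) {
  theta <- match.arg(theta); lambda <- match.arg(lambda); nu <- match.arg(nu)
  present <- unique(pairs$relationship)
  groups <- groups[vapply(groups, function(g) any(g %in% present), logical(1))]
  if (length(groups) < 1) stop("no pair groups present in data", call. = FALSE)
  md <- make_model_data(pheno, pairs, ...)
  model <- lifespan_correlation_model(groups, theta = theta,
                                      lambda = lambda, nu = nu)
  ml_fit(md, model, n_starts = n_starts, hessian = hessian)
}

#' Predicted lifespan correlation curves from a fitted model
#'
#' @param fit Fit returned by [fit_lifespan_model()].
#' @param ages Ages (years) at which to evaluate `t` (with `t0` from the
#'   twin/parent-offspring convention `t0 = adult_age`; spouse curves use
#'   `t = age - marriage_age`, never separated).
#' @param adult_age,marriage_age Clock conventions.
#' @return Data frame of predicted correlations by group and age.
#' @export
predict_lifespan_rho <- function(fit, ages = 0:90, adult_age = 18,
                                 marriage_age = 24) {
  model <- fit$model
  est <- fit$estimates
  gn <- names(model$groups)
  out <- do.call(rbind, lapply(gn, function(g) {
    th <- if (model$theta_mode == "free") est[[paste0("theta_", g)]] else 1
    la <- if (model$lambda_mode == "per_group") est[[paste0("lambda_", g)]] else
      est[["lambda"]]
    nuv <- if (model$nu_mode == "per_group") est[[paste0("nu_", g)]] else
      est[["nu"]]
    if (g == "SPOUSE") {
      t <- pmax(0, ages - marriage_age); t0 <- Inf
    } else {
      t <- ages; t0 <- adult_age
    }
    data.frame(group = g, age = ages,
               rho = pmin(0.99, pmax(-0.99, rho_cohab(t, t0, th, la, nuv))))
  }))
  out
}
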