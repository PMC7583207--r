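## Multivariate-normal pedigree likelihood, constrained maximization,
## standard errors, AIC and likelihood-ratio tests.
##
## All familial models in this package share one engine. A model supplies a
## correlation-scale kernel k(pair) for the off-diagonal of each family
## covariance matrix; the engine assembles Sigma_f with diagonal sigma^2_s
## (free per-study variances) and off-diagonals k * sigma_i * sigma_j,
## evaluates the joint Gaussian log-likelihood with analytic gradients, and
## maximizes it by multi-start BFGS on a transformed (unconstrained) scale.

LOG2PI <- log(2 * pi)

## ---- parameter transforms --------------------------------------------------

.tr_to_nat <- function(par, tr) {
  switch(tr,
         log = exp(par),
         tanh = tanh(par),
         logit02 = 2 * stats::plogis(par),
         identity = par)
}
.tr_dnat <- function(nat, tr) {
  switch(tr,
         log = nat,
         tanh = 1 - nat^2,
         logit02 = nat * (1 - nat / 2),
         identity = rep(1, length(nat)))
}
.tr_from_nat <- function(nat, tr) {
  switch(tr,
         log = log(nat),
         tanh = atanh(pmin(pmax(nat, -0.999999), 0.999999)),
         logit02 = stats::qlogis(pmin(pmax(nat / 2, 1e-8), 1 - 1e-8)),
         identity = nat)
}

## ---- model data assembly ---------------------------------------------------

#' Assemble fitting data from phenotype and pairs tables
#'
#' Joins the pairs table to the phenotype table, computes the cohabitation
#' clock and doubled kinship for every pair, and partitions families into
#' singletons, simple pairs (vectorized likelihood path) and larger blocks
#' (general multivariate path). The response is the analysis residual.
#'
#' @param pheno Phenotype table carrying the response column.
#' @param pairs Pairs table (`family_id`, `id_a`, `id_b`, `relationship`,
#'   optional `offspring_member`, `separation_time`).
#' @param response Name of the response column; defaults to
#'   `analysis_residual`, falling back to `raw_acceleration`.
#' @param adult_age,marriage_age Cohabitation-clock conventions, see
#'   [cohabitation_clock()].
#' @return An object of class `epicohab_data`.
#' @export
make_model_data <- function(pheno, pairs, response = NULL,
                            adult_age = 18, marriage_age = 24) {
  if (is.null(response)) {
    response <- if ("analysis_residual" %in% names(pheno)) "analysis_residual"
    else if ("raw_acceleration" %in% names(pheno)) "raw_acceleration"
    else stop("no response column found; run age_acceleration()/",
              "adjust_covariates() or name one via 'response'", call. = FALSE)
  }
  y <- as.numeric(pheno[[response]])
  if (any(!is.finite(y))) stop("non-finite phenotype values", call. = FALSE)
  validate_pairs(pairs, pheno)

  studies <- sort(unique(as.character(pheno$study_id)))
  member_study <- match(as.character(pheno$study_id), studies)

  ia <- match(pairs$id_a, pheno$individual_id)
  ib <- match(pairs$id_b, pheno$individual_id)
  pd <- data.frame(i = ia, j = ib,
                   relationship = check_relationship(pairs$relationship),
                   age_a = pheno$chronological_age[ia],
                   age_b = pheno$chronological_age[ib],
                   stringsAsFactors = FALSE)
  pd$offspring_member <- if (!is.null(pairs$offspring_member))
    as.character(pairs$offspring_member) else NA_character_
  pd$separation_time <- if (!is.null(pairs$separation_time))
    as.numeric(pairs$separation_time) else NA_real_
  pd <- cohabitation_clock(pd, adult_age = adult_age,
                           marriage_age = marriage_age)
  pd$kinship2 <- kinship2(pd$relationship)
  pd$mean_age <- (pd$age_a + pd$age_b) / 2

  famkey <- paste(pheno$study_id, pheno$family_id, sep = "\r")
  fam_of_pair <- famkey[pd$i]
  memb_per_fam <- table(famkey)
  pairs_per_fam <- table(fam_of_pair)

  simple_fam <- names(memb_per_fam)[memb_per_fam == 2L]
  simple_fam <- simple_fam[simple_fam %in% names(pairs_per_fam) &
                             pairs_per_fam[simple_fam] == 1L]

  pair_simple <- fam_of_pair %in% simple_fam
  big_fams <- setdiff(unique(fam_of_pair), simple_fam)
  big <- lapply(big_fams, function(f) {
    mem <- which(famkey == f)
    pr <- which(fam_of_pair == f)
    a <- match(pd$i[pr], mem)
    b <- match(pd$j[pr], mem)
    m <- length(mem)
    # linear indices into the m x m family matrix for speed
    list(mem = mem, pr = pr, a = a, b = b, m = m,
         dg = seq.int(1L, m * m, m + 1L),
         lin_ab = (b - 1L) * m + a,
         lin_ba = (a - 1L) * m + b)
  })
  in_block <- unique(c(pd$i[pair_simple], pd$j[pair_simple],
                       unlist(lapply(big, `[[`, "mem"))))
  singles <- setdiff(seq_along(y), in_block)

  structure(list(
    y = y, member_study = member_study, studies = studies,
    pd = pd, pair_simple = which(pair_simple), big = big,
    singles = singles,
    n_individuals = length(y),
    n_families = length(unique(famkey)),
    fingerprint = c(n = length(y), sum = sum(y), ss = sum(y^2)),
    adult_age = adult_age, marriage_age = marriage_age
  ), class = "epicohab_data")
}

## ---- log-likelihood with gradient ------------------------------------------

#' Gaussian log-likelihood of one family block
#'
#' Evaluates the multivariate normal log density
#' \eqn{-\tfrac12\{m\log 2\pi + \log|\Sigma| + (y-\mu)^\top\Sigma^{-1}(y-\mu)\}}
#' for a single family. A covariance matrix that is not positive definite
#' yields `-Inf` (the optimizer rejects such points rather than erroring).
#'
#' @param y Numeric phenotype vector for the family members.
#' @param Sigma Family covariance matrix.
#' @param mu Mean vector (default 0; residual phenotypes are centred).
#' @return Log-likelihood value (scalar), `-Inf` if `Sigma` is not PD.
#' @export
family_loglik <- function(y, Sigma, mu = 0) {
  if (any(!is.finite(y))) stop("non-finite phenotype", call. = FALSE)
  Sigma <- as.matrix(Sigma)
  if (!isTRUE(all.equal(Sigma, t(Sigma), tolerance = 1e-8))) {
    stop("Sigma must be symmetric", call. = FALSE)
  }
  L <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  e <- y - mu
  u <- backsolve(L, forwardsolve(t(L), e))
  -0.5 * (length(y) * LOG2PI + 2 * sum(log(diag(L))) + sum(e * u))
}

# Joint negative log-likelihood and gradient over the whole dataset.
# par = c(transformed kernel params, log study variances).
# Returns list(value, grad); invalid parameter points get a large penalized
# value with a zero gradient so line searches back off.
.negll <- function(par, md, model, want_grad = TRUE) {
  nk <- nrow(model$kpar)
  ns <- length(md$studies)
  kp_t <- par[seq_len(nk)]
  lv <- par[nk + seq_len(ns)]
  if (any(!is.finite(par)) || any(lv > 50) || any(lv < -50)) {
    return(list(value = 1e10, grad = rep(0, length(par))))
  }
  v <- exp(lv)
  kp <- if (nk) mapply(.tr_to_nat, kp_t, model$kpar$transform) else numeric(0)
  names(kp) <- model$kpar$name

  rho <- model$kval(md$pd, kp)            # correlation-scale off-diagonals
  vm <- v[md$member_study]
  sdm <- sqrt(vm)
  cc <- rho * sdm[md$pd$i] * sdm[md$pd$j]  # covariance-scale

  ll <- 0
  dll_dv <- numeric(md$n_individuals)      # d ll / d v_member (diagonal)
  dll_dc <- numeric(nrow(md$pd))           # d ll / d c_pair (off-diagonal)

  ## singletons
  if (length(md$singles)) {
    i <- md$singles
    ll <- ll - 0.5 * sum(LOG2PI + log(vm[i]) + md$y[i]^2 / vm[i])
    dll_dv[i] <- 0.5 * (md$y[i]^2 / vm[i]^2 - 1 / vm[i])
  }

  ## two-member families, vectorized
  if (length(md$pair_simple)) {
    p <- md$pair_simple
    i <- md$pd$i[p]; j <- md$pd$j[p]
    v1 <- vm[i]; v2 <- vm[j]; cp <- cc[p]
    y1 <- md$y[i]; y2 <- md$y[j]
    D <- v1 * v2 - cp^2
    if (any(D <= 1e-12)) {
      pen <- sum(pmax(0, 1e-12 - D))
      return(list(value = 1e10 + 1e12 * pen, grad = rep(0, length(par))))
    }
    u1 <- (v2 * y1 - cp * y2) / D
    u2 <- (v1 * y2 - cp * y1) / D
    ll <- ll - 0.5 * sum(2 * LOG2PI + log(D) + y1 * u1 + y2 * u2)
    dll_dv[i] <- dll_dv[i] + 0.5 * (u1^2 - v2 / D)
    dll_dv[j] <- dll_dv[j] + 0.5 * (u2^2 - v1 / D)
    dll_dc[p] <- u1 * u2 + cp / D
  }

  ## larger families, looped
  for (bf in md$big) {
    m <- bf$m
    S <- matrix(0, m, m)
    S[bf$dg] <- vm[bf$mem]
    S[bf$lin_ab] <- cc[bf$pr]
    S[bf$lin_ba] <- cc[bf$pr]
    L <- tryCatch(chol.default(S), error = function(e) NULL)
    if (is.null(L)) {
      return(list(value = 1e10 + 1e6, grad = rep(0, length(par))))
    }
    yy <- md$y[bf$mem]
    u <- backsolve(L, backsolve(L, yy, transpose = TRUE))
    ll <- ll - 0.5 * (m * LOG2PI + 2 * sum(log(L[bf$dg])) + sum(yy * u))
    if (want_grad) {
      Sinv <- chol2inv(L)
      dll_dv[bf$mem] <- dll_dv[bf$mem] + 0.5 * (u^2 - Sinv[bf$dg])
      dll_dc[bf$pr] <- dll_dc[bf$pr] + u[bf$a] * u[bf$b] - Sinv[bf$lin_ab]
    }
  }

  if (!want_grad) return(list(value = -ll, grad = NULL))

  grad <- numeric(length(par))
  ## kernel parameters: chain rule through c = rho * sd_i * sd_j
  if (nk > 0) {
    kg <- model$kgrad(md$pd, kp)           # n_pairs x nk, d rho / d natural
    w <- dll_dc * sdm[md$pd$i] * sdm[md$pd$j]
    dnat <- mapply(.tr_dnat, kp, model$kpar$transform)
    grad[seq_len(nk)] <- as.numeric(crossprod(kg, w)) * dnat
  }
  ## log study variances: diagonal terms plus the sd factors in c
  gv_diag <- rowsum(dll_dv * vm, md$member_study,
                    reorder = TRUE)[, 1]
  gv <- numeric(ns); gv[sort(unique(md$member_study))] <- gv_diag
  half <- dll_dc * cc                       # d ll/d log v_s via c: c/2 per side
  if (length(half)) {
    add <- rowsum(c(half, half) / 2,
                  c(md$member_study[md$pd$i], md$member_study[md$pd$j]),
                  reorder = TRUE)[, 1]
    idx <- sort(unique(c(md$member_study[md$pd$i], md$member_study[md$pd$j])))
    gv[idx] <- gv[idx] + add
  }
  grad[nk + seq_len(ns)] <- gv
  list(value = -ll, grad = -grad)
}

## ---- maximization ----------------------------------------------------------

#' Maximize a familial model likelihood
#'
#' Multi-start BFGS on the transformed scale (log for variances and rates,
#' atanh for correlations, scaled logistic for the correlation-model
#' offset), with analytic gradients. Standard errors come from the
#' observed information (numerical Hessian of the transformed-scale
#' likelihood) mapped back by the delta method; confidence intervals are
#' Wald intervals on the transformed scale mapped through the transform.
#'
#' @param md Data assembled by [make_model_data()].
#' @param model A model object (see [lifespan_correlation_model()],
#'   [variance_model()], [pair_correlation_model()]).
#' @param n_starts Number of jittered starts (default 5; the first start
#'   is not jittered).
#' @param jitter SD of the normal jitter on the transformed scale.
#' @param level Confidence level for Wald intervals.
#' @param hessian Compute the observed-information standard errors
#'   (default `TRUE`); disable for bulk simulation fits that only need
#'   point estimates.
#' @return An object of class `epicohab_fit` with elements `loglik`,
#'   `n_params`, `estimates`, `se`, `ci`, `aic`, `converged`,
#'   `n_families`, `n_individuals`.
#' @export
ml_fit <- function(md, model, n_starts = 5, jitter = 0.4, level = 0.95,
                   hessian = TRUE) {
  stopifnot(inherits(md, "epicohab_data"))
  nk <- nrow(model$kpar)
  ns <- length(md$studies)
  sv0 <- vapply(seq_len(ns), function(s) {
    yy <- md$y[md$member_study == s]
    max(stats::var(yy), 1e-4)
  }, numeric(1))
  base <- c(if (nk) mapply(.tr_from_nat, model$kpar$init,
                           model$kpar$transform) else numeric(0),
            log(sv0))

  fn <- function(p) .negll(p, md, model, want_grad = FALSE)$value
  gr <- function(p) .negll(p, md, model, want_grad = TRUE)$grad

  best <- NULL
  n_starts <- max(1L, n_starts)
  for (s in seq_len(n_starts)) {
    p0 <- if (s == 1L) base else base + stats::rnorm(length(base), 0, jitter)
    o <- tryCatch(
      stats::optim(p0, fn, gr, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value) || o$value > 1e9) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    return(structure(list(model_name = model$name, loglik = NA_real_,
                          n_params = nk + ns, converged = FALSE,
                          estimates = NULL, se = NULL, ci = NULL,
                          aic = NA_real_, n_families = md$n_families,
                          n_individuals = md$n_individuals,
                          fingerprint = md$fingerprint),
                     class = "epicohab_fit"))
  }
  ## polish from the best point
  o <- stats::optim(best$par, fn, gr, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))
  if (o$value > best$value) o <- best
  par <- o$par
  ll <- -o$value
  g <- gr(par)
  grad_norm <- sqrt(sum(g^2))
  converged <- is.finite(ll) && grad_norm < 1e-4 * max(1, abs(ll))

  H <- if (hessian) {
    tryCatch(stats::optimHess(par, fn, gr), error = function(e) NULL)
  } else NULL
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se_t <- if (!is.null(V)) {
    d <- diag(V); d[d < 0] <- NA_real_; sqrt(d)
  } else rep(NA_real_, length(par))

  trans <- c(model$kpar$transform, rep("log", ns))
  nat <- mapply(.tr_to_nat, par, trans)
  names(nat) <- c(model$kpar$name, paste0("var_", md$studies))
  dnat <- mapply(.tr_dnat, nat, trans)
  se <- se_t * abs(dnat)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lo = mapply(.tr_to_nat, par - zq * se_t, trans),
              hi = mapply(.tr_to_nat, par + zq * se_t, trans))
  rownames(ci) <- names(nat)
  names(se) <- names(nat)

  structure(list(
    model_name = model$name,
    model = model,
    loglik = ll,
    n_params = length(par),
    estimates = nat,
    se = se,
    ci = ci,
    aic = -2 * ll + 2 * length(par),
    converged = converged,
    grad_norm = grad_norm,
    par = par,
    vcov_trans = V,
    transforms = trans,
    n_families = md$n_families,
    n_individuals = md$n_individuals,
    n_pairs = nrow(md$pd),
    fingerprint = md$fingerprint
  ), class = "epicohab_fit")
}

#' @export
print.epicohab_fit <- function(x, ...) {
  cat("Familial model fit:", x$model_name, "\n")
  cat(sprintf("  logLik %.4f  AIC %.4f  k %d  converged %s\n",
              x$loglik, x$aic, x$n_params, x$converged))
  cat(sprintf("  %d individuals, %d families, %d pairs\n",
              x$n_individuals, x$n_families, x$n_pairs))
  if (!is.null(x$estimates)) {
    est <- data.frame(estimate = x$estimates, se = x$se,
                      lo = x$ci[, "lo"], hi = x$ci[, "hi"])
    print(utils::head(est, 20), digits = 4)
    if (nrow(est) > 20) cat("  ... (", nrow(est) - 20, " more)\n", sep = "")
  }
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' @param fit An `epicohab_fit`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(model = fit$model_name, loglik = fit$loglik,
              n_params = fit$n_params, aic = fit$aic,
              converged = fit$converged,
              estimates = as.list(fit$estimates),
              se = as.list(fit$se),
              ci = apply(fit$ci, 1, as.list),
              n_families = fit$n_families,
              n_individuals = fit$n_individuals)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

## ---- model comparison ------------------------------------------------------

#' Likelihood-ratio test between nested fits
#'
#' @param fit_null,fit_alt Fits of nested models on the same data.
#' @param df Degrees of freedom; defaults to the difference in free
#'   parameter counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(fit_null, fit_alt, df = NULL) {
  if (is.null(df)) df <- fit_alt$n_params - fit_null$n_params
  if (df < 1) stop("df must be >= 1 (models not nested?)", call. = FALSE)
  if (!is.null(fit_null$fingerprint) && !is.null(fit_alt$fingerprint) &&
      !isTRUE(all.equal(fit_null$fingerprint, fit_alt$fingerprint))) {
    stop("fits were made on different data", call. = FALSE)
  }
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  # allow tiny optimizer-level deficits of the larger model; anything
  # bigger signals non-nested or unconverged fits
  tol <- max(0.05, 1e-6 * abs(fit_null$loglik))
  if (stat < -tol) {
    stop("alternative log-likelihood below null beyond tolerance; ",
         "fits non-nested or not converged", call. = FALSE)
  }
  stat <- max(0, stat)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
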