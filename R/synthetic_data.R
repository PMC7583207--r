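## Synthetic family cohorts with the covariance structure the analysis
## assumes: multiple studies with distinct residual variances, the five
## relationship types, and phenotypes drawn jointly per family from a
## multivariate normal whose off-diagonals follow a chosen
## cohabitation-dependent generating model.

## ---- age distributions -----------------------------------------------------

#' Age distribution specifications for cohort blocks
#'
#' @param x,lo,hi,mean,sd Distribution parameters in years.
#' @return A specification list consumed by the generator.
#' @name age_dists
NULL

#' @rdname age_dists
#' @export
age_fixed <- function(x) list(dist = "fixed", a = x)

#' @rdname age_dists
#' @export
age_unif <- function(lo, hi) list(dist = "uniform", a = lo, b = hi)

#' @rdname age_dists
#' @export
age_norm <- function(mean, sd, lo = 0, hi = 92) {
  list(dist = "normal", a = mean, b = sd, lo = lo, hi = hi)
}

.draw_age <- function(spec, n) {
  switch(spec$dist,
         fixed = rep(spec$a, n),
         uniform = stats::runif(n, spec$a, spec$b),
         normal = pmin(spec$hi, pmax(spec$lo,
                                     stats::rnorm(n, spec$a, spec$b))),
         stop("unknown age distribution: ", spec$dist, call. = FALSE))
}

## ---- block constructors ----------------------------------------------------

#' Cohort building blocks
#'
#' `pair_block()` describes `n` independent two-member families of one
#' relationship type; `family_block()` describes `n` households (two
#' parents plus `n_children` children, the first two of which may be
#' twins) or, with `parents = FALSE`, a sibship.
#'
#' @param study_id Study label.
#' @param relationship Pair relationship type (for `pair_block`).
#' @param n Number of families of this shape.
#' @param age Age specification (see [age_fixed()]) — for pairs the age of
#'   the (younger) member; for families the age of the youngest child.
#' @param variance Residual phenotype variance of the study (years^2).
#' @param age_gap Sibling age gap range, years (`SIB` pairs and extra
#'   children in families).
#' @param parent_offset Parent minus oldest-child age range, years.
#' @param separation Spouse separation time (`Inf` = never separated).
#' @param n_children,twins,parents Family composition (for
#'   `family_block`): number of children, `"MZ"`/`"DZ"`/`NULL` twins among
#'   them, and whether parents are present.
#' @return A block specification list.
#' @name cohort_blocks
NULL

#' @rdname cohort_blocks
#' @export
pair_block <- function(study_id, relationship, n, age, variance = 1,
                       age_gap = c(1, 6), parent_offset = c(22, 38),
                       separation = Inf) {
  list(kind = "pair", study_id = study_id,
       relationship = check_relationship(relationship), n = as.integer(n),
       age = age, variance = variance, age_gap = age_gap,
       parent_offset = parent_offset, separation = separation)
}

#' @rdname cohort_blocks
#' @export
family_block <- function(study_id, n, n_children = 2, twins = NULL,
                         age = age_unif(5, 18), variance = 1,
                         age_gap = c(1, 6), parent_offset = c(22, 38),
                         parents = TRUE) {
  if (!is.null(twins)) check_relationship(twins)
  list(kind = "family", study_id = study_id, n = as.integer(n),
       n_children = as.integer(n_children), twins = twins, age = age,
       variance = variance, age_gap = age_gap,
       parent_offset = parent_offset, parents = parents)
}

#' Assemble a cohort configuration
#'
#' @param blocks List of blocks from [pair_block()]/[family_block()].
#' @param model Generating model: either
#'   `list(kind = "correlation", theta, lambda, nu, groups)` with `lambda`
#'   (and optionally `theta`, `nu`) named per group, or
#'   `list(kind = "variance", variant, params)` with `params` naming the
#'   kernel parameters of [variance_model()].
#' @param sex_effect Years added to the DNAm age of males (removed later
#'   by the sex adjustment).
#' @param dnam_slope,dnam_intercept Linear map from chronological age to
#'   the systematic part of DNAm age; slope 1, intercept 0 makes the
#'   acceleration residual equal to the drawn family deviate.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(blocks, model, sex_effect = 0,
                          dnam_slope = 1, dnam_intercept = 0) {
  stopifnot(length(blocks) > 0, model$kind %in% c("correlation", "variance"))
  structure(list(blocks = blocks, model = model, sex_effect = sex_effect,
                 dnam_slope = dnam_slope, dnam_intercept = dnam_intercept),
            class = "cohort_config")
}

## ---- generating kernels ----------------------------------------------------

# correlation-scale off-diagonal for generated pairs under the config model
.gen_k <- function(pd, model) {
  if (model$kind == "correlation") {
    groups <- if (is.null(model$groups)) default_pair_groups() else model$groups
    lk <- .group_lookup(groups)
    g <- lk[pd$relationship]
    pick <- function(x, default = 0) {
      if (is.null(x)) rep(default, length(g))
      else if (length(x) == 1 && is.null(names(x))) rep(x, length(g))
      else unname(x[g])
    }
    th <- pick(model$theta, 1); if (is.null(model$theta)) th <- rep(1, length(g))
    la <- pick(model$lambda)
    nuv <- pick(model$nu)
    rho_cohab(pd$t, pd$t0, th, la, nuv)
  } else {
    p <- model$params
    g0 <- function(n) if (is.null(p[[n]])) 0 else p[[n]]
    variant <- model$variant
    betaA <- if (variant %in% c("COHAB_AE", "COHAB_ACE")) pd$kinship2 else 0
    betaC <- switch(variant,
                    AE = 0, COHAB_AE = 0,
                    COHAB_ACE = rep(1, nrow(pd)),
                    .bC_of(pd$relationship, g0("bC_MZ"), g0("bC_PO")))
    sigmaA2 <- if (variant %in% c("AE", "COHAB_CE_PLUS_A")) g0("sigmaA2") else 0
    cov_cohab(pd$t, pd$t0, pd$kinship2, sigmaA2 = sigmaA2,
              betaA = betaA, lambdaA = g0("lambdaA"), nuA = g0("nuA"),
              betaC = betaC, lambdaC = g0("lambdaC"), nuC = g0("nuC"))
  }
}

## ---- generation ------------------------------------------------------------

#' Generate a synthetic family cohort
#'
#' Draws a phenotype table and a pairs table under the configuration's
#' generating model. Per family, the correlation matrix is assembled from
#' the model kernel (unit diagonal), scaled by the study variance, and the
#' members' deviates are drawn jointly from the multivariate normal. DNAm
#' age is emitted as `intercept + slope * age + sex_effect * male +
#' deviate`, so the age-acceleration pipeline recovers the deviates.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (mandatory; same seed, same cohort).
#' @return List with `phenotypes`, `pairs` and a `truth` manifest
#'   recording every generating parameter.
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"), !missing(seed))
  set.seed(as.integer(seed))
  ph_list <- list(); pr_list <- list()
  fam_counter <- 0L

  for (blk in config$blocks) {
    if (blk$n <= 0L) next
    if (blk$kind == "pair") {
      gen <- .gen_pair_block(blk, config, fam_counter)
    } else {
      gen <- .gen_family_block(blk, config, fam_counter)
    }
    fam_counter <- fam_counter + blk$n
    ph_list[[length(ph_list) + 1L]] <- gen$pheno
    pr_list[[length(pr_list) + 1L]] <- gen$pairs
  }
  pheno <- do.call(rbind, ph_list)
  pairs <- do.call(rbind, pr_list)
  rownames(pheno) <- rownames(pairs) <- NULL
  truth <- list(seed = as.integer(seed), model = config$model,
                sex_effect = config$sex_effect,
                dnam_slope = config$dnam_slope,
                dnam_intercept = config$dnam_intercept,
                study_variances = stats::setNames(
                  vapply(config$blocks, `[[`, 0, "variance"),
                  vapply(config$blocks, `[[`, "", "study_id")),
                n_individuals = nrow(pheno), n_pairs = nrow(pairs))
  list(phenotypes = pheno, pairs = pairs, truth = truth)
}

.emit_dnam <- function(age, sex, dev, config) {
  config$dnam_intercept + config$dnam_slope * age +
    config$sex_effect * (sex == "male") + dev
}

.gen_pair_block <- function(blk, config, fam0) {
  n <- blk$n
  rel <- blk$relationship
  a1 <- .draw_age(blk$age, n)
  if (rel %in% c("MZ", "DZ")) {
    a2 <- a1
  } else if (rel == "SIB") {
    a2 <- a1 + stats::runif(n, blk$age_gap[1], blk$age_gap[2])
  } else if (rel == "PO") {
    a2 <- a1 + stats::runif(n, blk$parent_offset[1], blk$parent_offset[2])
  } else { # SPOUSE: partner age a few years apart, floored at 0
    a2 <- pmax(0, a1 + stats::runif(n, -3, 3))
  }
  sep <- if (rel == "SPOUSE" && is.finite(blk$separation)) blk$separation
  else NA_real_
  pd <- data.frame(relationship = rel, age_a = a1, age_b = a2,
                   offspring_member = if (rel == "PO") "a" else NA_character_,
                   separation_time = sep)
  pd <- cohabitation_clock(pd)
  pd$kinship2 <- kinship2(pd$relationship)
  k <- .gen_k(pd, config$model)
  if (any(abs(k) >= 1)) {
    stop("generating model implies |correlation| >= 1 (max ",
         signif(max(abs(k)), 4), ") for block ", blk$study_id, "/", rel,
         "; offending kernel parameters too large", call. = FALSE)
  }
  z1 <- stats::rnorm(n)
  z2 <- k * z1 + sqrt(1 - k^2) * stats::rnorm(n)
  s <- sqrt(blk$variance)
  fam <- sprintf("%s_f%05d", blk$study_id, fam0 + seq_len(n))
  id_a <- paste0(fam, "_1"); id_b <- paste0(fam, "_2")
  if (rel == "MZ") {
    sx1 <- sx2 <- sample(c("female", "male"), n, replace = TRUE)
  } else if (rel == "SPOUSE") {
    sx1 <- rep("female", n); sx2 <- rep("male", n)
  } else {
    sx1 <- sample(c("female", "male"), n, replace = TRUE)
    sx2 <- sample(c("female", "male"), n, replace = TRUE)
  }
  role <- switch(rel, MZ = c("twin", "twin"), DZ = c("twin", "twin"),
                 SIB = c("sibling", "sibling"),
                 PO = c("offspring", "parent"),
                 SPOUSE = c("spouse", "spouse"))
  pheno <- data.frame(
    study_id = blk$study_id,
    family_id = rep(fam, 2),
    individual_id = c(id_a, id_b),
    sex = c(sx1, sx2),
    chronological_age = c(a1, a2),
    dnam_age = c(.emit_dnam(a1, sx1, s * z1, config),
                 .emit_dnam(a2, sx2, s * z2, config)),
    tissue = NA_character_,
    role = rep(role, each = n))
  pairs <- data.frame(
    family_id = fam, id_a = id_a, id_b = id_b, relationship = rel,
    offspring_member = if (rel == "PO") "a" else NA_character_,
    separation_time = if (rel == "SPOUSE" && is.finite(blk$separation))
      blk$separation else NA_real_)
  list(pheno = pheno, pairs = pairs)
}

.gen_family_block <- function(blk, config, fam0) {
  ph <- list(); pr <- list()
  for (f in seq_len(blk$n)) {
    fam <- sprintf("%s_f%05d", blk$study_id, fam0 + f)
    nk <- blk$n_children
    ages <- numeric(nk)
    ages[1] <- .draw_age(blk$age, 1)
    if (nk >= 2) {
      for (ci in 2:nk) {
        gap <- if (!is.null(blk$twins) && ci == 2) 0 else
          stats::runif(1, blk$age_gap[1], blk$age_gap[2])
        ages[ci] <- ages[ci - 1] + gap
      }
    }
    roles <- rep("sibling", nk)
    sexes <- sample(c("female", "male"), nk, replace = TRUE)
    if (!is.null(blk$twins)) {
      roles[1:2] <- "twin"
      if (blk$twins == "MZ") sexes[2] <- sexes[1]
    }
    members <- data.frame(
      id = paste0(fam, "_c", seq_len(nk)), sex = sexes, age = ages,
      role = roles, stringsAsFactors = FALSE)
    rels <- list()
    for (i in seq_len(nk - 1)) for (j in (i + 1):nk) {
      rel <- if (!is.null(blk$twins) && i == 1 && j == 2) blk$twins else "SIB"
      rels[[length(rels) + 1L]] <- data.frame(a = i, b = j,
                                              relationship = rel,
                                              offspring_member = NA_character_)
    }
    if (isTRUE(blk$parents)) {
      poff <- stats::runif(2, blk$parent_offset[1], blk$parent_offset[2])
      pidx <- nk + 1:2
      members <- rbind(members, data.frame(
        id = paste0(fam, c("_m", "_d")), sex = c("female", "male"),
        age = max(ages) + poff, role = "parent"))
      for (p in pidx) for (ci in seq_len(nk)) {
        rels[[length(rels) + 1L]] <- data.frame(a = ci, b = p,
                                                relationship = "PO",
                                                offspring_member = "a")
      }
      rels[[length(rels) + 1L]] <- data.frame(a = pidx[1], b = pidx[2],
                                              relationship = "SPOUSE",
                                              offspring_member = NA_character_)
    }
    rels <- do.call(rbind, rels)
    pd <- data.frame(relationship = rels$relationship,
                     age_a = members$age[rels$a], age_b = members$age[rels$b],
                     offspring_member = rels$offspring_member,
                     separation_time = NA_real_)
    pd <- cohabitation_clock(pd)
    pd$kinship2 <- kinship2(pd$relationship)
    k <- .gen_k(pd, config$model)
    m <- nrow(members)
    R <- diag(m)
    R[cbind(rels$a, rels$b)] <- k
    R[cbind(rels$b, rels$a)] <- k
    L <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(L)) {
      stop("family template in block ", blk$study_id,
           " yields a non-positive-definite correlation matrix; ",
           "kernel multipliers too large for a ", m, "-member family",
           call. = FALSE)
    }
    dev <- sqrt(blk$variance) * as.numeric(crossprod(L, stats::rnorm(m)))
    ph[[f]] <- data.frame(
      study_id = blk$study_id, family_id = fam, individual_id = members$id,
      sex = members$sex, chronological_age = members$age,
      dnam_age = .emit_dnam(members$age, members$sex, dev, config),
      tissue = NA_character_, role = members$role)
    pr[[f]] <- data.frame(
      family_id = fam, id_a = members$id[rels$a], id_b = members$id[rels$b],
      relationship = rels$relationship,
      offspring_member = rels$offspring_member,
      separation_time = NA_real_)
  }
  list(pheno = do.call(rbind, ph), pairs = do.call(rbind, pr))
}

## ---- ready-made configurations ---------------------------------------------

#' Balanced pair-cohort configuration for recovery experiments
#'
#' One synthetic study of independent relative pairs with unit residual
#' variance and ages spread across the lifespan; the workhorse design of
#' the simulation experiments.
#'
#' @param n_per_type Named integer vector of pair counts
#'   (names among MZ, DZ, SIB, PO, SPOUSE).
#' @param model Generating model (see [cohort_config()]).
#' @param age Age specification (default uniform 0--90).
#' @param variance Study residual variance.
#' @param sex_effect Planted sex effect in years.
#' @param study_id Study label.
#' @return A `cohort_config`.
#' @export
pairs_cohort_config <- function(n_per_type, model, age = age_unif(0, 90),
                                variance = 1, sex_effect = 1,
                                study_id = "sim") {
  blocks <- lapply(names(n_per_type), function(r) {
    pair_block(study_id, r, n_per_type[[r]], age, variance = variance)
  })
  cohort_config(blocks, model, sex_effect = sex_effect)
}

#' Configuration mirroring the pooled ten-study design
#'
#' Reproduces the composition of the pooled cohort the analysis targets:
#' newborn and infant twin studies, an adolescent family study with
#' parents and siblings, a large 18-year-old twin study, adult and
#' elderly twin studies, sister/sibling studies, and a spouse study —
#' with block sizes, age distributions and residual variances modelled on
#' the published per-study descriptives. At `scale = 1` the cohort holds
#' 4217 individuals; block counts scale as `ceiling(scale * n)`.
#'
#' @param scale Positive multiplier on every block count.
#' @param model Generating model; defaults to the cohabitation-dependent
#'   CE model at its published point estimates (see [ce_truth()]).
#' @param sex_effect Planted sex effect in years (default 1).
#' @return A `cohort_config`.
#' @export
paper_like_cohort <- function(scale = 1, model = NULL, sex_effect = 1) {
  stopifnot(scale > 0)
  if (is.null(model)) model <- ce_truth()
  n <- function(x) as.integer(ceiling(scale * x))
  adol <- age_norm(13.8, 1.9); adol2 <- age_norm(13.2, 2.0)
  b <- list(
    pair_block("PETS_EPIC", "MZ", n(23), age_fixed(0), 0.16),
    pair_block("PETS_EPIC", "DZ", n(22), age_fixed(0), 0.16),
    pair_block("PETS_27K", "MZ", n(22), age_fixed(0), 0.06),
    pair_block("PETS_27K", "DZ", n(11), age_fixed(0), 0.06),
    pair_block("PETS_450K_birth", "MZ", n(9), age_fixed(0), 0.09),
    pair_block("PETS_450K_birth", "DZ", n(5), age_fixed(0), 0.09),
    pair_block("PETS_450K_18m", "MZ", n(6), age_fixed(1.5), 0.25),
    pair_block("PETS_450K_18m", "DZ", n(4), age_fixed(1.5), 0.25),
    family_block("BSGS", n(37), n_children = 3, twins = "MZ", age = adol,
                 variance = 7.3, parent_offset = c(24, 36)),
    family_block("BSGS", n(22), n_children = 3, twins = "DZ", age = adol2,
                 variance = 7.3, parent_offset = c(24, 36)),
    pair_block("BSGS", "MZ", n(30), adol, 7.3),
    pair_block("BSGS", "DZ", n(89), adol2, 7.3),
    pair_block("BSGS", "SIB", n(39), age_norm(13, 2.5), 7.3,
               age_gap = c(1, 5)),
    family_block("BSGS", n(1), n_children = 3, age = age_norm(13, 2.5),
                 variance = 7.3, parents = FALSE),
    pair_block("E_Risk", "MZ", n(426), age_fixed(18), 14.8),
    pair_block("E_Risk", "DZ", n(306), age_fixed(18), 14.8),
    pair_block("DTR_younger", "MZ", n(73), age_norm(33.1, 2.0), 18.6),
    pair_block("AMDTSS", "MZ", n(66), age_norm(55.6, 8.4), 23.0),
    pair_block("AMDTSS", "DZ", n(66), age_norm(57.0, 7.2), 23.0),
    pair_block("AMDTSS", "SIB", n(106), age_norm(54, 8), 23.0,
               age_gap = c(1, 8)),
    family_block("AMDTSS", n(1), n_children = 3, age = age_norm(54, 8),
                 variance = 23.0, parents = FALSE),
    pair_block("TwinsUK", "MZ", n(33), age_norm(58.4, 9.1), 21.0),
    pair_block("TwinsUK", "DZ", n(43), age_norm(56.6, 7.7), 21.0),
    pair_block("MuTHER", "MZ", n(93), age_norm(61.0, 9.3), 13.0),
    pair_block("MuTHER", "DZ", n(153), age_norm(57.4, 9.3), 13.0),
    pair_block("DTR_older", "MZ", n(77), age_norm(63.2, 4.1), 31.7),
    pair_block("OATS", "MZ", n(108), age_norm(71.2, 6.0), 28.7),
    pair_block("LSADT_1997", "MZ", n(18), age_norm(76.3, 2.0), 22.0),
    pair_block("LSADT_1997", "DZ", n(25), age_norm(76.2, 1.6), 22.0),
    pair_block("LSADT_2007", "MZ", n(18), age_norm(86.2, 2.0), 26.7),
    pair_block("LSADT_2007", "DZ", n(25), age_norm(86.1, 1.6), 26.7),
    pair_block("MCCS", "SPOUSE", n(62), age_norm(60.1, 6.2), 38.3))
  cohort_config(b, model, sex_effect = sex_effect)
}

## ---- published point estimates as generating truths ------------------------

#' Generating-model truths used by the recovery experiments
#'
#' Point estimates of the final fitted models, used as generating values
#' for the simulation round-trips: the theta = 1 lifespan correlation
#' model with group-specific rise rates and a shared decay rate
#' (`correlation_truth()`); the cohabitation-dependent CE covariance
#' model with its shared-environment multipliers (`ce_truth()`); the AE
#' model at 52% heritability (`ae_truth()`); and the CE model plus a
#' constant genetic component explaining 13% of variance
#' (`ce_plus_a_truth()`). Decay rates and the shared-environment rise
#' rate are not printed as point estimates in the source tables; the
#' values here (`lambdaC = 0.03`, `nu = nuC = 0.005`) are the package's
#' chosen plausible values consistent with the reported lifespan curves.
#'
#' @return A generating-model list for [cohort_config()].
#' @name truths
NULL

#' @rdname truths
#' @export
correlation_truth <- function() {
  list(kind = "correlation",
       theta = c(MZ = 1, DZSIB = 1, PO = 1, SPOUSE = 1),
       lambda = c(MZ = 0.041, DZSIB = 0.026, PO = 0.011, SPOUSE = 0.011),
       nu = c(MZ = 0.005, DZSIB = 0.005, PO = 0.005, SPOUSE = 0.005),
       groups = default_pair_groups())
}

#' @rdname truths
#' @export
ce_truth <- function() {
  list(kind = "variance", variant = "COHAB_CE",
       params = list(bC_MZ = 1.41, bC_PO = 1 / 2.03,
                     lambdaC = 0.03, nuC = 0.005))
}

#' @rdname truths
#' @export
ae_truth <- function() {
  list(kind = "variance", variant = "AE", params = list(sigmaA2 = 0.52))
}

#' @rdname truths
#' @export
ce_plus_a_truth <- function() {
  list(kind = "variance", variant = "COHAB_CE_PLUS_A",
       params = list(sigmaA2 = 0.13, bC_MZ = 1.41, bC_PO = 1 / 2.03,
                     lambdaC = 0.03, nuC = 0.005))
}
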