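## Epigenetic age acceleration: residualization and descriptives.

#' Compute epigenetic age acceleration residuals
#'
#' Epigenetic age acceleration is the residual from an ordinary
#' least-squares regression of DNAm age on chronological age, computed
#' separately within strata (by default one stratum per study; datasets
#' with longitudinal waves or generations should map each to its own
#' stratum). Strata in which chronological age is (nearly) constant fall
#' back to an intercept-only model (simple centering) with a warning.
#'
#' @param pheno Phenotype table (see [validate_phenotypes()]).
#' @param strata Optional character vector naming the columns that define
#'   regression strata; default `"study_id"`. A column `stratum` may also
#'   be supplied directly.
#' @return `pheno` with columns `stratum_id` and `raw_acceleration`
#'   (years) appended.
#' @examples
#' ph <- data.frame(study_id = "s", family_id = 1:6, individual_id = 1:6,
#'                  sex = "female", chronological_age = c(0, 10, 20, 30, 40, 50),
#'                  dnam_age = c(2, 11, 24, 28, 44, 49))
#' head(age_acceleration(ph)$raw_acceleration)
#' @export
age_acceleration <- function(pheno, strata = "study_id") {
  validate_phenotypes(pheno)
  stratum <- interaction(pheno[strata], drop = TRUE, sep = ":")
  res <- numeric(nrow(pheno))
  for (s in levels(stratum)) {
    i <- which(stratum == s)
    age <- pheno$chronological_age[i]
    y <- pheno$dnam_age[i]
    if (length(i) < 2L || stats::sd(age) < 1e-10) {
      if (stats::sd(age) < 1e-10 && length(i) >= 2L) {
        warning("stratum '", s, "' has a single age value; ",
                "intercept-only residuals used", call. = FALSE)
      }
      res[i] <- y - mean(y)
    } else {
      res[i] <- stats::lm.fit(cbind(1, age), y)$residuals
    }
  }
  pheno$stratum_id <- as.character(stratum)
  pheno$raw_acceleration <- res
  pheno
}

#' Average per-tissue standardized DNAm age across tissues
#'
#' For cohorts measured in several biological samples per person, DNAm age
#' is first standardized (zero mean, unit variance, sample n-1 convention)
#' within each tissue and the per-individual mean of the available
#' standardized values is used as the DNAm-age phenotype.
#'
#' @param pheno Phenotype table in long form: one row per individual x
#'   tissue, with a non-missing `tissue` column. Other columns
#'   (ages, sex, ids) must agree across an individual's rows.
#' @return Phenotype table with one row per individual; `dnam_age` holds
#'   the averaged standardized value and `tissue` records the number of
#'   tissues averaged.
#' @export
standardize_multitissue <- function(pheno) {
  stopifnot("tissue" %in% names(pheno), !any(is.na(pheno$tissue)))
  z <- numeric(nrow(pheno))
  for (tis in unique(pheno$tissue)) {
    i <- which(pheno$tissue == tis)
    if (length(i) < 2L) {
      stop("tissue '", tis, "' has fewer than 2 individuals", call. = FALSE)
    }
    s <- stats::sd(pheno$dnam_age[i])
    if (s < 1e-12) {
      stop("tissue '", tis, "' has zero DNAm-age variance; cannot standardize",
           call. = FALSE)
    }
    z[i] <- (pheno$dnam_age[i] - mean(pheno$dnam_age[i])) / s
  }
  key <- paste(pheno$study_id, pheno$individual_id, sep = "\r")
  first <- !duplicated(key)
  out <- pheno[first, , drop = FALSE]
  zbar <- tapply(z, key, mean)
  ntis <- tapply(z, key, length)
  k <- paste(out$study_id, out$individual_id, sep = "\r")
  out$dnam_age <- as.numeric(zbar[k])
  out$tissue <- as.integer(ntis[k])
  rownames(out) <- NULL
  out
}

#' Adjust acceleration residuals for sex and optional cell composition
#'
#' Regresses raw acceleration on an intercept plus sex (and, optionally,
#' estimated cell-composition proportions) within each stratum, returning
#' the residuals as the analysis phenotype. A cell-fraction column that is
#' collinear with the others (fractions summing to ~1 alongside the
#' intercept) is dropped automatically with a message.
#'
#' @param accel Output of [age_acceleration()].
#' @param cells Logical; also adjust for cell-proportion columns
#'   (prefix `cell_`). Default `FALSE`.
#' @param per_stratum Logical; adjust within each stratum (default) or
#'   pooled across the whole table.
#' @return `accel` with an `analysis_residual` column appended.
#' @export
adjust_covariates <- function(accel, cells = FALSE, per_stratum = TRUE) {
  stopifnot("raw_acceleration" %in% names(accel))
  cell_cols <- if (cells) grep("^cell_", names(accel), value = TRUE) else character()
  if (cells && !length(cell_cols)) {
    stop("cells = TRUE but no cell_* columns present", call. = FALSE)
  }
  groups <- if (per_stratum) accel$stratum_id else rep("all", nrow(accel))
  out <- numeric(nrow(accel))
  for (g in unique(groups)) {
    i <- which(groups == g)
    X <- cbind(`(Intercept)` = 1,
               sexmale = as.numeric(accel$sex[i] == "male"))
    for (cc in cell_cols) X <- cbind(X, accel[[cc]][i])
    colnames(X) <- c("(Intercept)", "sexmale", cell_cols)
    if (any(is.na(X))) {
      stop("missing covariate values in stratum '", g, "'", call. = FALSE)
    }
    keep <- qr(X)$rank
    if (keep < ncol(X)) {
      # drop trailing collinear columns (typically the last cell fraction)
      q <- qr(X)
      drop_cols <- colnames(X)[-seq_len(q$rank)]
      pivoted <- colnames(X)[q$pivot[seq_len(q$rank)]]
      message("dropping collinear covariate(s) in stratum '", g, "': ",
              paste(setdiff(colnames(X), pivoted), collapse = ", "))
      X <- X[, pivoted, drop = FALSE]
    }
    out[i] <- stats::lm.fit(X, accel$raw_acceleration[i])$residuals
  }
  accel$analysis_residual <- out
  accel
}

#' Per-study descriptive statistics for DNAm age
#'
#' One row per study: Pearson correlation between chronological and DNAm
#' age, mean (SD) of the absolute deviation between them, and mean (SD) of
#' age-adjusted DNAm age (the raw acceleration). Studies with constant age
#' report `NA` correlation.
#'
#' @param pheno Phenotype table; if it lacks `raw_acceleration`,
#'   [age_acceleration()] is applied first.
#' @return Data frame of per-study descriptives.
#' @export
cohort_descriptives <- function(pheno) {
  if (!"raw_acceleration" %in% names(pheno)) pheno <- age_acceleration(pheno)
  studies <- unique(pheno$study_id)
  rows <- lapply(studies, function(s) {
    d <- pheno[pheno$study_id == s, ]
    if (nrow(d) < 2L) {
      warning("study '", s, "' has < 2 individuals; skipped", call. = FALSE)
      return(NULL)
    }
    r <- if (stats::sd(d$chronological_age) < 1e-10 ||
             stats::sd(d$dnam_age) < 1e-10) NA_real_ else
      stats::cor(d$chronological_age, d$dnam_age)
    dev <- abs(d$dnam_age - d$chronological_age)
    data.frame(study_id = s, n = nrow(d),
               mean_age = mean(d$chronological_age),
               cor_age_dnam = r,
               abs_dev_mean = mean(dev), abs_dev_sd = stats::sd(dev),
               accel_mean = mean(d$raw_acceleration),
               accel_sd = stats::sd(d$raw_acceleration))
  })
  do.call(rbind, rows)
}

#' Variance of age-adjusted DNAm age by age bin
#'
#' Pooled-cohort variance profile of the raw acceleration across age,
#' using decade bins by default and reporting only bins with at least
#' `min_n` observations.
#'
#' @param pheno Phenotype table (acceleration computed if absent).
#' @param width Bin width in years (default 10).
#' @param min_n Minimum observations per reported bin (default 5).
#' @return Data frame with bin bounds, midpoint, n and variance.
#' @export
acceleration_variance_by_age <- function(pheno, width = 10, min_n = 5) {
  if (!"raw_acceleration" %in% names(pheno)) pheno <- age_acceleration(pheno)
  lo <- floor(pheno$chronological_age / width) * width
  out <- do.call(rbind, lapply(sort(unique(lo)), function(b) {
    i <- lo == b
    if (sum(i) < min_n) return(NULL)
    data.frame(age_lo = b, age_hi = b + width, age_mid = b + width / 2,
               n = sum(i), variance = stats::var(pheno$raw_acceleration[i]))
  }))
  out
}
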