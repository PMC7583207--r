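## Orchestration: the full analysis ladder from phenotype + pairs tables
## to descriptives, within-study correlations, the lifespan correlation
## model and the variance-components comparison, with all outputs written
## as TSV/JSON.

.read_table <- function(x) {
  if (is.data.frame(x)) return(x)
  stopifnot(is.character(x), file.exists(x))
  sep <- if (grepl("\\.tsv$", x, ignore.case = TRUE)) "\t" else ","
  utils::read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the analysis ladder: (multi-tissue standardization when
#' needed) -> age-acceleration residuals -> sex (and optional cell)
#' adjustment -> per-study descriptives -> within-study pair correlations
#' -> the lifespan correlation-model sequence (theta free, theta = 1;
#' rate-heterogeneity tests) -> the five variance-components variants
#' with AIC comparison and variance-proportion curves. All stage outputs
#' are written under `out_dir` when given.
#'
#' @param pheno Phenotype table or CSV/TSV path.
#' @param pairs Pairs table or CSV/TSV path.
#' @param out_dir Optional output directory (created if missing).
#' @param cells Adjust for cell-composition columns too.
#' @param strata Stratum-defining columns for the acceleration regression.
#' @param adult_age,marriage_age Cohabitation-clock conventions.
#' @param n_starts Optimizer starts per fit.
#' @param seed Integer seed controlling the jittered optimizer starts, so
#'   pipeline output is a pure function of (inputs, configuration, seed).
#'   The caller's RNG state is restored on exit.
#' @param variants Variance-model variants to fit.
#' @return List with `acceleration`, `descriptives`, `variance_by_age`,
#'   `pair_correlations`, `lifespan` (fits + tests + curves),
#'   `variance_models` (fits, comparison, proportions) and `manifest`.
#' @export
run_pipeline <- function(pheno, pairs, out_dir = NULL, cells = FALSE,
                         strata = "study_id", adult_age = 18,
                         marriage_age = 24, n_starts = 3, seed = 1,
                         variants = variance_variants()) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  pheno <- .read_table(pheno)
  pairs_tab <- .read_table(pairs)
  validate_phenotypes(pheno)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(d, name) {
    if (!is.null(out_dir) && !is.null(d)) {
      .write_tsv(d, file.path(out_dir, name))
    }
  }

  if ("tissue" %in% names(pheno) && !all(is.na(pheno$tissue)) &&
      anyDuplicated(paste(pheno$study_id, pheno$individual_id))) {
    pheno <- standardize_multitissue(pheno)
  }

  accel <- adjust_covariates(age_acceleration(pheno, strata = strata),
                             cells = cells)
  emit(accel, "acceleration.tsv")
  desc <- cohort_descriptives(accel)
  emit(desc, "descriptives.tsv")
  vba <- acceleration_variance_by_age(accel)
  emit(vba, "variance_by_age.tsv")

  out <- list(acceleration = accel, descriptives = desc,
              variance_by_age = vba)

  if (is.null(pairs_tab) || nrow(pairs_tab) == 0) {
    message("pairs table empty: familial model stages skipped")
    out$manifest <- .pipeline_manifest(pheno, pairs_tab)
    if (!is.null(out_dir)) {
      writeLines(jsonlite::toJSON(out$manifest, auto_unbox = TRUE,
                                  digits = NA),
                 file.path(out_dir, "manifest.json"))
    }
    return(invisible(out))
  }
  validate_pairs(pairs_tab, pheno)

  out$pair_correlations <- fit_pair_correlations(
    accel, pairs_tab, n_starts = n_starts,
    adult_age = adult_age, marriage_age = marriage_age)
  emit(out$pair_correlations, "within_study_correlations.tsv")

  ## lifespan correlation-model ladder
  clk <- list(adult_age = adult_age, marriage_age = marriage_age)
  fit_theta_free <- do.call(fit_lifespan_model,
                            c(list(accel, pairs_tab, theta = "free",
                                   n_starts = n_starts), clk))
  fit_final <- do.call(fit_lifespan_model,
                       c(list(accel, pairs_tab, theta = "one",
                              n_starts = n_starts), clk))
  fit_shared_lambda <- do.call(fit_lifespan_model,
                               c(list(accel, pairs_tab, theta = "one",
                                      lambda = "shared",
                                      n_starts = n_starts), clk))
  fit_pg_nu <- do.call(fit_lifespan_model,
                       c(list(accel, pairs_tab, theta = "one",
                              nu = "per_group", n_starts = n_starts), clk))
  lifespan_tests <- list(
    theta_equal_one = lrt(fit_final, fit_theta_free),
    lambda_heterogeneity = lrt(fit_shared_lambda, fit_final),
    nu_heterogeneity = lrt(fit_final, fit_pg_nu))
  curves <- predict_lifespan_rho(fit_final, adult_age = adult_age,
                                 marriage_age = marriage_age)
  emit(curves, "lifespan_correlation_curves.tsv")
  out$lifespan <- list(fit = fit_final, fit_theta_free = fit_theta_free,
                       tests = lifespan_tests, curves = curves)
  if (!is.null(out_dir)) {
    fit_to_json(fit_final, file.path(out_dir, "lifespan_fit.json"))
  }

  ## variance-components ladder
  vfits <- list()
  for (v in variants) {
    vfits[[v]] <- tryCatch(
      do.call(fit_variance_model,
              c(list(accel, pairs_tab, variant = v,
                     n_starts = n_starts), clk)),
      error = function(e) {
        message("variance model ", v, " skipped: ", conditionMessage(e))
        NULL
      })
  }
  vfits <- Filter(Negate(is.null), vfits)
  if (length(vfits) >= 1) {
    nested <- list()
    if (all(c("COHAB_CE", "COHAB_CE_PLUS_A") %in% names(vfits))) {
      nested <- c(nested, list(c("COHAB_CE", "COHAB_CE_PLUS_A")))
    }
    cmp <- compare_variants(vfits, nested = if (length(nested)) nested)
    emit(cmp, "variance_model_comparison.tsv")
    best <- cmp$model[1]
    props <- variance_proportion_curves(vfits[[best]],
                                        adult_age = adult_age,
                                        marriage_age = marriage_age)
    emit(props, "variance_proportions.tsv")
    out$variance_models <- list(fits = vfits, comparison = cmp,
                                best = best, proportions = props)
    if (!is.null(out_dir)) {
      for (v in names(vfits)) {
        fit_to_json(vfits[[v]],
                    file.path(out_dir, paste0("variance_fit_", v, ".json")))
      }
    }
  }

  out$manifest <- .pipeline_manifest(pheno, pairs_tab)
  if (!is.null(out_dir)) {
    writeLines(jsonlite::toJSON(out$manifest, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "manifest.json"))
  }
  invisible(out)
}

.pipeline_manifest <- function(pheno, pairs) {
  list(package = "epicohab",
       version = as.character(utils::packageVersion("epicohab")),
       r_version = as.character(getRversion()),
       n_individuals = nrow(pheno),
       n_pairs = if (is.null(pairs)) 0L else nrow(pairs),
       n_studies = length(unique(pheno$study_id)),
       pheno_checksum = sum(pheno$dnam_age),
       timestamp = format(Sys.time(), tz = "UTC"))
}
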