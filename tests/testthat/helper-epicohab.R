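# Shared fixtures and numerical utilities for the test suite.

# minimal phenotype table: one study, n independent individuals
toy_pheno <- function(n, study = "s1", age = NULL, dnam = NULL,
                      sex = NULL, family = NULL) {
  age <- if (is.null(age)) seq_len(n) * 5 else age
  data.frame(
    study_id = study,
    family_id = if (is.null(family)) paste0(study, "_f", seq_len(n)) else family,
    individual_id = paste0(study, "_i", seq_len(n)),
    sex = if (is.null(sex)) rep(c("female", "male"), length.out = n) else sex,
    chronological_age = age,
    dnam_age = if (is.null(dnam)) age + rnorm(n) else dnam,
    stringsAsFactors = FALSE)
}

# phenotype + pairs tables for n independent pairs of one relationship type
toy_pairs_cohort <- function(n, relationship, age_a, age_b = age_a,
                             rho, var = 1, study = "s1") {
  fam <- paste0(study, "_f", seq_len(n))
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  pheno <- data.frame(
    study_id = study, family_id = rep(fam, 2),
    individual_id = c(paste0(fam, "_1"), paste0(fam, "_2")),
    sex = "female",
    chronological_age = c(rep(age_a, length.out = n),
                          rep(age_b, length.out = n)),
    dnam_age = 0,
    analysis_residual = sqrt(var) * c(z1, z2),
    stringsAsFactors = FALSE)
  pairs <- data.frame(
    family_id = fam, id_a = paste0(fam, "_1"), id_b = paste0(fam, "_2"),
    relationship = relationship,
    offspring_member = if (relationship == "PO") "a" else NA_character_,
    stringsAsFactors = FALSE)
  list(pheno = pheno, pairs = pairs)
}

# central finite-difference gradient
num_grad <- function(f, p, h = 1e-6) {
  vapply(seq_along(p), function(i) {
    e <- rep(0, length(p)); e[i] <- h
    (f(p + e) - f(p - e)) / (2 * h)
  }, numeric(1))
}

# brute-force 3x3 MVN log-likelihood via cofactor expansion (no chol/solve)
loglik3_cofactor <- function(y, S) {
  cof <- function(M, i, j) (-1)^(i + j) * det2(M[-i, -j, drop = FALSE])
  det2 <- function(M) M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  d <- S[1, 1] * cof(S, 1, 1) + S[1, 2] * cof(S, 1, 2) + S[1, 3] * cof(S, 1, 3)
  adj <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) adj[j, i] <- cof(S, i, j)
  Sinv <- adj / d
  -0.5 * (3 * log(2 * pi) + log(d) + drop(t(y) %*% Sinv %*% y))
}
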