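#' @keywords internal
"_PACKAGE"

## Relationship vocabulary ----------------------------------------------------

#' Recognised relative-pair relationship types
#'
#' The five relationship types handled throughout the package:
#' monozygotic twins (`MZ`), dizygotic twins (`DZ`), non-twin siblings
#' (`SIB`), parent--offspring pairs (`PO`) and spouse pairs (`SPOUSE`).
#'
#' @return Character vector of the five relationship codes.
#' @export
relationship_types <- function() c("MZ", "DZ", "SIB", "PO", "SPOUSE")

#' Doubled kinship coefficient for a relationship type
#'
#' The additive-genetic covariance between two relatives scales with twice
#' their kinship coefficient: 1 for MZ twins, 0.5 for DZ twins, full
#' siblings and parent--offspring pairs, and 0 for spouses.
#'
#' @param relationship Character vector of relationship codes (see
#'   [relationship_types()]).
#' @return Numeric vector of doubled kinship coefficients.
#' @examples
#' kinship2(c("MZ", "DZ", "SIB", "PO", "SPOUSE"))
#' @export
kinship2 <- function(relationship) {
  relationship <- check_relationship(relationship)
  unname(c(MZ = 1, DZ = 0.5, SIB = 0.5, PO = 0.5, SPOUSE = 0)[relationship])
}

check_relationship <- function(relationship) {
  relationship <- toupper(as.character(relationship))
  bad <- !(relationship %in% relationship_types())
  if (any(bad)) {
    stop("unknown relationship type(s): ",
         paste(unique(relationship[bad]), collapse = ", "),
         call. = FALSE)
  }
  relationship
}

## Cohabitation clock ---------------------------------------------------------

#' Compute the cohabitation clock (t, t0) for relative pairs
#'
#' Every pair of relatives carries a clock `(t, t0)`: `t` counts the years
#' relevant to shared exposure and `t0` marks when cohabitation ends, so the
#' pair is in the "cohabiting" regime while `t <= t0` and "separated"
#' afterwards. The rules are relationship specific:
#'
#' * twins (MZ/DZ): `t` = chronological age, `t0 = adult_age`;
#' * siblings: `t` = age of the younger sibling, `t0` = the younger
#'   sibling's age when the older turned `adult_age` (clamped at 0 when the
#'   age gap exceeds `adult_age`);
#' * parent--offspring: `t` = offspring age, `t0 = adult_age`;
#' * spouses: `t` = years since marriage, taken as the pair's mean age minus
#'   `marriage_age` (clamped at 0), and `t0` = separation time when known,
#'   otherwise `Inf` (still cohabiting).
#'
#' @param pairs Data frame with one row per pair and columns
#'   `relationship`, `age_a`, `age_b`, and optionally `offspring_member`
#'   (`"a"` or `"b"`, required for PO pairs) and `separation_time`
#'   (years, spouses; `NA` = never separated).
#' @param adult_age Age (years) at which children are assumed to leave the
#'   family home. Default 18.
#' @param marriage_age Assumed mean age (years) at marriage for spouse
#'   pairs. Default 24.
#' @return `pairs` with columns `t`, `t0` and `regime`
#'   (`"cohabiting"`/`"separated"`) appended.
#' @examples
#' p <- data.frame(relationship = c("MZ", "SIB", "SPOUSE"),
#'                 age_a = c(13.8, 20, 58), age_b = c(13.8, 24, 62.2))
#' cohabitation_clock(p)
#' @export
cohabitation_clock <- function(pairs, adult_age = 18, marriage_age = 24) {
  stopifnot(is.data.frame(pairs),
            all(c("relationship", "age_a", "age_b") %in% names(pairs)))
  rel <- check_relationship(pairs$relationship)
  aa <- as.numeric(pairs$age_a)
  ab <- as.numeric(pairs$age_b)
  miss <- is.na(aa) | is.na(ab)
  if (any(miss)) {
    stop("missing chronological age for pair row(s): ",
         paste(utils::head(which(miss), 5L), collapse = ", "), call. = FALSE)
  }

  t <- t0 <- numeric(nrow(pairs))

  tw <- rel %in% c("MZ", "DZ")
  if (any(tw)) {
    # twins measured at the same wave; mean guards against tiny input jitter
    t[tw] <- (aa[tw] + ab[tw]) / 2
    t0[tw] <- adult_age
  }

  sb <- rel == "SIB"
  if (any(sb)) {
    young <- pmin(aa[sb], ab[sb])
    old <- pmax(aa[sb], ab[sb])
    t[sb] <- young
    t0[sb] <- pmax(0, young - (old - adult_age))
  }

  po <- rel == "PO"
  if (any(po)) {
    off <- pairs$offspring_member
    if (is.null(off)) {
      stop("PO pairs require an 'offspring_member' column (\"a\" or \"b\")",
           call. = FALSE)
    }
    off <- as.character(off)
    if (any(po & !(off %in% c("a", "b")))) {
      stop("offspring_member must be \"a\" or \"b\" for PO pair row(s): ",
           paste(utils::head(which(po & !(off %in% c("a", "b"))), 5L),
                 collapse = ", "), call. = FALSE)
    }
    t[po] <- ifelse(off[po] == "a", aa[po], ab[po])
    t0[po] <- adult_age
  }

  sp <- rel == "SPOUSE"
  if (any(sp)) {
    t[sp] <- pmax(0, (aa[sp] + ab[sp]) / 2 - marriage_age)
    sep <- rep(Inf, sum(sp))
    if (!is.null(pairs$separation_time)) {
      st <- as.numeric(pairs$separation_time)[sp]
      sep[!is.na(st)] <- st[!is.na(st)]
    }
    t0[sp] <- sep
  }

  pairs$t <- t
  pairs$t0 <- t0
  pairs$regime <- ifelse(t <= t0, "cohabiting", "separated")
  pairs
}

## Input validation -----------------------------------------------------------

#' Validate a phenotype table
#'
#' Checks the individual-level table consumed by the pipeline: required
#' columns, non-negative chronological ages, unique `(study_id,
#' individual_id)` keys, and cell-composition fractions in `[0, 1]` when
#' present.
#'
#' @param pheno Data frame with columns `study_id`, `family_id`,
#'   `individual_id`, `sex`, `chronological_age`, `dnam_age`, and
#'   optionally `tissue`, `role` and cell-proportion columns (prefix
#'   `cell_`).
#' @return `pheno`, invisibly, after validation.
#' @export
validate_phenotypes <- function(pheno) {
  req <- c("study_id", "family_id", "individual_id", "sex",
           "chronological_age", "dnam_age")
  missing_cols <- setdiff(req, names(pheno))
  if (length(missing_cols)) {
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(pheno$chronological_age) | pheno$chronological_age < 0)) {
    stop("chronological_age must be present and >= 0 for every row",
         call. = FALSE)
  }
  key <- paste(pheno$study_id, pheno$individual_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("(study_id, individual_id) must be unique; duplicated: ",
         paste(utils::head(pheno$individual_id[duplicated(key)], 5L),
               collapse = ", "), call. = FALSE)
  }
  cells <- grep("^cell_", names(pheno), value = TRUE)
  for (cc in cells) {
    v <- pheno[[cc]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("cell proportion column ", cc, " outside [0, 1]", call. = FALSE)
    }
  }
  invisible(pheno)
}

#' Validate a pairs table against a phenotype table
#'
#' Checks that each listed pair joins two distinct members of the same
#' family, with a recognised relationship type, and that twins have equal
#' chronological ages.
#'
#' @param pairs Data frame with columns `family_id`, `id_a`, `id_b`,
#'   `relationship`, and optionally `offspring_member` and
#'   `separation_time`.
#' @param pheno Validated phenotype table (see [validate_phenotypes()]).
#' @return `pairs`, invisibly.
#' @export
validate_pairs <- function(pairs, pheno) {
  req <- c("family_id", "id_a", "id_b", "relationship")
  missing_cols <- setdiff(req, names(pairs))
  if (length(missing_cols)) {
    stop("pairs table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_relationship(pairs$relationship)
  if (any(pairs$id_a == pairs$id_b)) {
    stop("pair members must be distinct individuals", call. = FALSE)
  }
  idx_a <- match(pairs$id_a, pheno$individual_id)
  idx_b <- match(pairs$id_b, pheno$individual_id)
  if (any(is.na(idx_a)) || any(is.na(idx_b))) {
    stop("pairs reference individual_id(s) absent from the phenotype table",
         call. = FALSE)
  }
  same_fam <- pheno$family_id[idx_a] == pheno$family_id[idx_b]
  if (any(!same_fam)) {
    stop("pair members must share family_id; offending rows: ",
         paste(utils::head(which(!same_fam), 5L), collapse = ", "),
         call. = FALSE)
  }
  tw <- pairs$relationship %in% c("MZ", "DZ")
  if (any(tw)) {
    da <- abs(pheno$chronological_age[idx_a][tw] -
                pheno$chronological_age[idx_b][tw])
    if (any(da > 1e-6)) {
      stop("twin pairs must have equal chronological ages", call. = FALSE)
    }
  }
  invisible(pairs)
}
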