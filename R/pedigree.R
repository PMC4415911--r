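#' Read a pedigree file
#'
#' A tab-separated PED dialect with a header row. Fixed columns: `Family`,
#' `Individual`, `Father`, `Mother` (`0` = founder), `Sex` (1 male, 2
#' female, 0 unknown), `Phenotype` (2 affected, 1 unaffected, 0 missing),
#' `CancerType` (semicolon-separated, `0` = none recorded), `AgeDx`
#' (comma-separated ages at diagnosis, `0` = none; when several, the first
#' is used by age-based summaries), `Proband` (exactly one row = 1). Any
#' further column is a variant identifier holding carrier genotypes:
#' `M/w` carrier, `w/w` non-carrier, `0` untested.
#'
#' @param path File path.
#' @return A `pedigree` object: list with `family_id`, `members`
#'   (`data.frame` incl. `affected`, `cancer_types` list-column, `age_dx`
#'   list-column), `proband_id`, and `genotypes` (long `data.frame`:
#'   `individual`, `variant_id`, `status`).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  fixed <- c("Family", "Individual", "Father", "Mother", "Sex", "Phenotype",
             "CancerType", "AgeDx", "Proband")
  missing <- setdiff(fixed, names(df))
  if (length(missing)) {
    stop("pedigree file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$Individual)) {
    stop("duplicated individual id in pedigree", call. = FALSE)
  }
  for (p in c("Father", "Mother")) {
    dangling <- setdiff(setdiff(df[[p]], "0"), df$Individual)
    if (length(dangling)) {
      stop("pedigree references unknown ", tolower(p), "(s): ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
  }
  probands <- df$Individual[df$Proband == "1"]
  if (length(probands) != 1) {
    stop("pedigree must flag exactly one proband; found ",
         length(probands), call. = FALSE)
  }
  affected <- df$Phenotype == "2"
  cancer_types <- lapply(df$CancerType, function(x) {
    if (x %in% c("0", "")) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
  })
  age_dx <- lapply(df$AgeDx, function(x) {
    if (x %in% c("0", "")) numeric(0) else
      as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
  })
  if (any(affected & lengths(cancer_types) == 0)) {
    stop("affected individual without a cancer type", call. = FALSE)
  }
  if (any(!affected & lengths(age_dx) > 0)) {
    stop("diagnosis age recorded for an unaffected individual", call. = FALSE)
  }
  members <- data.frame(
    id = df$Individual, father = df$Father, mother = df$Mother,
    sex = c("0" = "unknown", "1" = "male", "2" = "female")[df$Sex],
    affected = affected, stringsAsFactors = FALSE
  )
  members$cancer_types <- cancer_types
  members$age_dx <- age_dx
  gcols <- setdiff(names(df), fixed)
  genotypes <- do.call(rbind, lapply(gcols, function(v) {
    status <- c("M/w" = "carrier", "w/w" = "non_carrier", "0" = "untested",
                "M/M" = "carrier")[df[[v]]]
    if (anyNA(status)) {
      stop("genotype column '", v, "' has values other than M/w, w/w, M/M, 0",
           call. = FALSE)
    }
    data.frame(individual = df$Individual, variant_id = v, status = status,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (is.null(genotypes)) {
    genotypes <- data.frame(individual = character(0),
                            variant_id = character(0),
                            status = character(0), stringsAsFactors = FALSE)
  }
  structure(list(family_id = df$Family[1], members = members,
                 proband_id = probands, genotypes = genotypes),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> family %s: %d members, proband %s, %d genotyped variant(s)\n",
              x$family_id, nrow(x$members), x$proband_id,
              length(unique(x$genotypes$variant_id))))
  invisible(x)
}

#' Study eligibility rule for a breast-cancer proband
#'
#' Eligible when one of:
#' * age at diagnosis <= 35 with >= 1 blood relative with any cancer;
#' * 35 < age <= 50 with >= 2 blood relatives *in the same lineage* with
#'   any cancer;
#' * age > 50 with >= 3 blood relatives in the same lineage with any cancer.
#'
#' @param proband_age Age at diagnosis (years).
#' @param relatives_with_cancer Number of blood relatives with any cancer.
#' @param same_lineage_count Largest number of affected blood relatives
#'   sharing one lineage (paternal or maternal, each including the nuclear
#'   family, which belongs to both).
#' @return Logical vector (arguments are recycled).
#' @examples
#' check_eligibility(30, 1, 0)  # TRUE
#' check_eligibility(40, 1, 1)  # FALSE
#' @export
check_eligibility <- function(proband_age, relatives_with_cancer,
                              same_lineage_count) {
  stopifnot(all(relatives_with_cancer >= 0), all(same_lineage_count >= 0))
  (proband_age <= 35 & relatives_with_cancer >= 1) |
    (proband_age > 35 & proband_age <= 50 & same_lineage_count >= 2) |
    (proband_age > 50 & same_lineage_count >= 3)
}

#' Derive the eligibility inputs from a pedigree
#'
#' Counts affected blood relatives overall and per lineage. A non-proband
#' member is *paternal* when connected to the proband only through the
#' father, *maternal* through the mother, and *nuclear* (siblings,
#' descendants - both lineages) otherwise. The per-lineage count used for
#' eligibility is `max(paternal, maternal) + nuclear`.
#'
#' @param ped A [read_pedigree()] object.
#' @return List with `proband_age` (first recorded diagnosis age),
#'   `relatives_with_cancer`, `same_lineage_count`, and `eligible`.
#' @export
eligibility_from_pedigree <- function(ped) {
  m <- ped$members
  pro <- m[m$id == ped$proband_id, ]
  ancestors <- function(id) {
    out <- character(0)
    frontier <- id
    while (length(frontier)) {
      rows <- m[m$id %in% frontier, ]
      parents <- setdiff(unique(c(rows$father, rows$mother)), "0")
      parents <- setdiff(parents, out)
      out <- c(out, parents)
      frontier <- parents
    }
    out
  }
  descendants_of <- function(ids) {
    out <- character(0)
    frontier <- ids
    while (length(frontier)) {
      kids <- m$id[m$father %in% frontier | m$mother %in% frontier]
      kids <- setdiff(kids, c(out, ids))
      out <- c(out, kids)
      frontier <- kids
    }
    out
  }
  pat_anc <- if (pro$father == "0") character(0) else
    c(pro$father, ancestors(pro$father))
  mat_anc <- if (pro$mother == "0") character(0) else
    c(pro$mother, ancestors(pro$mother))
  paternal <- setdiff(unique(c(pat_anc, descendants_of(pat_anc))), c(ped$proband_id, mat_anc))
  maternal <- setdiff(unique(c(mat_anc, descendants_of(mat_anc))), c(ped$proband_id, pat_anc))
  nuclear <- intersect(paternal, maternal)   # siblings & proband descendants
  paternal <- setdiff(paternal, nuclear)
  maternal <- setdiff(maternal, nuclear)
  aff <- m$id[m$affected & m$id != ped$proband_id]
  n_pat <- sum(aff %in% paternal); n_mat <- sum(aff %in% maternal)
  n_nuc <- sum(aff %in% nuclear)
  age <- if (length(pro$age_dx[[1]])) pro$age_dx[[1]][1] else NA_real_
  res <- list(proband_age = age,
              relatives_with_cancer = length(aff),
              same_lineage_count = max(n_pat, n_mat) + n_nuc)
  res$eligible <- !is.na(age) &&
    check_eligibility(age, res$relatives_with_cancer, res$same_lineage_count)
  res
}

#' Score segregation of a variant in a family
#'
#' Counts carriers among the genotyped ("tested") members, formats the
#' familiar `"positive/tested"` display (or `"U/A"` when nobody was tested),
#' and judges completeness: segregation is *complete* when every tested
#' **affected** member carries the variant - an unaffected tested
#' non-carrier does not break completeness (unaffected carriers are expected
#' under incomplete penetrance, and unaffected non-carriers are the ideal).
#'
#' @param ped A [read_pedigree()] object with genotype columns.
#' @param variant_id A variant identifier present in the pedigree's
#'   genotype table.
#' @return List: `variant_id`, `positive`, `tested`, `display`,
#'   `completeness` (`complete`, `incomplete`, `unavailable`).
#' @examples
#' ped <- read_pedigree(hc_example("family49_reconstruction.ped"))
#' score_segregation(ped, "MSH3:c.199_207del9")
#' @export
score_segregation <- function(ped, variant_id) {
  g <- ped$genotypes[ped$genotypes$variant_id == variant_id, ]
  if (!nrow(g)) {
    stop("variant '", variant_id, "' is unknown to every member of family ",
         ped$family_id, call. = FALSE)
  }
  tested <- g[g$status != "untested", ]
  positive <- sum(tested$status == "carrier")
  n_tested <- nrow(tested)
  if (n_tested == 0) {
    return(list(variant_id = variant_id, positive = 0L, tested = 0L,
                display = "U/A", completeness = "unavailable"))
  }
  aff_ids <- ped$members$id[ped$members$affected]
  tested_aff <- tested[tested$individual %in% aff_ids, ]
  complete <- all(tested_aff$status == "carrier")
  list(variant_id = variant_id, positive = as.integer(positive),
       tested = as.integer(n_tested),
       display = sprintf("%d/%d", positive, n_tested),
       completeness = if (complete) "complete" else "incomplete")
}
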