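#' Round a percentage half-up to one decimal
#'
#' Curated cohort reports round half-up (18/99 -> 18.2, 7/34 -> 20.6),
#' unlike R's round-half-even.
#'
#' @param numerator,denominator Counts.
#' @return Percentage rounded half-up to one decimal.
#' @export
pct <- function(numerator, denominator) {
  floor(numerator / denominator * 1000 + 0.5) / 10
}

#' Cohort-level summary of deleterious calls
#'
#' Aggregates per-variant deleterious calls into the headline cohort
#' numbers: variants, genes, carriers, per-category counts (a carrier
#' contributes to every category it belongs to; a multi-gene carrier is
#' counted once in `multi_gene_carriers`), per-consequence-class counts,
#' and labeled fractions.
#'
#' @param calls `data.frame` of deleterious variant calls with columns
#'   `Sample`, `Gene`, `cDNA` and (for class counts) `Consequence`.
#' @param panel Gene panel `data.frame` ([read_gene_panel()]).
#' @param flags Optional per-family syndrome flags ([read_syndrome_flags()]);
#'   enables the carriers-among-flagged-families fractions.
#' @param n_probands Number of probands screened (denominator for carrier
#'   fractions).
#' @return List: `n_probands`, `n_variants`, `n_genes`, `n_carriers`,
#'   `multi_gene_carriers`, `per_class_variant_counts`,
#'   `per_category_variant_counts`, `per_category_carrier_counts`,
#'   `per_category_gene_counts`, and `fractions` (each a list with `value`
#'   in percent, `numerator`, `denominator`).
#' @export
summarize_cohort <- function(calls, panel, flags = NULL, n_probands) {
  stopifnot(n_probands >= 0)
  unknown <- setdiff(unique(calls$Gene), panel$Gene)
  if (length(unknown)) {
    stop("gene(s) absent from the panel file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n_variants <- nrow(calls)
  carriers <- unique(calls$Sample)
  n_carriers <- length(carriers)
  if (n_probands < n_carriers) {
    stop("n_probands (", n_probands, ") is smaller than the number of ",
         "carriers (", n_carriers, ")", call. = FALSE)
  }
  genes_per_carrier <- tapply(calls$Gene, calls$Sample,
                              function(g) length(unique(g)))
  multi <- sum(genes_per_carrier >= 2)
  category <- panel$Category[match(calls$Gene, panel$Gene)]
  per_class <- if (n_variants) table_to_list(table(calls$Consequence)) else list()
  per_cat_var <- if (n_variants) table_to_list(table(category)) else list()
  per_cat_carrier <- if (n_variants) {
    lapply(split(calls$Sample, category), function(s) length(unique(s)))
  } else list()
  per_cat_gene <- if (n_variants) {
    lapply(split(calls$Gene, category), function(g) length(unique(g)))
  } else list()

  brca_carriers <- unique(calls$Sample[category == "BRCA"])
  fractions <- list(
    carriers_of_cohort = frac(n_carriers, n_probands),
    brca_carriers_of_cohort = frac(length(brca_carriers), n_probands),
    multi_gene_of_carriers = frac(multi, max(n_carriers, 1L))
  )
  if (n_variants) {
    bd <- category_gene_breakdown(calls, panel)
    if (bd$non_brca_genes > 0) {
      fractions$fa_genes_of_non_brca <-
        frac(bd$per_category[["FA"]] %||% 0L, bd$non_brca_genes)
    }
  }
  if (!is.null(flags)) {
    n_hbocs <- sum(flags$HBOCS)
    hbocs_fams <- flags$Family[flags$HBOCS]
    fractions$brca_carriers_of_hbocs_families <-
      frac(sum(brca_carriers %in% hbocs_fams), n_hbocs)
  }
  list(n_probands = n_probands, n_variants = n_variants,
       n_genes = length(unique(calls$Gene)), n_carriers = n_carriers,
       multi_gene_carriers = multi,
       per_class_variant_counts = per_class,
       per_category_variant_counts = per_cat_var,
       per_category_carrier_counts = per_cat_carrier,
       per_category_gene_counts = per_cat_gene,
       fractions = fractions)
}

frac <- function(num, den) {
  list(value = pct(num, den), numerator = as.integer(num),
       denominator = as.integer(den))
}

table_to_list <- function(tab) {
  out <- as.list(as.integer(tab))
  names(out) <- names(tab)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Distinct mutated genes per category
#'
#' @param calls Deleterious calls (`Sample`, `Gene`).
#' @param panel Gene panel.
#' @return List: `per_category` (distinct gene count per category present)
#'   and `non_brca_genes` (distinct mutated genes outside the BRCA
#'   category).
#' @export
category_gene_breakdown <- function(calls, panel) {
  category <- panel$Category[match(calls$Gene, panel$Gene)]
  per_cat <- lapply(split(calls$Gene, category), function(g) length(unique(g)))
  non_brca <- length(unique(calls$Gene[category != "BRCA"]))
  list(per_category = per_cat, non_brca_genes = non_brca)
}

#' Syndrome-criteria cross-tabulation of carriers
#'
#' For each high-penetrance gene group, counts carriers whose family does
#' and does not fulfill the matching hereditary-cancer-syndrome criteria:
#' BRCA1/2 against HBOCS, TP53 against LFS, mismatch-repair (MMR) genes
#' against LS.
#'
#' @param calls Deleterious calls (`Sample`, `Gene`).
#' @param panel Gene panel.
#' @param flags Per-family syndrome flags ([read_syndrome_flags()]); every
#'   carrier family must appear.
#' @return `data.frame` with rows BRCA1/2, TP53, MMR and columns `carriers`,
#'   `fulfilling`, `not_fulfilling`.
#' @export
syndrome_crosstab <- function(calls, panel, flags) {
  category <- panel$Category[match(calls$Gene, panel$Gene)]
  groups <- list(`BRCA1/2` = c("BRCA", "HBOCS"), TP53 = c("TP53", "LFS"),
                 MMR = c("MMR", "LS"))
  rows <- lapply(names(groups), function(g) {
    cat_name <- groups[[g]][1]; flag_name <- groups[[g]][2]
    fams <- unique(calls$Sample[category == cat_name])
    hit <- match(fams, flags$Family)
    if (anyNA(hit)) {
      stop("carrier family without syndrome flags: ",
           paste(fams[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    fulfilled <- flags[[flag_name]][hit]
    data.frame(group = g, carriers = length(fams),
               fulfilling = sum(fulfilled),
               not_fulfilling = sum(!fulfilled), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sample comparison of onset ages
#'
#' Classical two-sample t-test on ages at diagnosis, pooled-variance by
#' default (Welch selectable), two-sided.
#'
#' @param group_a,group_b Numeric vectors of onset ages (each length >= 2).
#' @param variant `"pooled"` or `"welch"`.
#' @return List: `t`, `p`, `df`, `mean_a`, `mean_b`, `variant`.
#' @examples
#' onset_age_ttest(c(30, 32, 34, 36), c(40, 42, 44, 46))
#' @export
onset_age_ttest <- function(group_a, group_b,
                            variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least two onset ages", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    # degenerate but well-defined: identical constant groups differ by 0
    return(list(t = 0, p = 1, df = length(group_a) + length(group_b) - 2,
                mean_a = mean(group_a), mean_b = mean(group_b),
                variant = variant))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = variant == "pooled",
                       alternative = "two.sided")
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter),
       mean_a = mean(group_a), mean_b = mean(group_b), variant = variant)
}
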