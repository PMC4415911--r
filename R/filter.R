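#' Call-level quality filter
#'
#' A call passes when quality score, neighbor distance and read depth all
#' meet their thresholds (defaults: quality >= 20, neighbor distance >= 5,
#' depth >= 4).
#'
#' @param quality,neighbor_distance,depth Numeric vectors (recycled).
#' @param qual_min,neighbor_min,depth_min Non-negative thresholds.
#' @return Logical vector: `TRUE` for passing calls.
#' @examples
#' qc_filter(20, 5, 4)     # boundary values pass
#' qc_filter(19.9, 5, 4)   # fails on quality
#' @export
qc_filter <- function(quality, neighbor_distance, depth,
                      qual_min = 20, neighbor_min = 5, depth_min = 4) {
  stopifnot(qual_min >= 0, neighbor_min >= 0, depth_min >= 0)
  quality >= qual_min & neighbor_distance >= neighbor_min & depth >= depth_min
}

#' Apply the candidate filter cascade to a classified variant table
#'
#' Evaluates, per variant, the call-level QC pre-filter and the four
#' candidate criteria, and resolves a final state:
#'
#' 1. *region*: exonic, or splice-region within the splice window;
#' 2. *class*: consequence in frameshift/non-frameshift indel, nonsense,
#'    missense or splicing;
#' 3. *frequency*: population minor allele frequency absent or `<= maf_max`;
#' 4. *inheritance*: any genotype in a dominantly acting (or unknown-mode)
#'    gene; in a recessively acting gene, a homozygous genotype, a compound
#'    heterozygote (two or more class-passing variants of that gene in the
#'    same sample), or a single heterozygous *strong candidate* - a stop
#'    introduced at the changed residue or a canonical splice-site variant.
#'
#' A heterozygous strong candidate in a recessive gene is flagged
#' (`recessive_flagged`) and is fully retained only when a curation entry
#' with evidence (mutation database or literature) matches its gene and cDNA
#' change; otherwise its state is `retained_needs_curation`, keeping the
#' manual-confirmation step explicit. All criteria are always evaluated, so
#' the retained set does not depend on evaluation order; the exclusion
#' reason reported is the first failing stage in the order
#' qc, region, class, frequency, inheritance.
#'
#' @param variants Variant `data.frame` with a `Consequence` column (see
#'   [classify_variants()]).
#' @param panel Gene panel `data.frame` ([read_gene_panel()]); every gene in
#'   `variants` must appear in it.
#' @param curation Optional curation `data.frame` ([read_curation()]).
#' @param maf_max Frequency criterion threshold (default 0.01).
#' @param qual_min,neighbor_min,depth_min QC thresholds ([qc_filter()]).
#' @param splice_window Canonical splice window (default 2).
#' @param qc_indels Apply the QC pre-filter to indel calls as well as
#'   substitutions. Default `FALSE`: QC metrics come from the SNV caller and
#'   are evaluated for substitutions only.
#' @return A `data.frame` (one row per input variant, input order) with
#'   `variant_id`, `Sample`, `Gene`, `cDNA`, `Consequence`, the per-stage
#'   logicals `qc_pass`, `criterion_region`, `criterion_class`,
#'   `criterion_frequency`, `criterion_inheritance`, `recessive_flagged`,
#'   `final_state` (`retained`, `retained_needs_curation`, `excluded`) and
#'   `exclusion_reason` (`NA` for retained variants).
#' @export
filter_variants <- function(variants, panel, curation = NULL,
                            maf_max = 0.01, qual_min = 20, neighbor_min = 5,
                            depth_min = 4, splice_window = 2,
                            qc_indels = FALSE) {
  if (is.null(variants$Consequence)) {
    stop("variants must carry a Consequence column; run classify_variants()",
         call. = FALSE)
  }
  unknown <- setdiff(unique(variants$Gene), panel$Gene)
  if (length(unknown)) {
    stop("gene(s) absent from the panel file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(variants)
  parsed <- parse_hgvs(variants$cDNA, variants$Protein)
  inheritance <- panel$Inheritance[match(variants$Gene, panel$Gene)]

  qc <- qc_filter(variants$Qual, variants$NeighborDist, variants$Depth,
                  qual_min, neighbor_min, depth_min)
  qc[is.na(qc)] <- FALSE
  if (!qc_indels) {
    # QC metrics are produced by the SNV caller; indel calls pass through
    qc[parsed$kind != "sub"] <- TRUE
  }

  splice_ok <- !is.na(parsed$intron_offset) &
    abs(parsed$intron_offset) <= splice_window
  crit_region <- variants$Region == "exonic" |
    (variants$Region == "splicing" & splice_ok)

  allowed <- c("frameshift_indel", "nonframeshift_indel", "nonsense",
               "missense", "splicing")
  crit_class <- variants$Consequence %in% allowed

  crit_freq <- is.na(variants$MAF_1000G) | variants$MAF_1000G <= maf_max

  strong <- strong_candidate(variants$Consequence, parsed)
  genotype <- variants$Genotype
  recessive <- inheritance == "recessive"
  # compound heterozygosity: >=2 class-passing variants of one recessive
  # gene in one sample
  key <- paste(variants$Sample, variants$Gene, sep = "\r")
  class_hits <- tapply(crit_class, key, sum)
  compound <- recessive & genotype == "het" &
    as.vector(class_hits[key]) >= 2 & crit_class
  single_strong <- recessive & genotype == "het" & !compound & strong
  crit_inherit <- !recessive |
    genotype == "hom" | compound | single_strong
  recessive_flagged <- single_strong & crit_class & crit_region & crit_freq & qc

  curated <- rep(FALSE, n)
  if (!is.null(curation) && nrow(curation)) {
    ck <- paste(curation$Gene, curation$cDNA)
    hit <- match(paste(variants$Gene, variants$cDNA), ck)
    curated <- !is.na(hit) & curation$Evidence[hit] != "none"
  }

  all_ok <- qc & crit_region & crit_class & crit_freq & crit_inherit
  final <- ifelse(!all_ok, "excluded",
                  ifelse(recessive_flagged & !curated,
                         "retained_needs_curation", "retained"))
  reason <- rep(NA_character_, n)
  stages <- list(qc = qc, region = crit_region, class = crit_class,
                 frequency = crit_freq, inheritance = crit_inherit)
  for (stage in rev(names(stages))) {
    reason[!stages[[stage]]] <- stage
  }
  reason[all_ok] <- NA_character_

  data.frame(
    variant_id = variant_id(variants$Sample, variants$Gene, variants$cDNA),
    Sample = variants$Sample, Gene = variants$Gene, cDNA = variants$cDNA,
    Consequence = variants$Consequence,
    qc_pass = qc, criterion_region = crit_region,
    criterion_class = crit_class, criterion_frequency = crit_freq,
    criterion_inheritance = crit_inherit,
    recessive_flagged = recessive_flagged,
    curation_match = curated,
    final_state = final, exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
}

# strong candidate for the recessive single-allele clause: an immediately
# truncating change (bare stop at the changed residue or nonsense class) or
# a canonical splice-site variant
strong_candidate <- function(consequence, parsed) {
  consequence %in% c("nonsense", "splicing") | parsed$protein_terminates
}
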