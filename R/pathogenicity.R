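#' Two-feature in-silico missense rule
#'
#' A missense variant is in-silico damaging when *both* features flag it:
#'
#' * *prediction* (amino-acid level): SIFT calls it damaging (`"D"`) **or**
#'   PolyPhen-2 calls it damaging / probably damaging / possibly damaging
#'   (`"D"`, `"PD"`, `"P"`);
#' * *conservation* (nucleotide level): PhyloP **or** LRT calls the site
#'   conserved (`"C"`).
#'
#' Within a feature, an absent tool call (`NA`) contributes "not damaging";
#' but both tools of a feature absent is an input error, since the rule then
#' has no evidence to act on.
#'
#' @param sift,polyphen Character vectors of categorical tool calls
#'   (`"D"`/`"B"`, and `"PD"`/`"D"`/`"P"`/`"B"`); `NA` for no call.
#' @param phylop,lrt Character vectors (`"C"`/`"NC"`); `NA` for no call.
#' @return A `data.frame` with logical columns `feature_prediction`,
#'   `feature_conservation`, `damaging` (the conjunction).
#' @examples
#' missense_insilico("D", "B", "C", "NC")   # damaging
#' missense_insilico("B", "B", "NC", "NC")  # not damaging
#' @export
missense_insilico <- function(sift, polyphen, phylop, lrt) {
  n <- max(length(sift), length(polyphen), length(phylop), length(lrt))
  sift <- rep_len(sift, n); polyphen <- rep_len(polyphen, n)
  phylop <- rep_len(phylop, n); lrt <- rep_len(lrt, n)
  if (any(is.na(sift) & is.na(polyphen))) {
    stop("missense rule needs at least one of SIFT/PolyPhen-2 per variant",
         call. = FALSE)
  }
  if (any(is.na(phylop) & is.na(lrt))) {
    stop("missense rule needs at least one of PhyloP/LRT per variant",
         call. = FALSE)
  }
  pred <- (!is.na(sift) & sift == "D") |
    (!is.na(polyphen) & polyphen %in% c("PD", "D", "P"))
  cons <- (!is.na(phylop) & phylop == "C") | (!is.na(lrt) & lrt == "C")
  data.frame(feature_prediction = pred, feature_conservation = cons,
             damaging = pred & cons)
}

#' Final pathogenicity call for filter-surviving variants
#'
#' Truncating consequence classes (frameshift indel, non-frameshift indel,
#' nonsense, splicing) are called deleterious outright. Missense variants
#' are deleterious only when the two-feature in-silico rule
#' ([missense_insilico()]) flags them damaging *and* a curation entry with
#' evidence matches the variant (the manual database/literature gate).
#' Prediction columns on non-missense variants are ignored: the in-silico
#' rule is scoped to the missense class. Any other class is not deleterious.
#'
#' @param variants Variant `data.frame` with a `Consequence` column; for
#'   missense rows the `SIFT`/`PolyPhen2`/`PhyloP`/`LRT` columns feed the
#'   in-silico rule (a missense row with all four absent is an error).
#' @param curation Optional curation `data.frame` ([read_curation()]).
#' @return A `data.frame` with `variant_id`, `deleterious`, `basis`
#'   (`truncating_class`, `missense_insilico_plus_curation`,
#'   `not_deleterious`) and, for missense rows, the two feature logicals
#'   (`NA` elsewhere).
#' @export
call_pathogenicity <- function(variants, curation = NULL) {
  if (is.null(variants$Consequence)) {
    stop("variants must carry a Consequence column; run classify_variants()",
         call. = FALSE)
  }
  n <- nrow(variants)
  truncating <- c("frameshift_indel", "nonframeshift_indel", "nonsense",
                  "splicing")
  deleterious <- rep(FALSE, n)
  basis <- rep("not_deleterious", n)
  feat_pred <- feat_cons <- rep(NA, n)

  is_trunc <- variants$Consequence %in% truncating
  deleterious[is_trunc] <- TRUE
  basis[is_trunc] <- "truncating_class"

  is_mis <- variants$Consequence == "missense"
  if (any(is_mis)) {
    ins <- missense_insilico(variants$SIFT[is_mis],
                             variants$PolyPhen2[is_mis],
                             variants$PhyloP[is_mis],
                             variants$LRT[is_mis])
    curated <- rep(FALSE, sum(is_mis))
    if (!is.null(curation) && nrow(curation)) {
      ck <- paste(curation$Gene, curation$cDNA)
      hit <- match(paste(variants$Gene[is_mis], variants$cDNA[is_mis]), ck)
      curated <- !is.na(hit) & curation$Evidence[hit] != "none"
    }
    deleterious[is_mis] <- ins$damaging & curated
    basis[is_mis] <- ifelse(ins$damaging & curated,
                            "missense_insilico_plus_curation",
                            "not_deleterious")
    feat_pred[is_mis] <- ins$feature_prediction
    feat_cons[is_mis] <- ins$feature_conservation
  }

  data.frame(
    variant_id = variant_id(variants$Sample, variants$Gene, variants$cDNA),
    deleterious = deleterious, basis = basis,
    feature_prediction = feat_pred, feature_conservation = feat_cons,
    stringsAsFactors = FALSE
  )
}
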