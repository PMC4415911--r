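#' Classify, filter and call pathogenicity in one pass
#'
#' Runs the analysis stages in order: consequence classification
#' ([classify_variants()]), QC pre-filter and candidate filter cascade
#' ([filter_variants()]), and final pathogenicity assignment
#' ([call_pathogenicity()], applied to cascade survivors). Every input
#' variant appears exactly once in the result, either retained (with its
#' pathogenicity call) or excluded with one machine-readable reason.
#'
#' @param variants Annotated variant `data.frame`
#'   ([read_variant_table()]).
#' @param panel Gene panel ([read_gene_panel()]).
#' @param curation Optional curation table ([read_curation()]).
#' @param maf_max,qual_min,neighbor_min,depth_min,splice_window,qc_indels
#'   Thresholds, see [filter_variants()].
#' @return A `data.frame`: the input columns plus `Consequence`,
#'   `variant_id`, the cascade trace columns, `deleterious` (`FALSE` for
#'   excluded variants) and `basis`.
#' @examples
#' variants <- read_variant_table(hc_example("hbc99_variants.tsv"))
#' panel <- read_gene_panel(hc_example("hbc99_panel.tsv"))
#' curation <- read_curation(hc_example("hbc99_curation.tsv"))
#' res <- screen_variants(variants, panel, curation)
#' sum(res$deleterious)
#' @export
screen_variants <- function(variants, panel, curation = NULL,
                            maf_max = 0.01, qual_min = 20, neighbor_min = 5,
                            depth_min = 4, splice_window = 2,
                            qc_indels = FALSE) {
  classified <- classify_variants(variants, splice_window)
  trace <- filter_variants(classified, panel, curation, maf_max, qual_min,
                           neighbor_min, depth_min, splice_window, qc_indels)
  out <- cbind(classified,
               trace[, c("variant_id", "qc_pass", "criterion_region",
                         "criterion_class", "criterion_frequency",
                         "criterion_inheritance", "recessive_flagged",
                         "final_state", "exclusion_reason")])
  out$deleterious <- FALSE
  out$basis <- NA_character_
  kept <- out$final_state != "excluded"
  if (any(kept)) {
    calls <- call_pathogenicity(classified[kept, , drop = FALSE], curation)
    out$deleterious[kept] <- calls$deleterious
    out$basis[kept] <- calls$basis
  }
  # a recessive het candidate still awaiting curation is not counted as a
  # deleterious call; its basis records what it would resolve to
  out$deleterious[out$final_state == "retained_needs_curation"] <- FALSE
  out
}

#' Run the full pipeline from a configuration file
#'
#' Executes the stages in the order QC -> filter cascade -> pathogenicity ->
#' (optional) segregation -> cohort summary, and writes report files. The
#' run is a pure function of the inputs and configuration.
#'
#' The YAML configuration names the inputs and thresholds:
#' ```yaml
#' variants: path/to/variants.tsv     # or a list of paths
#' panel: path/to/panel.tsv
#' curation: path/to/curation.tsv     # optional
#' syndrome_flags: path/to/flags.tsv  # optional
#' pedigrees: [path/a.ped, path/b.ped]  # optional
#' n_probands: 99
#' thresholds:                        # all optional, defaults shown
#'   maf_max: 0.01
#'   qual_min: 20
#'   neighbor_min: 5
#'   depth_min: 4
#'   splice_window: 2
#'   qc_indels: false
#' ```
#'
#' @param config Path to a YAML configuration file.
#' @param out_dir Output directory (created if needed). Writes
#'   `screened.tsv` (all variants with trace and calls), `deleterious.tsv`,
#'   `exclusions.tsv`, `summary.json`, `crosstab.tsv` (when flags given)
#'   and `segregation.tsv` (when pedigrees given).
#' @return Invisibly, a list with `screened`, `calls`, `summary`,
#'   `crosstab`, `segregation`.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  cfg <- yaml::read_yaml(config)
  for (key in c("variants", "panel")) {
    if (is.null(cfg[[key]])) {
      stop("pipeline config must name '", key, "'", call. = FALSE)
    }
  }
  th <- cfg$thresholds %||% list()
  defaults <- list(maf_max = 0.01, qual_min = 20, neighbor_min = 5,
                   depth_min = 4, splice_window = 2, qc_indels = FALSE)
  th <- utils::modifyList(defaults, th)

  variants <- do.call(rbind, lapply(unlist(cfg$variants), read_variant_table))
  panel <- read_gene_panel(cfg$panel)
  curation <- if (!is.null(cfg$curation)) read_curation(cfg$curation)
  flags <- if (!is.null(cfg$syndrome_flags)) read_syndrome_flags(cfg$syndrome_flags)

  screened <- screen_variants(variants, panel, curation,
                              maf_max = th$maf_max, qual_min = th$qual_min,
                              neighbor_min = th$neighbor_min,
                              depth_min = th$depth_min,
                              splice_window = th$splice_window,
                              qc_indels = th$qc_indels)
  calls <- screened[screened$deleterious, , drop = FALSE]
  n_probands <- cfg$n_probands %||% length(unique(variants$Sample))
  summary <- summarize_cohort(calls, panel, flags, n_probands)
  crosstab <- if (!is.null(flags) && nrow(calls)) {
    syndrome_crosstab(calls, panel, flags)
  }
  segregation <- NULL
  if (!is.null(cfg$pedigrees)) {
    segregation <- do.call(rbind, lapply(unlist(cfg$pedigrees), function(p) {
      ped <- read_pedigree(p)
      vids <- unique(ped$genotypes$variant_id)
      do.call(rbind, lapply(vids, function(v) {
        s <- score_segregation(ped, v)
        data.frame(family = ped$family_id, variant_id = v,
                   display = s$display, completeness = s$completeness,
                   stringsAsFactors = FALSE)
      }))
    }))
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(screened, file.path(out_dir, "screened.tsv"))
  write_variant_table(calls, file.path(out_dir, "deleterious.tsv"))
  write_variant_table(screened[screened$final_state == "excluded", ,
                               drop = FALSE],
                      file.path(out_dir, "exclusions.tsv"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(crosstab)) {
    utils::write.table(crosstab, file.path(out_dir, "crosstab.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(segregation)) {
    utils::write.table(segregation, file.path(out_dir, "segregation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(screened = screened, calls = calls, summary = summary,
                 crosstab = crosstab, segregation = segregation))
}
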