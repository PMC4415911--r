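# Shared fixture loaders and small builders used across test files.

fixture_variants <- function() read_variant_table(hc_example("hbc99_variants.tsv"))
fixture_panel <- function() read_gene_panel(hc_example("hbc99_panel.tsv"))
fixture_curation <- function() read_curation(hc_example("hbc99_curation.tsv"))
fixture_flags <- function() read_syndrome_flags(hc_example("hbc99_syndrome_flags.tsv"))
fixture_markers <- function() read_marker_table(hc_example("msh3_markers.csv"))

fixture_calls <- function() {
  res <- screen_variants(fixture_variants(), fixture_panel(),
                         fixture_curation())
  res[res$deleterious, , drop = FALSE]
}

# one minimal valid annotated variant row, fields overridable
make_variant <- function(Sample = "S1", Gene = "BRCA1", cDNA = "c.100C>T",
                         Protein = "p.Q34*", Region = "exonic",
                         MAF_1000G = 0, SIFT = NA_character_,
                         PolyPhen2 = NA_character_, PhyloP = NA_character_,
                         LRT = NA_character_, Genotype = "het", Qual = 99,
                         NeighborDist = 10, Depth = 50) {
  data.frame(Sample = Sample, Gene = Gene, Transcript = ".", cDNA = cDNA,
             Protein = Protein, Chrom = "1", Start = 1000, End = 1000,
             Region = Region, MAF_1000G = MAF_1000G, SIFT = SIFT,
             PolyPhen2 = PolyPhen2, PhyloP = PhyloP, LRT = LRT,
             Genotype = Genotype, Qual = Qual, NeighborDist = NeighborDist,
             Depth = Depth, stringsAsFactors = FALSE)
}

# marker call vector with every marker stable except `unstable`
make_marker_calls <- function(unstable = character(0)) {
  calls <- stats::setNames(rep("-", length(unlist(marker_panel()))),
                           unlist(marker_panel()))
  calls[unstable] <- "+"
  calls
}
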