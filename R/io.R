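#' Read an annotated variant table
#'
#' Reads the tab-separated annotated-variant format used throughout the
#' pipeline (one row per called variant per sample). Required columns:
#' `Sample`, `Gene`, `Transcript`, `cDNA`, `Protein`, `Chrom`, `Start`,
#' `End`, `Region`, `MAF_1000G`, `SIFT`, `PolyPhen2`, `PhyloP`, `LRT`,
#' `Genotype`, `Qual`, `NeighborDist`, `Depth`. Additional columns are kept.
#'
#' Missing annotation values are written as `"."` (or left empty). A missing
#' population allele frequency is parsed as `NA`, which is deliberately
#' distinct from `0`: a printed `0` means the variant was queried against the
#' frequency resource and not observed, while `NA` means it was never
#' queried. Both pass the frequency criterion of [filter_variants()].
#' Coordinates are 1-based inclusive.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect `"tsv"` (the native format) or `"vcf_lite"`, a minimal VCF
#'   reader that takes `CHROM`/`POS`/`REF`/`ALT`/`QUAL` plus INFO keys
#'   `SAMPLE,GENE,TRANSCRIPT,CDNA,PROTEIN,REGION,MAF,SIFT,PP2,PHYLOP,LRT,GT,ND,DP`
#'   and converts to the native column layout at the boundary.
#' @return A `data.frame`, one row per input record, in file order, with the
#'   columns above (`MAF_1000G`, `Qual`, `Start`, `End`, `NeighborDist`,
#'   `Depth` numeric; annotation blanks normalized to `NA`).
#' @seealso [write_variant_table()], [classify_variants()], [screen_variants()]
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf_lite")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant table not found: ", path, call. = FALSE)
  if (dialect == "vcf_lite") {
    return(read_vcf_lite(path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  required <- c("Sample", "Gene", "Transcript", "cDNA", "Protein", "Chrom",
                "Start", "End", "Region", "MAF_1000G", "SIFT", "PolyPhen2",
                "PhyloP", "LRT", "Genotype", "Qual", "NeighborDist", "Depth")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("variant table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- normalize_variant_table(df, path)
  df
}

# shared post-parse normalization: types, blank -> NA, invariant checks
normalize_variant_table <- function(df, path) {
  blank_to_na <- function(x) {
    x[x %in% c(".", "", "-", "NA")] <- NA_character_
    x
  }
  for (col in c("SIFT", "PolyPhen2", "PhyloP", "LRT", "Transcript")) {
    df[[col]] <- blank_to_na(df[[col]])
  }
  maf_raw <- blank_to_na(df$MAF_1000G)
  maf <- suppressWarnings(as.numeric(maf_raw))
  bad <- which(!is.na(maf_raw) & is.na(maf))
  if (length(bad)) {
    stop(sprintf("unparseable MAF value '%s' at data row %d of %s",
                 maf_raw[bad[1]], bad[1], path), call. = FALSE)
  }
  if (any(!is.na(maf) & (maf < 0 | maf > 1))) {
    stop("MAF_1000G outside [0, 1] in ", path, call. = FALSE)
  }
  df$MAF_1000G <- maf
  for (col in c("Start", "End", "Qual", "NeighborDist", "Depth")) {
    df[[col]] <- suppressWarnings(as.numeric(blank_to_na(df[[col]])))
  }
  if (nrow(df) && any(stats::na.omit(df$Start > df$End))) {
    stop("variant with Start > End in ", path, call. = FALSE)
  }
  gt <- tolower(df$Genotype)
  gt[!gt %in% c("het", "hom")] <- "unknown"
  df$Genotype <- gt
  df$Region <- tolower(df$Region)
  df$Region[!df$Region %in% c("exonic", "splicing", "intronic")] <- "other"
  rownames(df) <- NULL
  df
}

read_vcf_lite <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1], "#CHROM")) {
    stop("vcf_lite input lacks a #CHROM header line: ", path, call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else ".", character(1))
  }
  if (!length(body)) {
    fields <- character(0)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (length(parts) && any(lengths(parts) < 8)) {
    stop("vcf_lite record with fewer than 8 fields in ", path, call. = FALSE)
  }
  get <- function(i) vapply(parts, `[[`, character(1), i)
  n <- length(parts)
  if (n == 0) {
    info <- character(0); pos <- numeric(0)
    chrom <- character(0); qual <- numeric(0)
  } else {
    chrom <- get(1)
    pos <- as.numeric(get(2))
    qual <- suppressWarnings(as.numeric(get(6)))
    info <- get(8)
  }
  span <- function(ref) pmax(nchar(ref), 1)
  ref <- if (n) get(4) else character(0)
  df <- data.frame(
    Sample = info_get(info, "SAMPLE"),
    Gene = info_get(info, "GENE"),
    Transcript = info_get(info, "TRANSCRIPT"),
    cDNA = info_get(info, "CDNA"),
    Protein = info_get(info, "PROTEIN"),
    Chrom = chrom,
    # VCF POS is the 1-based start of REF; the native table is 1-based
    # inclusive [start, end], so End = POS + nchar(REF) - 1
    Start = pos,
    End = pos + span(ref) - 1,
    Region = info_get(info, "REGION"),
    MAF_1000G = info_get(info, "MAF"),
    SIFT = info_get(info, "SIFT"),
    PolyPhen2 = info_get(info, "PP2"),
    PhyloP = info_get(info, "PHYLOP"),
    LRT = info_get(info, "LRT"),
    Genotype = info_get(info, "GT"),
    Qual = as.character(qual),
    NeighborDist = info_get(info, "ND"),
    Depth = info_get(info, "DP"),
    stringsAsFactors = FALSE
  )
  normalize_variant_table(df, path)
}

#' Write an annotated variant table
#'
#' Writes the native tab-separated format read by [read_variant_table()].
#' Numeric annotation gaps are serialized as `"."` so that a write/read
#' round trip preserves every field.
#'
#' @param variants A variant `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  out <- variants
  for (col in names(out)) {
    x <- out[[col]]
    if (is.numeric(x)) {
      x <- ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE))
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "."
    }
    out[[col]] <- x
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene panel file
#'
#' @param path Tab-separated file with columns `Gene`, `Inheritance`
#'   (`dominant`, `recessive` or `unknown`) and `Category` (one of `BRCA`,
#'   `TP53`, `MMR`, `CDH1`, `FA`, `OTHER`).
#' @return A `data.frame` with one row per gene.
#' @export
read_gene_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("Gene", "Inheritance", "Category")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("gene panel is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$Inheritance <- tolower(df$Inheritance)
  if (any(!df$Inheritance %in% c("dominant", "recessive", "unknown"))) {
    stop("gene panel Inheritance must be dominant/recessive/unknown",
         call. = FALSE)
  }
  if (any(!df$Category %in% c("BRCA", "TP53", "MMR", "CDH1", "FA", "OTHER"))) {
    stop("gene panel Category must be one of BRCA/TP53/MMR/CDH1/FA/OTHER",
         call. = FALSE)
  }
  if (anyDuplicated(df$Gene)) stop("duplicated gene in panel", call. = FALSE)
  df
}

#' Read a curation-evidence file
#'
#' Curation entries record the outcome of the manual lookup of a variant in
#' gene-specific mutation databases or the published literature. An entry
#' with `Evidence = none` must not carry a source label.
#'
#' @param path Tab-separated file with columns `Gene`, `cDNA`, `Evidence`
#'   (`database`, `literature` or `none`) and `Source`.
#' @return A `data.frame` of curation entries.
#' @export
read_curation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("Gene", "cDNA", "Evidence", "Source")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("curation file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!df$Evidence %in% c("database", "literature", "none"))) {
    stop("curation Evidence must be database/literature/none", call. = FALSE)
  }
  bad <- df$Evidence == "none" & nzchar(trimws(df$Source)) & df$Source != "."
  if (any(bad)) {
    stop("curation entry with Evidence=none must not carry a source label",
         call. = FALSE)
  }
  df
}

#' Read per-family hereditary-cancer-syndrome flags
#'
#' @param path Tab-separated file with columns `Family`, `HBOCS`, `LFS`,
#'   `LS` (0/1 flags).
#' @return A `data.frame` with logical flag columns.
#' @export
read_syndrome_flags <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(Family = "character"))
  required <- c("Family", "HBOCS", "LFS", "LS")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("syndrome flags file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("HBOCS", "LFS", "LS")) df[[col]] <- df[[col]] != 0
  df
}

#' Read a microsatellite marker-call table
#'
#' One row per sample/tissue, one column per marker with `"+"` (unstable),
#' `"-"` (stable) or `"f"` (failed assay). Non-marker columns (sample labels,
#' IHC scores, ...) are preserved.
#'
#' @param path CSV file path.
#' @return A `data.frame` in file order.
#' @seealso [classify_msi_table()]
#' @export
read_marker_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  markers <- intersect(unlist(marker_panel()), names(df))
  if (!length(markers)) {
    stop("no recognized microsatellite marker columns in ", path, call. = FALSE)
  }
  for (m in markers) {
    bad <- !df[[m]] %in% c("+", "-", "f")
    if (any(bad)) {
      stop(sprintf("marker %s has call '%s'; expected +, - or f",
                   m, df[[m]][which(bad)[1]]), call. = FALSE)
    }
  }
  df
}
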