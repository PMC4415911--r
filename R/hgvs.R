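#' Parse cDNA and protein HGVS strings
#'
#' Extracts the features needed for consequence classification from the HGVS
#' dialect used in curated panel tables: substitutions (`c.1214C>G`),
#' deletions (`c.754delC`, `c.162_179del18`, `c.5468-1_5474del8`),
#' duplications (`c.7409dupT`, `c.2699_2704dupGGCAAT`), insertions
#' (`c.8956_8957insAA`), deletion-insertions (`c.1050_1051delinsTCT`) and
#' intronic offsets (`c.850-2A>G`, `c.194+2T>C`).
#'
#' Lengths: for deletions and duplications the length is taken from the
#' stated bases or count when given, else from the position range; for
#' insertions it is the number of inserted bases; for deletion-insertions it
#' is the replaced reference span.
#'
#' @param cdna Character vector of cDNA HGVS strings (must begin `"c."`).
#' @param protein Character vector of protein HGVS strings (begin `"p."`,
#'   `"p.?"` for no annotation, or `NA`). Recycled against `cdna`.
#' @return A `data.frame` with one row per input: `raw_cdna`, `raw_protein`,
#'   `kind` (`sub`, `del`, `dup`, `ins`, `delins`), `intron_offset` (signed,
#'   `NA` for exonic positions), `indel_length` (`NA` for substitutions),
#'   `frameshift_tagged`, `protein_terminates` (bare stop at the changed
#'   residue), `protein_inframe_del` (in-frame deletion annotation),
#'   `protein_known`, `aa_ref`, `aa_alt` (for simple substitutions).
#' @examples
#' parse_hgvs("c.850-2A>G", "p.?")
#' parse_hgvs("c.1189_1191delTAT", "p.I397del")
#' @export
parse_hgvs <- function(cdna, protein = NA_character_) {
  n <- max(length(cdna), length(protein))
  cdna <- rep_len(as.character(cdna), n)
  protein <- rep_len(as.character(protein), n)
  out <- lapply(seq_len(n), function(i) parse_hgvs_one(cdna[i], protein[i]))
  do.call(rbind, out)
}

parse_hgvs_one <- function(cdna, protein) {
  if (is.na(cdna) || !startsWith(cdna, "c.")) {
    stop("unsupported cDNA HGVS (must begin 'c.'): ", cdna, call. = FALSE)
  }
  body <- sub("^c\\.", "", cdna)

  # position block: first position token, optional intronic offset, optional
  # range partner "A_B" (either end may carry an offset; the smallest |offset|
  # end is taken, so a deletion spanning an acceptor reports the -1 boundary)
  pos_re <- "(\\*?\\d+)([+-]\\d+)?"
  range_re <- paste0("^", pos_re, "(?:_", pos_re, ")?")
  m <- regmatches(body, regexec(range_re, body))[[1]]
  if (!length(m)) stop("unparseable cDNA HGVS: ", cdna, call. = FALSE)
  off1 <- if (nzchar(m[3])) as.integer(m[3]) else NA_integer_
  off2 <- if (length(m) >= 5 && nzchar(m[5])) as.integer(m[5]) else NA_integer_
  offsets <- c(off1, off2)
  intron_offset <- if (all(is.na(offsets))) NA_integer_ else {
    offs <- offsets[!is.na(offsets)]
    offs[which.min(abs(offs))]
  }
  p1 <- suppressWarnings(as.integer(sub("\\*", "", m[2])))
  p2 <- if (length(m) >= 4 && nzchar(m[4])) {
    suppressWarnings(as.integer(sub("\\*", "", m[4])))
  } else NA_integer_
  span <- if (is.na(p2)) 1L else abs(p2 - p1) + 1L
  rest <- substr(body, nchar(m[1]) + 1L, nchar(body))

  tail_len <- function(tail) {
    # "TAT" -> 3, "18" -> 18, "" -> NA (fall back to the range span)
    if (!nzchar(tail)) return(NA_integer_)
    if (grepl("^\\d+$", tail)) return(as.integer(tail))
    if (grepl("^[ACGTN]+$", tail)) return(nchar(tail))
    stop("unsupported HGVS tail: ", tail, call. = FALSE)
  }

  kind <- NA_character_
  indel_length <- NA_integer_
  if (grepl("^delins", rest)) {
    kind <- "delins"
    indel_length <- span   # replaced reference span
  } else if (grepl("^del", rest)) {
    kind <- "del"
    len <- tail_len(sub("^del", "", rest))
    indel_length <- if (is.na(len)) span else len
  } else if (grepl("^dup", rest)) {
    kind <- "dup"
    len <- tail_len(sub("^dup", "", rest))
    indel_length <- if (is.na(len)) span else len
  } else if (grepl("^ins", rest)) {
    kind <- "ins"
    len <- tail_len(sub("^ins", "", rest))
    if (is.na(len)) stop("insertion without inserted bases: ", cdna, call. = FALSE)
    indel_length <- len
  } else if (grepl("^[ACGTN]>[ACGTN]$", rest)) {
    kind <- "sub"
  } else if (rest == "=") {
    kind <- "sub"
  } else {
    stop("unsupported cDNA HGVS form: ", cdna, call. = FALSE)
  }
  if (!is.na(indel_length) && indel_length <= 0) {
    stop("non-positive indel length in ", cdna, call. = FALSE)
  }
  if (!is.na(intron_offset) && intron_offset == 0L) {
    stop("zero intronic offset in ", cdna, call. = FALSE)
  }

  # protein-level features
  p <- protein
  protein_known <- !is.na(p) && nzchar(p) && p != "p.?" && p != "."
  frameshift_tagged <- protein_known && grepl("fs", p, fixed = TRUE)
  protein_terminates <- protein_known &&
    grepl("^p\\.[A-Z][a-z]{0,2}\\d+(\\*|Ter)$", p)
  protein_inframe_del <- protein_known && !frameshift_tagged &&
    grepl("del$", p) && !grepl("ins", p)
  aa_ref <- aa_alt <- NA_character_
  if (protein_known) {
    mm <- regmatches(p, regexec("^p\\.([A-Z])(\\d+)([A-Z*=])$", p))[[1]]
    if (length(mm) == 4) {
      aa_ref <- mm[2]
      aa_alt <- mm[4]
    }
  }
  synonymous <- protein_known &&
    (p == "p.=" || (!is.na(aa_alt) && aa_alt == "=") ||
       (!is.na(aa_ref) && !is.na(aa_alt) && aa_ref == aa_alt))

  data.frame(raw_cdna = cdna, raw_protein = protein, kind = kind,
             intron_offset = intron_offset, indel_length = indel_length,
             frameshift_tagged = frameshift_tagged,
             protein_terminates = protein_terminates,
             protein_inframe_del = protein_inframe_del,
             protein_known = protein_known, synonymous = synonymous,
             aa_ref = aa_ref, aa_alt = aa_alt,
             stringsAsFactors = FALSE)
}

#' Assign a consequence class to a parsed variant
#'
#' One class per variant, in priority order: `splicing` (intronic offset
#' within the splice window), `frameshift_indel`, `nonsense`,
#' `nonframeshift_indel`, `missense`, `synonymous`, `other`.
#'
#' Rules, in the order applied after the splice-window check:
#' * a frameshift-tagged protein annotation (`...fs*N`) is `frameshift_indel`
#'   regardless of the cDNA arithmetic (so a deletion spanning a splice
#'   acceptor but annotated `fs` counts as frameshift, not splicing);
#' * a *substitution* whose protein annotation is a bare stop (`p.X123*`)
#'   is `nonsense`; stop-gain indels are truncating events and group with
#'   `frameshift_indel`;
#' * an insertion/deletion is `nonframeshift_indel` when the protein
#'   annotation is an in-frame deletion, or - when no protein annotation is
#'   available - when its length is a multiple of 3; any other annotated
#'   indel (including in-frame duplications whose protein annotation is an
#'   insertion of new residues) is counted with `frameshift_indel`, matching
#'   curated panel-study counting practice (see the package vignette);
#' * substitutions changing one residue are `missense`; `p.=` (or unchanged
#'   residue) is `synonymous`; anything else falls through to `other`.
#'
#' @param parsed A `data.frame` from [parse_hgvs()] (any number of rows).
#' @param splice_window Positive integer; canonical splice window in bases,
#'   applied symmetrically to donor (`+`) and acceptor (`-`) offsets.
#'   Default 2.
#' @return Character vector of consequence classes, one per row.
#' @examples
#' classify_consequence(parse_hgvs("c.194+2T>C", "p.?"))
#' classify_consequence(parse_hgvs("c.7007G>A", "p.R2336H"))
#' @export
classify_consequence <- function(parsed, splice_window = 2) {
  stopifnot(is.data.frame(parsed), splice_window >= 1)
  vapply(seq_len(nrow(parsed)), function(i) {
    x <- parsed[i, ]
    if (!is.na(x$intron_offset) && abs(x$intron_offset) <= splice_window &&
        !x$frameshift_tagged) {
      return("splicing")
    }
    if (x$frameshift_tagged) return("frameshift_indel")
    is_indel <- x$kind %in% c("del", "dup", "ins", "delins")
    if (!is_indel) {
      if (x$protein_terminates) return("nonsense")
      if (x$synonymous) return("synonymous")
      if (!is.na(x$aa_ref) && !is.na(x$aa_alt) && x$aa_alt != "*" &&
          x$aa_alt != "=" && x$aa_ref != x$aa_alt) {
        return("missense")
      }
      return("other")
    }
    inframe <- if (x$protein_known) {
      x$protein_inframe_del && x$indel_length %% 3L == 0L
    } else {
      x$indel_length %% 3L == 0L
    }
    if (inframe) "nonframeshift_indel" else "frameshift_indel"
  }, character(1))
}

#' Classify every variant in an annotated table
#'
#' Convenience wrapper: parses the `cDNA`/`Protein` columns and appends a
#' `Consequence` column.
#'
#' @param variants Variant `data.frame` as from [read_variant_table()].
#' @param splice_window Splice window passed to [classify_consequence()].
#' @return `variants` with an added `Consequence` column.
#' @export
classify_variants <- function(variants, splice_window = 2) {
  parsed <- parse_hgvs(variants$cDNA, variants$Protein)
  variants$Consequence <- classify_consequence(parsed, splice_window)
  variants
}
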