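#' Build a simulation configuration
#'
#' Defines the statistical shape of a synthetic panel-screen cohort:
#' family-ascertained probands, background polymorphisms with a two-part
#' allele-frequency mixture, spiked deleterious variants of chosen
#' consequence classes, and mismatch-repair-conditioned marker instability
#' rates. The seed is mandatory; the whole cohort is a deterministic
#' function of the configuration.
#'
#' Background variants are constructed to violate at least one candidate
#' criterion or to fail the missense in-silico rule, so truth labels are
#' exact: a fraction `p_common` draws a common allele frequency (uniform on
#' (0.01, 0.5], failing the frequency criterion) and the rest draw rare
#' frequencies (uniform on \[0, 0.01\]); independently each background
#' variant is synonymous with probability `fraction_synonymous`, deep
#' intronic with probability `fraction_deep_intronic`, and otherwise a
#' missense with a benign prediction profile. `n_adversarial_missense`
#' background variants per cohort instead get damaging profiles *and*
#' curation entries: they are constructed false positives for specificity
#' studies.
#'
#' @param seed Integer seed (mandatory).
#' @param n_families Number of families/probands.
#' @param background_per_sample Background variants per proband.
#' @param p_common Mass of the common component of the MAF mixture.
#' @param fraction_synonymous,fraction_deep_intronic Background class mix.
#' @param n_adversarial_missense Constructed false positives (default 0).
#' @param spike_plan `data.frame` with columns `gene`, `class`, `zygosity`
#'   (`het`/`hom`), `count`: deleterious variants spiked into randomly
#'   chosen families. Default: 10 spikes spanning all five retained classes.
#' @param relatives_affected_range Integer range (length 2) for the number
#'   of affected relatives beyond the eligibility minimum.
#' @param marker_rates Named list `deficient`/`proficient`, each a named
#'   numeric vector `mono`/`di`/`emast` of per-marker instability
#'   probabilities.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_families = 20,
                              background_per_sample = 50,
                              p_common = 0.7,
                              fraction_synonymous = 0.15,
                              fraction_deep_intronic = 0.15,
                              n_adversarial_missense = 0,
                              spike_plan = default_spike_plan(),
                              relatives_affected_range = c(1L, 3L),
                              marker_rates = list(
                                deficient = c(mono = 0.02, di = 0.25,
                                              emast = 0.50),
                                proficient = c(mono = 0.01, di = 0.02,
                                               emast = 0.05))) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("simulation_config requires an integer seed", call. = FALSE)
  }
  fracs <- c(p_common, fraction_synonymous, fraction_deep_intronic)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (fraction_synonymous + fraction_deep_intronic > 1) {
    stop("fraction_synonymous + fraction_deep_intronic must be <= 1",
         call. = FALSE)
  }
  stopifnot(n_families >= 1, background_per_sample >= 0,
            n_adversarial_missense >= 0,
            length(relatives_affected_range) == 2,
            all(unlist(marker_rates) >= 0), all(unlist(marker_rates) <= 1))
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 background_per_sample = as.integer(background_per_sample),
                 p_common = p_common,
                 fraction_synonymous = fraction_synonymous,
                 fraction_deep_intronic = fraction_deep_intronic,
                 n_adversarial_missense = as.integer(n_adversarial_missense),
                 spike_plan = spike_plan,
                 relatives_affected_range = as.integer(relatives_affected_range),
                 marker_rates = marker_rates),
            class = "simulation_config")
}

#' Default spike plan
#'
#' Ten deleterious spikes spanning all five retained consequence classes in
#' dominantly acting panel genes.
#'
#' @return A `data.frame` with columns `gene`, `class`, `zygosity`, `count`.
#' @export
default_spike_plan <- function() {
  data.frame(
    gene = c("BRCA1", "BRCA2", "TP53", "MLH1", "PALB2"),
    class = c("frameshift_indel", "nonsense", "missense", "splicing",
              "nonframeshift_indel"),
    zygosity = "het",
    count = c(3L, 2L, 2L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

# independent substream per family: reproducible under partial regeneration
family_seed <- function(seed, index) {
  (as.integer(seed) * 7919L + index * 104729L) %% 2147483629L
}

#' Generate a synthetic cohort
#'
#' Produces pedigrees satisfying the study eligibility rules, per-sample
#' annotated variant tables (background plus spikes) with truth labels, a
#' curation table covering the spikes that need evidence, and
#' mismatch-repair-conditioned marker profiles. Deterministic given the
#' configuration; each family consumes its own pseudo-random substream.
#'
#' @param config A [simulation_config()].
#' @param panel Gene panel `data.frame`; defaults to the bundled panel.
#' @return A `synthetic_cohort` list: `variants` (one table, `Sample` =
#'   family id), `truth` (`variant_id`, `label` in
#'   `spiked_pathogenic`/`background`), `curation`, `pedigrees` (list of
#'   [read_pedigree()]-shaped objects), `marker_profiles`, `panel`,
#'   `config`.
#' @export
simulate_cohort <- function(config, panel = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(panel)) panel <- read_gene_panel(hc_example("hbc99_panel.tsv"))
  validate_spike_plan(config$spike_plan, panel)

  fam_ids <- sprintf("F%03d", seq_len(config$n_families))
  # spread spike instances over families round-robin after a seeded shuffle
  plan <- config$spike_plan
  spikes <- plan[rep(seq_len(nrow(plan)), plan$count), c("gene", "class", "zygosity")]
  withr_seed(config$seed, {
    spikes <- spikes[sample.int(nrow(spikes)), , drop = FALSE]
  })
  spikes$family <- fam_ids[(seq_len(nrow(spikes)) - 1L) %% config$n_families + 1L]

  variants <- list(); truths <- list(); curations <- list(); peds <- list()
  for (i in seq_along(fam_ids)) {
    fam <- fam_ids[i]
    withr_seed(family_seed(config$seed, i), {
      fam_spikes <- spikes[spikes$family == fam, , drop = FALSE]
      sv <- sim_spike_variants(fam, fam_spikes)
      bv <- sim_background_variants(fam, config)
      peds[[i]] <- sim_pedigree(fam, config,
                                spike_ids = variant_id(fam, sv$Gene, sv$cDNA))
      variants[[i]] <- rbind(sv, bv)
      truths[[i]] <- data.frame(
        variant_id = variant_id(fam, variants[[i]]$Gene, variants[[i]]$cDNA),
        label = c(rep("spiked_pathogenic", nrow(sv)),
                  rep("background", nrow(bv))),
        stringsAsFactors = FALSE)
      curations[[i]] <- sim_curation(sv, bv)
    })
  }
  adversarial <- sim_adversarial(config, fam_ids)
  variants <- do.call(rbind, c(variants, list(adversarial$variants)))
  truth <- do.call(rbind, c(truths, list(adversarial$truth)))
  curation <- do.call(rbind, c(curations, list(adversarial$curation)))
  rownames(variants) <- rownames(truth) <- rownames(curation) <- NULL
  markers <- withr_seed(config$seed + 1L, {
    generate_marker_profiles(config, n_deficient = 4L, n_proficient = 4L,
                             .reseed = FALSE)
  })
  structure(list(variants = variants, truth = truth, curation = curation,
                 pedigrees = peds, marker_profiles = markers,
                 panel = panel, config = config),
            class = "synthetic_cohort")
}

# run code under a temporary RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

validate_spike_plan <- function(plan, panel) {
  required <- c("gene", "class", "zygosity", "count")
  if (!all(required %in% names(plan))) {
    stop("spike plan needs columns gene/class/zygosity/count", call. = FALSE)
  }
  unknown <- setdiff(plan$gene, panel$Gene)
  if (length(unknown)) {
    stop("spike plan gene(s) absent from panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ok_class <- c("frameshift_indel", "nonframeshift_indel", "nonsense",
                "missense", "splicing")
  if (any(!plan$class %in% ok_class)) {
    stop("spike class must be one of ", paste(ok_class, collapse = ", "),
         call. = FALSE)
  }
  inh <- panel$Inheritance[match(plan$gene, panel$Gene)]
  weak_het <- inh == "recessive" & plan$zygosity == "het" &
    !plan$class %in% c("nonsense", "splicing")
  if (any(weak_het)) {
    stop("infeasible spike plan: a heterozygous spike in recessive gene(s) ",
         paste(unique(plan$gene[weak_het]), collapse = ", "),
         " must be a nonsense or canonical splice-site variant",
         call. = FALSE)
  }
}

aa3 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

sim_spike_variants <- function(fam, fam_spikes) {
  n <- nrow(fam_spikes)
  rows <- lapply(seq_len(n), function(j) {
    class <- fam_spikes$class[j]
    pos <- sample(300:5000, 1) * 3L   # codon-aligned anchor
    res <- pos %/% 3L
    a1 <- sample(aa3, 1); a2 <- sample(aa3, 1)
    hg <- switch(class,
      frameshift_indel = list(
        cdna = sprintf("c.%ddelC", pos),
        prot = sprintf("p.%s%d%sfs*%d", a1, res, a2, sample(3:60, 1)),
        region = "exonic"),
      nonframeshift_indel = list(
        cdna = sprintf("c.%d_%ddel%d", pos, pos + 8L, 9L),
        prot = sprintf("p.%s%d_%s%ddel", a1, res, a2, res + 2L),
        region = "exonic"),
      nonsense = list(
        cdna = sprintf("c.%dC>T", pos),
        prot = sprintf("p.%s%d*", a1, res),
        region = "exonic"),
      missense = list(
        cdna = sprintf("c.%dG>A", pos),
        prot = sprintf("p.%s%d%s", a1, res, setdiff(aa3, a1)[1]),
        region = "exonic"),
      splicing = list(
        cdna = sprintf("c.%d+2T>C", pos),
        prot = "p.?",
        region = "splicing"))
    mis <- class == "missense"
    data.frame(Sample = fam, Gene = fam_spikes$gene[j], Transcript = ".",
               cDNA = hg$cdna, Protein = hg$prot,
               Chrom = as.character(sample(1:22, 1)),
               Start = pos + 1e6, End = pos + 1e6, Region = hg$region,
               MAF_1000G = 0,
               SIFT = if (mis) "D" else NA_character_,
               PolyPhen2 = if (mis) "PD" else NA_character_,
               PhyloP = if (mis) "C" else NA_character_,
               LRT = if (mis) "C" else NA_character_,
               Genotype = fam_spikes$zygosity[j],
               Qual = 60 + sample(0:40, 1), NeighborDist = 10, Depth = 60,
               stringsAsFactors = FALSE)
  })
  if (!n) return(empty_variant_table())
  do.call(rbind, rows)
}

sim_background_variants <- function(fam, config) {
  n <- config$background_per_sample
  if (!n) return(empty_variant_table())
  common <- stats::runif(n) < config$p_common
  maf <- ifelse(common,
                stats::runif(n, 0.01 + 1e-6, 0.5),
                stats::runif(n, 0, 0.01))
  u <- stats::runif(n)
  type <- ifelse(u < config$fraction_synonymous, "synonymous",
          ifelse(u < config$fraction_synonymous +
                   config$fraction_deep_intronic, "intronic", "missense"))
  pos <- 3L * sample(200:40000, n)
  res <- pos %/% 3L
  a1 <- sample(aa3, n, replace = TRUE)
  genes <- sample(c("BRCA1", "BRCA2", "TP53", "MLH1", "MSH3", "PALB2",
                    "RAD50", "CDH1", "FGFR3", "SPINK1"), n, replace = TRUE)
  cdna <- ifelse(type == "intronic",
                 sprintf("c.%d-%dA>G", pos, sample(20:80, n, replace = TRUE)),
                 sprintf("c.%dC>T", pos))
  prot <- ifelse(type == "synonymous", "p.=",
          ifelse(type == "intronic", "p.?",
                 sprintf("p.%s%d%s", a1, res,
                         vapply(a1, function(a) setdiff(aa3, a)[2],
                                character(1)))))
  mis <- type == "missense"
  data.frame(Sample = fam, Gene = genes, Transcript = ".",
             cDNA = cdna, Protein = prot,
             Chrom = as.character(sample(1:22, n, replace = TRUE)),
             Start = pos + 2e6, End = pos + 2e6,
             Region = ifelse(type == "intronic", "intronic", "exonic"),
             MAF_1000G = maf,
             SIFT = ifelse(mis, "B", NA_character_),
             PolyPhen2 = ifelse(mis, "B", NA_character_),
             PhyloP = ifelse(mis, "NC", NA_character_),
             LRT = ifelse(mis, "NC", NA_character_),
             Genotype = "het",
             Qual = 30 + round(stats::runif(n, 0, 60)),
             NeighborDist = sample(6:30, n, replace = TRUE),
             Depth = sample(10:120, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# constructed false positives: rare damaging missense with curation entries
sim_adversarial <- function(config, fam_ids) {
  n <- config$n_adversarial_missense
  if (!n) {
    return(list(variants = empty_variant_table(),
                truth = data.frame(variant_id = character(0),
                                   label = character(0),
                                   stringsAsFactors = FALSE),
                curation = empty_curation()))
  }
  withr_seed(config$seed + 2L, {
    fam <- sample(fam_ids, n, replace = TRUE)
    pos <- 3L * sample(50000:60000, n)
    res <- pos %/% 3L
    a1 <- sample(aa3, n, replace = TRUE)
    v <- data.frame(Sample = fam, Gene = "BRCA2", Transcript = ".",
                    cDNA = sprintf("c.%dG>A", pos),
                    Protein = sprintf("p.%s%d%s", a1, res,
                                      vapply(a1, function(a) setdiff(aa3, a)[3],
                                             character(1))),
                    Chrom = "13", Start = pos + 3e6, End = pos + 3e6,
                    Region = "exonic", MAF_1000G = 0,
                    SIFT = "D", PolyPhen2 = "PD", PhyloP = "C", LRT = "C",
                    Genotype = "het", Qual = 80, NeighborDist = 12, Depth = 70,
                    stringsAsFactors = FALSE)
    list(variants = v,
         truth = data.frame(variant_id = variant_id(v$Sample, v$Gene, v$cDNA),
                            label = "background", stringsAsFactors = FALSE),
         curation = data.frame(Gene = v$Gene, cDNA = v$cDNA,
                               Evidence = "literature",
                               Source = "synthetic adversarial entry",
                               stringsAsFactors = FALSE))
  })
}

sim_curation <- function(spiked, background) {
  mis <- spiked[spiked$Region == "exonic" & !is.na(spiked$SIFT), , drop = FALSE]
  strong_recessive <- spiked[grepl("\\*$", spiked$Protein) |
                               spiked$Region == "splicing", , drop = FALSE]
  src <- rbind(mis, strong_recessive)
  if (!nrow(src)) return(empty_curation())
  unique(data.frame(Gene = src$Gene, cDNA = src$cDNA, Evidence = "literature",
                    Source = "synthetic evidence entry",
                    stringsAsFactors = FALSE))
}

empty_variant_table <- function() {
  data.frame(Sample = character(0), Gene = character(0),
             Transcript = character(0), cDNA = character(0),
             Protein = character(0), Chrom = character(0),
             Start = numeric(0), End = numeric(0), Region = character(0),
             MAF_1000G = numeric(0), SIFT = character(0),
             PolyPhen2 = character(0), PhyloP = character(0),
             LRT = character(0), Genotype = character(0), Qual = numeric(0),
             NeighborDist = numeric(0), Depth = numeric(0),
             stringsAsFactors = FALSE)
}

empty_curation <- function() {
  data.frame(Gene = character(0), cDNA = character(0),
             Evidence = character(0), Source = character(0),
             stringsAsFactors = FALSE)
}

sim_pedigree <- function(fam, config, spike_ids = character(0)) {
  rng <- config$relatives_affected_range
  tier <- sample(1:3, 1)
  age <- c(sample(26:35, 1), sample(36:50, 1), sample(51:70, 1))[tier]
  need <- c(1L, 2L, 3L)[tier]
  extra <- sample(seq(rng[1], rng[2]), 1)
  n_aff <- need + extra
  n_rel <- max(n_aff, 4L)   # maternal-side relatives (incl. mother)
  rel_ids <- c("MTH", sprintf("MA%d", seq_len(n_rel - 1L)))
  aff_rel <- rel_ids[seq_len(n_aff)]
  ids <- c("MGF", "MGM", "FTH", rel_ids, "PB")
  members <- data.frame(
    id = ids,
    father = c("0", "0", "0", rep("MGF", n_rel), "FTH"),
    mother = c("0", "0", "0", rep("MGM", n_rel), "MTH"),
    sex = c("male", "female", "male", rep("female", n_rel), "female"),
    affected = ids %in% c(aff_rel, "PB"),
    stringsAsFactors = FALSE)
  members$cancer_types <- lapply(members$affected, function(a) {
    if (a) sample(c("Breast", "Ovary", "Colon", "Stomach"), 1) else character(0)
  })
  members$age_dx <- lapply(seq_len(nrow(members)), function(i) {
    if (!members$affected[i]) return(numeric(0))
    if (members$id[i] == "PB") age else sample(35:80, 1)
  })
  genotypes <- do.call(rbind, lapply(spike_ids, function(v) {
    tested <- c("PB", utils::head(aff_rel, 3))
    status <- stats::setNames(rep("untested", length(ids)), ids)
    status[tested] <- "carrier"
    data.frame(individual = ids, variant_id = v, status = unname(status[ids]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(genotypes)) {
    genotypes <- data.frame(individual = character(0),
                            variant_id = character(0), status = character(0),
                            stringsAsFactors = FALSE)
  }
  structure(list(family_id = fam, members = members, proband_id = "PB",
                 genotypes = genotypes), class = "pedigree")
}

#' Simulate mismatch-repair-conditioned marker profiles
#'
#' Mismatch-repair-deficient samples draw marker instability with elevated
#' dinucleotide and EMAST rates and near-zero mononucleotide rates;
#' proficient samples draw near-zero rates everywhere (the pattern expected
#' of MSH3 loss: EMAST plus low-level dinucleotide instability).
#'
#' @param config A [simulation_config()] (supplies seed and rates).
#' @param n_deficient,n_proficient Sample counts.
#' @param .reseed Reset the RNG from the config seed (default `TRUE`; the
#'   cohort generator passes `FALSE` because it manages streams itself).
#' @return `data.frame`: `Sample`, `MMR_status` (truth), one column per
#'   marker with `"+"`/`"-"` calls.
#' @export
generate_marker_profiles <- function(config, n_deficient, n_proficient,
                                     .reseed = TRUE) {
  run <- function() {
    panel <- marker_panel()
    mono <- panel$nci_mono
    di <- c(panel$nci_di, panel$extra_di)
    em <- panel$emast
    draw <- function(n, rates) {
      if (!n) return(NULL)
      m <- t(vapply(seq_len(n), function(i) {
        p <- c(rep(rates[["mono"]], length(mono)),
               rep(rates[["di"]], length(di)),
               rep(rates[["emast"]], length(em)))
        ifelse(stats::runif(length(p)) < p, "+", "-")
      }, character(length(mono) + length(di) + length(em))))
      colnames(m) <- c(mono, di, em)
      m
    }
    def <- draw(n_deficient, config$marker_rates$deficient)
    prof <- draw(n_proficient, config$marker_rates$proficient)
    m <- rbind(def, prof)
    out <- data.frame(
      Sample = sprintf("S%03d", seq_len(n_deficient + n_proficient)),
      MMR_status = c(rep("deficient", n_deficient),
                     rep("proficient", n_proficient)),
      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(m, stringsAsFactors = FALSE))
  }
  if (.reseed) withr_seed(config$seed + 1L, run()) else run()
}

#' Generate a distractor variant suite
#'
#' Each distractor is valid except for exactly one defect, cycling through
#' six modes: deep-intronic *region*, synonymous *class*, common-allele
#' *frequency*, heterozygous-missense-in-recessive-gene *inheritance*, a
#' missense failing the *in-silico* rule, and a damaging missense with no
#' *curation* evidence. The first four are rejected by the filter cascade
#' with the matching exclusion reason; the last two survive the cascade but
#' are not called deleterious.
#'
#' @param n Number of distractors (default 60).
#' @param seed Integer seed.
#' @return List: `variants` (annotated table), `curation` (entries for the
#'   in-silico-failure mode, whose defect must not be a missing entry), and
#'   `expected` (`variant_id`, `mode`).
#' @export
simulate_distractors <- function(n = 60, seed = 1) {
  modes <- c("region", "class", "frequency", "inheritance", "insilico",
             "curation")
  withr_seed(seed, {
    mode <- modes[(seq_len(n) - 1L) %% length(modes) + 1L]
    pos <- 3L * (100000L + sample.int(50000L, n))
    res <- pos %/% 3L
    a1 <- sample(aa3, n, replace = TRUE)
    a2 <- vapply(a1, function(a) setdiff(aa3, a)[1], character(1))
    gene <- ifelse(mode == "inheritance", "MUTYH", "BRCA1")
    cdna <- ifelse(mode == "region",
                   sprintf("c.%d-%dA>G", pos, sample(30:90, n, replace = TRUE)),
                   sprintf("c.%dC>T", pos))
    prot <- ifelse(mode == "region", "p.?",
            ifelse(mode == "class", "p.=",
                   sprintf("p.%s%d%s", a1, res, a2)))
    benign <- mode == "insilico"
    v <- data.frame(
      Sample = sprintf("DX%03d", seq_len(n)), Gene = gene, Transcript = ".",
      cDNA = cdna, Protein = prot,
      Chrom = as.character(sample(1:22, n, replace = TRUE)),
      Start = pos + 5e6, End = pos + 5e6,
      Region = ifelse(mode == "region", "intronic", "exonic"),
      MAF_1000G = ifelse(mode == "frequency",
                         stats::runif(n, 0.02, 0.4), 0),
      SIFT = ifelse(mode %in% c("region", "class"), NA_character_,
                    ifelse(benign, "B", "D")),
      PolyPhen2 = ifelse(mode %in% c("region", "class"), NA_character_,
                         ifelse(benign, "B", "PD")),
      PhyloP = ifelse(mode %in% c("region", "class"), NA_character_,
                      ifelse(benign, "NC", "C")),
      LRT = ifelse(mode %in% c("region", "class"), NA_character_,
                   ifelse(benign, "NC", "C")),
      Genotype = "het", Qual = 90, NeighborDist = 12, Depth = 60,
      stringsAsFactors = FALSE)
    cur_rows <- which(mode == "insilico")
    curation <- if (length(cur_rows)) {
      data.frame(Gene = v$Gene[cur_rows], cDNA = v$cDNA[cur_rows],
                 Evidence = "literature",
                 Source = "synthetic evidence entry",
                 stringsAsFactors = FALSE)
    } else empty_curation()
    list(variants = v, curation = curation,
         expected = data.frame(
           variant_id = variant_id(v$Sample, v$Gene, v$cDNA),
           mode = mode, stringsAsFactors = FALSE))
  })
}
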