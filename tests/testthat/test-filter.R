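test_that("qc_filter enforces all three thresholds with closed bounds", {
  expect_true(qc_filter(20, 5, 4))
  expect_false(qc_filter(19.9, 5, 4))
  expect_false(qc_filter(60, 0, 100))
  expect_false(qc_filter(60, 10, 3))
  expect_equal(qc_filter(c(20, 10), c(5, 5), c(4, 4)), c(TRUE, FALSE))
})

test_that("each cascade criterion excludes with the matching reason", {
  panel <- fixture_panel()
  screen1 <- function(v, curation = NULL, ...) {
    res <- screen_variants(v, panel, curation, ...)
    res[1, ]
  }
  # dominant missense, rare, exonic: retained
  r <- screen1(make_variant(Gene = "BRCA2", cDNA = "c.7007G>A",
                            Protein = "p.R2336H", SIFT = "D",
                            PolyPhen2 = "B", PhyloP = "C", LRT = "NC"))
  expect_identical(r$final_state, "retained")
  # common allele: frequency
  r <- screen1(make_variant(cDNA = "c.200C>T", Protein = "p.P67L",
                            MAF_1000G = 0.05, SIFT = "D", PolyPhen2 = "D",
                            PhyloP = "C", LRT = "C"))
  expect_identical(r$exclusion_reason, "frequency")
  # synonymous: class
  r <- screen1(make_variant(cDNA = "c.300C>T", Protein = "p.="))
  expect_identical(r$exclusion_reason, "class")
  # deep intronic: region
  r <- screen1(make_variant(cDNA = "c.300-40A>G", Protein = "p.?",
                            Region = "intronic"))
  expect_identical(r$exclusion_reason, "region")
  # splice-labeled region beyond the window: region governs
  r <- screen1(make_variant(cDNA = "c.300-7A>G", Protein = "p.?",
                            Region = "splicing"))
  expect_identical(r$exclusion_reason, "region")
  # failing QC on a substitution
  r <- screen1(make_variant(Qual = 10))
  expect_identical(r$exclusion_reason, "qc")
  # QC metrics do not gate indel calls by default, but do when asked
  v <- make_variant(cDNA = "c.100delC", Protein = "p.R34Vfs*5", Qual = 10)
  expect_identical(screen1(v)$final_state, "retained")
  expect_identical(screen1(v, qc_indels = TRUE)$exclusion_reason, "qc")
  # unknown gene is a configuration error naming the gene
  expect_error(screen_variants(make_variant(Gene = "NOTAGENE"), panel),
               "NOTAGENE")
})

test_that("inheritance criterion implements the recessive clauses", {
  panel <- fixture_panel()
  # het missense in a recessive gene, no second allele: excluded
  v <- make_variant(Gene = "MUTYH", cDNA = "c.100C>T", Protein = "p.P34L",
                    SIFT = "D", PolyPhen2 = "D", PhyloP = "C", LRT = "C")
  r <- screen_variants(v, panel)
  expect_identical(r$exclusion_reason, "inheritance")
  # homozygous: retained
  r <- screen_variants(transform(v, Genotype = "hom"), panel)
  expect_identical(r$final_state, "retained")
  # compound heterozygote: two class-passing variants, same gene and sample
  v2 <- rbind(v, make_variant(Gene = "MUTYH", cDNA = "c.500C>T",
                              Protein = "p.Q167*"))
  r <- screen_variants(v2, panel)
  expect_identical(r$final_state, c("retained", "retained"))
  # single strong het candidate: flagged, needs curation to fully retain
  strong <- make_variant(Gene = "MUTYH", cDNA = "c.850-2A>G", Protein = "p.?",
                         Region = "splicing", MAF_1000G = 0.002)
  r <- screen_variants(strong, panel)
  expect_true(r$recessive_flagged)
  expect_identical(r$final_state, "retained_needs_curation")
  r <- screen_variants(strong, panel, fixture_curation())
  expect_identical(r$final_state, "retained")
  expect_true(r$deleterious)
})

test_that("retention is monotone in the frequency threshold", {
  set.seed(11)
  d <- simulate_distractors(36, seed = 5)
  v <- rbind(fixture_variants()[, names(d$variants)], d$variants)
  panel <- fixture_panel()
  cur <- rbind(fixture_curation()[, names(d$curation)], d$curation)
  retained <- function(maf_max) {
    r <- screen_variants(v, panel, cur, maf_max = maf_max)
    r$variant_id[r$final_state != "excluded"]
  }
  grid <- c(0.2, 0.05, 0.01, 0.002, 0.0005, 0)
  sets <- lapply(grid, retained)
  for (i in seq_along(grid)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]),
                label = sprintf("maf_max %g subset of %g",
                                grid[i], grid[i - 1]))
  }
  # threshold 0: only variants never observed in the frequency resource
  # (MAF absent or printed 0) survive the frequency criterion
  r0 <- screen_variants(v, panel, cur, maf_max = 0)
  surv <- r0$criterion_frequency
  expect_identical(surv, is.na(v$MAF_1000G) | v$MAF_1000G == 0)
})

test_that("the retained set is the criterion-wise conjunction (order-free)", {
  d <- simulate_distractors(30, seed = 9)
  v <- rbind(fixture_variants()[, names(d$variants)], d$variants)
  r <- screen_variants(v, fixture_panel(), fixture_curation())
  conj <- r$qc_pass & r$criterion_region & r$criterion_class &
    r$criterion_frequency & r$criterion_inheritance
  expect_identical(r$final_state != "excluded", conj)
})

test_that("every record is accounted for exactly once", {
  d <- simulate_distractors(24, seed = 2)
  v <- rbind(fixture_variants()[, names(d$variants)], d$variants)
  r <- screen_variants(v, fixture_panel(), fixture_curation())
  expect_equal(nrow(r), nrow(v))
  expect_false(anyDuplicated(r$variant_id) > 0)
  excluded <- r$final_state == "excluded"
  expect_true(all(!is.na(r$exclusion_reason[excluded])))
  expect_true(all(is.na(r$exclusion_reason[!excluded])))
})
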