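test_that("percentages round half-up to one decimal", {
  expect_equal(pct(18, 99), 18.2)
  expect_equal(pct(7, 34), 20.6)
  expect_equal(pct(18, 88), 20.5)
  expect_equal(pct(6, 19), 31.6)
  expect_equal(pct(1, 8), 12.5)
  expect_equal(pct(1, 16), 6.3)   # exact half rounds up, not to even
})

test_that("cohort summary reproduces the headline screen numbers", {
  s <- summarize_cohort(fixture_calls(), fixture_panel(), fixture_flags(), 99)
  expect_equal(s$n_variants, 42)
  expect_equal(s$n_genes, 21)
  expect_equal(s$n_carriers, 34)
  expect_equal(s$multi_gene_carriers, 7)
  expect_equal(s$per_category_variant_counts$BRCA, 18)
  expect_equal(s$per_category_variant_counts$TP53, 3)
  expect_equal(s$per_category_variant_counts$MMR, 5)
  expect_equal(s$per_category_variant_counts$CDH1, 1)
  expect_equal(s$per_category_variant_counts$FA, 6)
  expect_equal(s$per_category_variant_counts$OTHER, 9)
  expect_equal(s$fractions$brca_carriers_of_cohort$value, 18.2)
  expect_equal(s$fractions$brca_carriers_of_cohort$numerator, 18)
  expect_equal(s$fractions$multi_gene_of_carriers$value, 20.6)
  expect_equal(s$fractions$brca_carriers_of_hbocs_families$value, 20.5)
  expect_equal(s$fractions$brca_carriers_of_hbocs_families$denominator, 88)
  expect_equal(s$fractions$fa_genes_of_non_brca$value, 31.6)
  # conservation: class counts sum to the variant total
  expect_equal(sum(unlist(s$per_class_variant_counts)), s$n_variants)
  # category carrier counts overlap (multi-gene carriers), so their sum is
  # at least the carrier total
  expect_gte(sum(unlist(s$per_category_carrier_counts)), s$n_carriers)
})

test_that("an empty call set gives an all-zero summary", {
  s <- summarize_cohort(fixture_calls()[0, ], fixture_panel(), NULL, 10)
  expect_equal(s$n_variants, 0)
  expect_equal(s$n_carriers, 0)
  expect_equal(s$multi_gene_carriers, 0)
  expect_length(s$per_class_variant_counts, 0)
})

test_that("summarize rejects more carriers than probands", {
  expect_error(summarize_cohort(fixture_calls(), fixture_panel(), NULL, 5),
               "n_probands")
})

test_that("gene-category breakdown isolates FA genes among non-BRCA genes", {
  calls <- fixture_calls()
  bd <- category_gene_breakdown(calls, fixture_panel())
  expect_equal(bd$per_category$FA, 6)
  expect_equal(bd$non_brca_genes, 19)
  brca_only <- calls[calls$Gene %in% c("BRCA1", "BRCA2"), ]
  bd <- category_gene_breakdown(brca_only, fixture_panel())
  expect_null(bd$per_category$FA)
  expect_equal(bd$non_brca_genes, 0)
  one <- calls[calls$Gene == "PALB2", ][1, ]
  bd <- category_gene_breakdown(one, fixture_panel())
  expect_equal(bd$per_category$FA, 1)
  expect_equal(bd$non_brca_genes, 1)
})

test_that("the syndrome crosstab matches the published cells", {
  ct <- syndrome_crosstab(fixture_calls(), fixture_panel(), fixture_flags())
  expect_equal(ct$fulfilling, c(18, 1, 2))
  expect_equal(ct$not_fulfilling, c(0, 2, 3))
  expect_equal(ct$carriers, c(18, 3, 5))
  ct0 <- syndrome_crosstab(fixture_calls()[0, ], fixture_panel(),
                           fixture_flags())
  expect_equal(ct0$carriers, c(0, 0, 0))
})

test_that("the pooled t-test matches the textbook formula", {
  a <- c(30, 32, 34, 36); b <- c(40, 42, 44, 46)
  # independent oracle: pooled-variance formula computed by hand
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), length(a) + length(b) - 2)
  r <- onset_age_ttest(a, b, variant = "pooled")
  expect_equal(r$t, t_oracle)
  expect_equal(r$p, p_oracle)
  expect_equal(r$df, 6)
  # identical constant groups: no difference
  r <- onset_age_ttest(c(40, 40, 40), c(40, 40, 40))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # Welch differs from pooled for unequal variances and sizes
  a2 <- c(28, 41, 33, 39, 50); b2 <- c(45, 46)
  expect_false(isTRUE(all.equal(
    onset_age_ttest(a2, b2, "pooled")$p,
    onset_age_ttest(a2, b2, "welch")$p)))
  expect_error(onset_age_ttest(c(40), b), "at least two")
})
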