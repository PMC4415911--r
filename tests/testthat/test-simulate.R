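test_that("a cohort is a deterministic function of its configuration", {
  cfg <- simulation_config(seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # and a different seed gives different draws
  c2 <- simulate_cohort(simulation_config(seed = 8))
  expect_false(identical(a$variants, c2$variants))
})

test_that("configuration validation catches infeasible requests", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, fraction_synonymous = 0.8,
                                 fraction_deep_intronic = 0.5), "<= 1")
  # a het missense spike in a recessive gene can never satisfy the
  # inheritance criterion
  bad <- data.frame(gene = "MUTYH", class = "missense", zygosity = "het",
                    count = 1L)
  expect_error(simulate_cohort(simulation_config(seed = 1, spike_plan = bad)),
               "infeasible")
  # but a canonical splice het spike in the same gene is allowed
  ok <- data.frame(gene = "MUTYH", class = "splicing", zygosity = "het",
                   count = 1L)
  cohort <- simulate_cohort(simulation_config(seed = 1, spike_plan = ok,
                                              n_families = 2,
                                              background_per_sample = 5))
  expect_equal(sum(cohort$truth$label == "spiked_pathogenic"), 1)
})

test_that("the pipeline recovers exactly the spiked variants", {
  cfg <- simulation_config(seed = 101, n_families = 10,
                           background_per_sample = 100)
  cohort <- simulate_cohort(cfg)
  res <- screen_variants(cohort$variants, cohort$panel, cohort$curation)
  tr <- merge(res, cohort$truth, by = "variant_id")
  spiked <- tr$label == "spiked_pathogenic"
  expect_equal(sum(spiked), 10)
  expect_true(all(tr$deleterious[spiked]))          # sensitivity 1
  expect_false(any(tr$deleterious[!spiked]))        # specificity 1
})

test_that("constructed false positives are recovered in exactly their number", {
  cfg <- simulation_config(seed = 5, n_families = 6,
                           background_per_sample = 40,
                           n_adversarial_missense = 4)
  cohort <- simulate_cohort(cfg)
  res <- screen_variants(cohort$variants, cohort$panel, cohort$curation)
  tr <- merge(res, cohort$truth, by = "variant_id")
  fp <- sum(tr$deleterious & tr$label == "background")
  expect_equal(fp, 4)
})

test_that("an all-synonymous background with no spikes retains nothing", {
  cfg <- simulation_config(seed = 3, n_families = 3,
                           background_per_sample = 30,
                           fraction_synonymous = 1,
                           fraction_deep_intronic = 0,
                           spike_plan = default_spike_plan()[0, ])
  cohort <- simulate_cohort(cfg)
  res <- screen_variants(cohort$variants, cohort$panel, cohort$curation)
  expect_true(all(res$final_state == "excluded"))
})

test_that("simulated pedigrees satisfy the eligibility rules", {
  cfg <- simulation_config(seed = 21, n_families = 15,
                           background_per_sample = 0)
  cohort <- simulate_cohort(cfg)
  for (ped in cohort$pedigrees) {
    el <- eligibility_from_pedigree(ped)
    expect_true(el$eligible, label = ped$family_id)
  }
})

test_that("marker profiles follow the configured instability rates", {
  cfg <- simulation_config(seed = 13)
  mp <- generate_marker_profiles(cfg, n_deficient = 1000, n_proficient = 0)
  markers <- marker_panel()
  for (grp in list(c("di", markers$nci_di, markers$extra_di),
                   c("emast", markers$emast),
                   c("mono", markers$nci_mono))) {
    rate <- cfg$marker_rates$deficient[[grp[1]]]
    cols <- grp[-1]
    obs <- mean(as.matrix(mp[, cols]) == "+")
    se <- sqrt(rate * (1 - rate) / (1000 * length(cols)))
    expect_lt(abs(obs - rate), 3 * se + 1e-9)
  }
  # degenerate rates
  cfg0 <- simulation_config(seed = 13, marker_rates = list(
    deficient = c(mono = 0, di = 0, emast = 0),
    proficient = c(mono = 0, di = 0, emast = 0)))
  mp0 <- classify_msi_table(generate_marker_profiles(cfg0, 20, 20))
  expect_true(all(mp0$NCI_D_status == "MSS"))
  expect_false(any(mp0$EMAST_positive))
  cfg1 <- simulation_config(seed = 13, marker_rates = list(
    deficient = c(mono = 0, di = 0, emast = 1),
    proficient = c(mono = 0, di = 0, emast = 0)))
  mp1 <- classify_msi_table(generate_marker_profiles(cfg1, 20, 0))
  expect_true(all(mp1$EMAST_positive))
})

test_that("deficient samples show more instability than proficient ones", {
  cfg <- simulation_config(seed = 31)
  mp <- classify_msi_table(generate_marker_profiles(cfg, 200, 200))
  hit <- mp$NCI_D_status != "MSS" | mp$EMAST_positive
  expect_gt(mean(hit[mp$MMR_status == "deficient"]),
            mean(hit[mp$MMR_status == "proficient"]))
})

test_that("distractors violate exactly their assigned defect", {
  d <- simulate_distractors(30, seed = 4)
  res <- screen_variants(d$variants, fixture_panel(), d$curation)
  tr <- merge(res, d$expected, by = "variant_id")
  cascade_modes <- c("region", "class", "frequency", "inheritance")
  for (i in seq_len(nrow(tr))) {
    if (tr$mode[i] %in% cascade_modes) {
      expect_identical(tr$exclusion_reason[i], tr$mode[i])
    } else {
      expect_identical(tr$final_state[i], "retained")
      expect_false(tr$deleterious[i])
    }
  }
})
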