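test_that("pedigree files parse with resolved parents and one proband", {
  ped <- read_pedigree(hc_example("family49_reconstruction.ped"))
  expect_s3_class(ped, "pedigree")
  expect_identical(ped$proband_id, "PB")
  pro <- ped$members[ped$members$id == "PB", ]
  expect_equal(pro$age_dx[[1]][1], 32)
  expect_true(all(c("Breast", "Ovary") %in% pro$cancer_types[[1]]))

  write_ped <- function(lines) {
    f <- withr::local_tempfile(fileext = ".ped", .local_envir = parent.frame())
    writeLines(lines, f)
    f
  }
  header <- paste("Family", "Individual", "Father", "Mother", "Sex",
                  "Phenotype", "CancerType", "AgeDx", "Proband", sep = "\t")
  # single individual is a valid pedigree of size 1
  ped1 <- read_pedigree(write_ped(c(header,
    "F1\tA\t0\t0\t2\t2\tBreast\t40\t1")))
  expect_equal(nrow(ped1$members), 1)
  # dangling parent reference
  expect_error(read_pedigree(write_ped(c(header,
    "F1\tA\tGHOST\t0\t2\t2\tBreast\t40\t1"))), "GHOST")
  # zero probands
  expect_error(read_pedigree(write_ped(c(header,
    "F1\tA\t0\t0\t2\t2\tBreast\t40\t0"))), "proband")
  # two probands
  expect_error(read_pedigree(write_ped(c(header,
    "F1\tA\t0\t0\t2\t2\tBreast\t40\t1",
    "F1\tB\t0\t0\t2\t2\tBreast\t41\t1"))), "proband")
})

test_that("eligibility rules use age and lineage-specific counts", {
  expect_true(check_eligibility(30, 1, 0))
  expect_true(check_eligibility(35, 1, 0))   # closed bound at 35
  expect_false(check_eligibility(36, 1, 1))
  expect_false(check_eligibility(40, 1, 1))
  expect_true(check_eligibility(40, 3, 2))
  expect_true(check_eligibility(50, 2, 2))   # closed bound at 50
  expect_false(check_eligibility(51, 2, 2))
  expect_true(check_eligibility(55, 3, 3))
  expect_false(check_eligibility(30, 0, 0))
  ped <- read_pedigree(hc_example("family22_reconstruction.ped"))
  el <- eligibility_from_pedigree(ped)
  expect_equal(el$proband_age, 37)
  expect_equal(el$same_lineage_count, 5)
  expect_true(el$eligible)
})

test_that("segregation counts carriers and judges completeness on affected members", {
  ped49 <- read_pedigree(hc_example("family49_reconstruction.ped"))
  s <- score_segregation(ped49, "MSH3:c.199_207del9")
  expect_identical(s$display, "5/5")
  expect_identical(s$completeness, "complete")

  ped22 <- read_pedigree(hc_example("family22_reconstruction.ped"))
  # every tested affected member carries the BRCA1 variant; the one
  # non-carrier is unaffected, so segregation is complete at 5/6
  s <- score_segregation(ped22, "BRCA1:c.2110_2111delAA")
  expect_identical(s$display, "5/6")
  expect_identical(s$completeness, "complete")
  # one tested affected member does not carry the MSH3 variant
  s <- score_segregation(ped22, "MSH3:c.162_179del18")
  expect_identical(s$display, "5/6")
  expect_identical(s$completeness, "incomplete")
  s <- score_segregation(ped22, "MUTYH:c.850-2A>G")
  expect_identical(s$display, "1/2")
  expect_error(score_segregation(ped22, "GENE:c.1A>G"), "unknown")
})

test_that("a variant nobody was tested for displays U/A", {
  ped <- read_pedigree(hc_example("family49_reconstruction.ped"))
  ped$genotypes$status <- "untested"
  s <- score_segregation(ped, "MSH3:c.199_207del9")
  expect_identical(s$display, "U/A")
  expect_identical(s$completeness, "unavailable")
  expect_equal(s$tested, 0L)
})

test_that("a fully-carried, fully-affected tested set is complete by construction", {
  ped <- read_pedigree(hc_example("family49_reconstruction.ped"))
  s <- score_segregation(ped, "MSH3:c.199_207del9")
  g <- ped$genotypes[ped$genotypes$status != "untested", ]
  aff <- ped$members$affected[match(g$individual, ped$members$id)]
  if (s$positive == s$tested && all(aff)) {
    expect_identical(s$completeness, "complete")
  }
})
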