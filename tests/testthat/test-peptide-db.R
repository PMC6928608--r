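test_that("bundle JSON round trip is byte-identical", {
  b <- generateFixture(seed = 11, nPeptides = 25, nEnzymes = 4)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  saveBundle(b, f1)
  b2 <- loadBundle(f1)
  saveBundle(b2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(peptides(b2)$sequence, peptides(b)$sequence)
  expect_equal(peptides(b2)$ec50_uM, peptides(b)$ec50_uM)
  expect_identical(specificityRules(b2), specificityRules(b))
})

test_that("TSV export/import reproduces the tables", {
  b <- generateFixture(seed = 12, nPeptides = 15, nEnzymes = 3)
  d <- withr::local_tempdir()
  exportBundleTSV(b, d)
  expect_setequal(list.files(d), c("peptides.tsv", "enzymes.tsv",
                                   "rules.tsv", "activities.tsv"))
  b2 <- importBundleTSV(d)
  expect_identical(peptides(b2)$sequence, peptides(b)$sequence)
  expect_identical(peptides(b2)$activity, peptides(b)$activity)
  expect_equal(peptides(b2)$ec50_uM, peptides(b)$ec50_uM)
  expect_identical(specificityRules(b2), specificityRules(b))
})

test_that("schema violations are rejected with named causes", {
  expect_error(makeBundle(peptides = data.frame(
    id = 1L, name = "x", sequence = "AP", activity = "flying")),
    "unknown activity.*flying")
  expect_error(makeBundle(peptides = data.frame(
    id = c(1L, 1L), name = "x", sequence = c("AP", "VY"),
    activity = "ACE inhibitor")), "duplicate peptide id")
  expect_error(makeBundle(peptides = data.frame(
    id = 1L, name = "x", sequence = "AP", activity = "ACE inhibitor",
    inchikey = "TOO-SHORT")), "inchikey")
  expect_error(makeBundle(
    enzymes = data.frame(enzyme_id = 1L, name = "e", ec_number = "1",
                         merops_id = NA),
    rules = data.frame(connection_id = 1L, enzyme_id = 1L,
                       recognition_seq = "AK", cut_residue_index = 3L,
                       side = "after")), "cut_residue_index")
})

test_that("non-positive EC50/IC50 is demoted to absent with a warning", {
  expect_warning(
    b <- makeBundle(peptides = data.frame(
      id = 9473L, name = "ACE inhibitor", sequence = "GHS",
      activity = "ACE inhibitor", ec50_uM = 0)),
    "non-positive.*9473")
  expect_true(is.na(peptides(b)$ec50_uM))
  # downstream: B undefined because the only hit has no usable value
  pr <- buildProfile("AGHSV", b, "ACE inhibitor")
  expect_true(is.na(potencyB(pr)))
})

test_that("sequence search separates substring from exact semantics", {
  b <- makeBundle(peptides = data.frame(
    id = 1:4, name = c("VPP", "IPP", "VPPK", "VPP opioid"),
    sequence = c("VPP", "IPP", "VPPK", "VPP"),
    activity = c("ACE inhibitor", "ACE inhibitor", "ACE inhibitor",
                 "opioid")))
  expect_equal(sort(searchPeptides(b, "sequence", "VPP")$id), c(1L, 3L, 4L))
  exact <- searchPeptides(b, "sequence", "VPP", exact = TRUE)
  # a peptide with k activity annotations returns k records
  expect_equal(sort(exact$id), c(1L, 4L))
  expect_setequal(exact$activity, c("ACE inhibitor", "opioid"))
  # sequence matching is case-sensitive (D- vs L-residues)
  b2 <- makeBundle(peptides = data.frame(
    id = 1:2, name = "x", sequence = c("FhL", "FHL"),
    activity = "ACE inhibitor"))
  expect_equal(searchPeptides(b2, "sequence", "FhL", exact = TRUE)$id, 1L)
})

test_that("id, mass and length searches ignore the exact flag", {
  b <- generateFixture(seed = 13, nPeptides = 30, nEnzymes = 2)
  expect_lte(nrow(searchPeptides(b, "id", 5L)), 1L)
  expect_identical(searchPeptides(b, "id", 5L, exact = TRUE),
                   searchPeptides(b, "id", 5L))
  lens <- nchar(peptides(b)$sequence)
  n8 <- sum(lens == 8L)
  expect_equal(nrow(searchPeptides(b, "length", 8L)), n8)
  masses <- vapply(peptides(b)$sequence,
                   function(s) peptideMasses(s)[["average"]], 0)
  rng <- c(500, 900)
  expect_equal(nrow(searchPeptides(b, "mass", rng)),
               sum(masses >= rng[1] & masses <= rng[2]))
  expect_error(searchPeptides(b, "mass", c(900, 500)), "closed range")
  expect_error(searchPeptides(b, "banana", "x"))
})

test_that("name/activity matching is case-insensitive substring", {
  b <- generateFixture(seed = 14, nPeptides = 40, nEnzymes = 2)
  sub <- searchPeptides(b, "activity", "INHIBITOR")
  expect_true(all(grepl("inhibitor", sub$activity, ignore.case = TRUE)))
  expect_gt(nrow(sub), 0)
  exact <- searchPeptides(b, "activity", "inhibitor", exact = TRUE)
  expect_true(all(exact$activity == "inhibitor"))
})

test_that("exact results are a subset of substring results", {
  b <- generateFixture(seed = 15, nPeptides = 50, nEnzymes = 3)
  queries <- list(name = "ACE", activity = "inhibitor",
                  sequence = substr(peptides(b)$sequence[1], 1, 2))
  for (field in names(queries)) {
    exact <- searchPeptides(b, field, queries[[field]], exact = TRUE)
    loose <- searchPeptides(b, field, queries[[field]], exact = FALSE)
    expect_true(all(exact$id %in% loose$id))
  }
})

test_that("findSequencesContaining agrees with the occurrence scan", {
  b <- generateFixture(seed = 16, nPeptides = 40, nEnzymes = 2)
  for (frag in c("VP", "A", "GG")) {
    hits <- findSequencesContaining(frag, b)
    oracle <- vapply(peptides(b)$sequence,
                     function(s) nrow(bruteForceOccurrences(frag, s)) > 0,
                     NA, USE.NAMES = FALSE)
    expect_setequal(hits$id, peptides(b)$id[oracle])
  }
  expect_equal(nrow(findSequencesContaining("WWWWWWWW", b)), 0L)
})

test_that("fixture generation is deterministic and honors its knobs", {
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  saveBundle(generateFixture(seed = 7, nPeptides = 50, nEnzymes = 5), f1)
  saveBundle(generateFixture(seed = 7, nPeptides = 50, nEnzymes = 5), f2)
  expect_identical(readLines(f1), readLines(f2))

  b <- generateFixture(seed = 8, nPeptides = 60, nEnzymes = 4,
                       ec50Fraction = 0)
  expect_true(all(is.na(peptides(b)$ec50_uM)))
  pr <- buildProfile(peptides(b)$sequence[1], b, "ALL")
  expect_true(all(is.na(precursorPotency(pr)$B)))

  mix <- c("ACE inhibitor" = 0.5, "opioid" = 0.3, "antibacterial" = 0.2)
  b2 <- generateFixture(seed = 9, nPeptides = 40, nEnzymes = 2,
                        activityMix = mix)
  counts <- table(peptides(b2)$activity)
  expect_equal(as.integer(counts[names(mix)]), c(20L, 12L, 8L))
  lens <- nchar(peptides(b2)$sequence)
  expect_true(all(lens >= 2 & lens <= 15))
  ec <- peptides(b2)$ec50_uM
  expect_true(all(is.na(ec) | (ec >= 0.01 & ec <= 1000)))
})
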