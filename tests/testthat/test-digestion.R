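test_that("a carboxyl-side Phe rule cleaves the worked precursor at 4 and 8", {
  b <- apBundle()
  sites <- cleavageSites("RWAFAPGFAPGHIP", b, 1L)
  expect_equal(sites$bond, c(4L, 8L))
  dg <- digestSequence("RWAFAPGFAPGHIP", b, 1L)
  expect_equal(digestFragments(dg)$sequence, c("RWAF", "APGF", "APGHIP"))
  expect_equal(digestFragments(dg)$start, c(1L, 5L, 9L))
  expect_equal(digestFragments(dg)$end, c(4L, 8L, 14L))
  expect_equal(degreeOfHydrolysis(dg), 2 / 13 * 100)
})

test_that("digests handle the no-cut and all-cut extremes", {
  b <- plasminLikeBundle()
  dg <- digestSequence("GAVLIF", b, 1L)   # no K or R anywhere
  expect_equal(nrow(digestFragments(dg)), 1L)
  expect_equal(digestFragments(dg)$sequence, "GAVLIF")
  expect_equal(degreeOfHydrolysis(dg), 0)

  dg2 <- digestSequence("KKKKK", b, 1L)   # every bond follows a K
  expect_equal(nrow(digestFragments(dg2)), 5L)
  expect_true(all(nchar(digestFragments(dg2)$sequence) == 1L))
  expect_equal(degreeOfHydrolysis(dg2), 100)
})

test_that("multi-enzyme sites are the union of single-enzyme sites", {
  set.seed(77)
  for (i in 1:10) {
    b <- generateFixture(seed = 30 + i, nPeptides = 5, nEnzymes = 4)
    prec <- randomLSequence(sample(20:60, 1))
    ids <- enzymes(b)$enzyme_id
    together <- cleavageSites(prec, b, ids)$bond
    alone <- sort(unique(unlist(lapply(ids, function(e)
      cleavageSites(prec, b, e)$bond))))
    expect_equal(together, alone)
    # permutation invariance and per-enzyme containment
    expect_equal(cleavageSites(prec, b, rev(ids))$bond, together)
    for (e in ids)
      expect_true(all(cleavageSites(prec, b, e)$bond %in% together))
    # fragments tile the precursor
    dg <- digestSequence(prec, b, ids)
    frag <- digestFragments(dg)
    expect_equal(paste(frag$sequence, collapse = ""), prec)
    expect_equal(frag$start[1], 1L)
    expect_equal(frag$end[nrow(frag)], nchar(prec))
    expect_true(degreeOfHydrolysis(dg) >= 0 && degreeOfHydrolysis(dg) <= 100)
  }
})

test_that("merged contributors record every (enzyme, connection) pair", {
  b <- plasminLikeBundle()
  sites <- cleavageSites("AKRGPAK", b, c(1L, 2L))
  # bond 2 (K-) and 3 (R-) from plasmin-like; GPA rule cuts after P (bond
  # 5); the terminal K would map to bond 7, outside [1, N-1], and is dropped
  expect_equal(sites$bond, c(2L, 3L, 5L))
  expect_equal(sites$contributors[[1]]$connection_id, 1L)
  expect_equal(sites$contributors[[2]]$connection_id, 2L)
  expect_equal(sites$contributors[[3]]$connection_id, 3L)
})

test_that("bonds flanked by D-residues or phosphoserine resist by default", {
  b <- apBundle()
  # D-alanine after the recognition Phe blocks the cut unless relaxed
  expect_equal(nrow(cleavageSites("RWFaPG", b, 1L)), 0L)
  expect_equal(cleavageSites("RWFaPG", b, 1L, cleaveModified = TRUE)$bond, 3L)
  expect_equal(nrow(cleavageSites("RWFBPG", b, 1L)), 0L)
  expect_equal(cleavageSites("RWFAPG", b, 1L)$bond, 3L)
})

test_that("release scores count whole-fragment matches only", {
  b <- apBundle()   # AP annotated; digest never frees AP itself
  dg <- digestSequence("RWAFAPGFAPGHIP", b, 1L)
  rel <- releasedBioactive(dg, b, "ACE inhibitor")
  expect_equal(rel$d_released, 0L)
  expect_equal(rel$A_E, 0)
  expect_equal(rel$W, 0)          # A > 0, nothing released

  b2 <- apBundle(withAPGF = TRUE) # APGF is itself annotated
  dg2 <- digestSequence("RWAFAPGFAPGHIP", b2, 1L)
  rel2 <- releasedBioactive(dg2, b2, "ACE inhibitor")
  expect_equal(rel2$d_released, 1L)
  expect_equal(rel2$A_E, 1 / 14)
})

test_that("released scores stay dominated by the occurrence scores", {
  set.seed(88)
  for (i in 1:8) {
    b <- generateFixture(seed = 40 + i, nPeptides = 40, nEnzymes = 3)
    prec <- randomLSequence(50)
    dg <- digestSequence(prec, b, enzymes(b)$enzyme_id)
    rel <- releasedBioactive(dg, b, "ALL")
    pot <- precursorPotency(buildProfile(prec, b, "ALL"))
    for (j in seq_len(nrow(rel))) {
      A <- pot$A[pot$activity == rel$activity[j]]
      expect_lte(rel$A_E[j], A)
      if (!is.na(rel$W[j]))
        expect_true(rel$W[j] >= 0 && rel$W[j] <= 1)
      if (!is.na(rel$V[j]))
        expect_true(rel$V[j] >= 0 && rel$V[j] <= 1)
      if (!is.na(rel$B_E[j]) && !is.na(rel$B[j]))
        expect_lte(rel$B_E[j], rel$B[j] + 1e-12)
    }
  }
})

test_that("specificity search matches rules field by field", {
  b <- plasminLikeBundle()
  hit <- findEnzymesWithSpecificity(b, cuttingResidue = "K", side = "after")
  expect_equal(hit$name, "plasmin-like proteinase")
  expect_equal(hit$matched_rules[[1]]$connection_id, 1L)
  # omitted fields match anything: both plasmin-like rules
  both <- findEnzymesWithSpecificity(b, side = "after")
  expect_setequal(both$enzyme_id, c(1L, 2L))
  expect_equal(nrow(findEnzymesWithSpecificity(b, cuttingResidue = "W")), 0L)
  multi <- findEnzymesWithSpecificity(b, recognitionSeq = "GPA")
  expect_equal(multi$name, "zingipain-like proteinase")
})

test_that("release events of the worked example are 1N/1C/2N/2C", {
  b <- apBundle()
  rep <- enzymesForRelease("AP", "RWAFAPGFAPGHIP", b)[["AP"]]
  expect_equal(rep$occurrences, data.frame(start = c(5L, 9L),
                                           end = c(6L, 10L)))
  ev <- rep$events
  expect_equal(ev$label, c("1N", "1C", "2N", "2C"))
  expect_equal(ev$bond, c(4L, 6L, 8L, 10L))
  expect_false(any(ev$terminal))
  # the Phe-carboxyl enzyme catalyzes event 1N (bond 4) but not 1C (bond 6)
  expect_equal(ev$enzymes[[1]]$enzyme_id, 1L)
  expect_equal(ev$enzymes[[1]]$cutting_seq, "F-")
  expect_equal(nrow(ev$enzymes[[2]]), 0L)
  # enzyme list also names event 2N (bond 8, after the second Phe)
  expect_equal(ev$enzymes[[3]]$enzyme_id, 1L)
})

test_that("terminal occurrences need no cleavage and misses are not errors", {
  b <- apBundle()
  whole <- enzymesForRelease("RWAFAPGFAPGHIP", "RWAFAPGFAPGHIP",
                             b)[["RWAFAPGFAPGHIP"]]
  expect_equal(whole$events$label, c("1N", "1C"))
  expect_true(all(whole$events$terminal))
  expect_true(all(is.na(whole$events$bond)))
  miss <- enzymesForRelease("WWW", "RWAFAPGFAPGHIP", b)[["WWW"]]
  expect_equal(nrow(miss$occurrences), 0L)
  expect_equal(nrow(miss$events), 0L)
})

test_that("event bonds always come from the enzymes' own site sets", {
  set.seed(99)
  for (i in 1:5) {
    b <- generateFixture(seed = 50 + i, nPeptides = 20, nEnzymes = 3)
    prec <- randomLSequence(40)
    pep <- substr(prec, 10, 12)
    rep <- enzymesForRelease(pep, prec, b)[[1]]
    allSites <- cleavageSites(prec, b, enzymes(b)$enzyme_id)
    ev <- rep$events
    for (j in seq_len(nrow(ev))) {
      df <- ev$enzymes[[j]]
      if (nrow(df))
        expect_true(ev$bond[j] %in% allSites$bond)
    }
  }
})
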