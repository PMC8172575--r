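mkInv <- function(sf, lf, source = "s1") {
  prepareInventory(SenseInventory(data.frame(sf = sf, lf = lf,
                                             source = source)))
}

test_that("training filter splits by short-form equality above the cutoff", {
  # same normalized SF, identical LFs: a potential positive
  inv <- mkInv(c("MS", "ms"), c("mitral stenosis", "mitral stenosis"))
  tc <- generateTrainingCandidates(inv)
  expect_equal(nrow(tc$positives), 1)
  expect_equal(nrow(tc$pertinent_negatives), 0)
  expect_equal(tc$positives$prefilter_score, 1)
  # different SF, near-identical LFs: a pertinent negative (ratio 36/37)
  inv2 <- mkInv(c("OC", "OCS"),
                c("oral contraceptive", "oral contraceptives"))
  tc2 <- generateTrainingCandidates(inv2)
  expect_equal(nrow(tc2$positives), 0)
  expect_equal(nrow(tc2$pertinent_negatives), 1)
  expect_equal(tc2$pertinent_negatives$prefilter_score, 36 / 37)
  # dissimilar LFs fall below the cutoff entirely
  inv3 <- mkInv(c("X", "x"), c("alpha", "gamma"))
  expect_true(oracleRatio("alpha", "gamma") <= 0.8)
  tc3 <- generateTrainingCandidates(inv3)
  expect_equal(nrow(tc3$positives) + nrow(tc3$pertinent_negatives), 0)
  # fewer than two records: empty, not an error
  tc4 <- generateTrainingCandidates(mkInv("A", "alpha"))
  expect_equal(nrow(tc4$positives), 0)
})

test_that("the 0.8 cutoff is strict, the 0.5 candidate cutoff inclusive", {
  # construct a pair with ratio exactly 0.8: lengths 4+6, distance 2
  expect_equal(oracleRatio("abcd", "abcdef"), 0.8)
  inv <- mkInv(c("A", "a"), c("abcd", "abcdef"))
  tc <- generateTrainingCandidates(inv, ratioThreshold = 0.8)
  expect_equal(nrow(tc$positives), 0)   # strictly greater required
  # partial ratio exactly at 0.5 is kept
  p <- partialRatio("ab", "zz")
  inv2 <- mkInv(c("B", "b"), c("ab", "zz"))
  got <- generateCandidatePairs(inv2, partialThreshold = p)
  expect_equal(nrow(got), 1)
})

test_that("candidate generation equals the brute-force all-pairs oracle", {
  set.seed(21)
  lfs <- c("aortic stenosis", "aortic stenoses", "stenosis of aorta",
           "mitral valve", "mitral valves", "bowel injury", "brain injury",
           "renal failure", "renal failures", "failure renal")
  inv <- prepareInventory(SenseInventory(data.frame(
    sf = sample(c("AS", "MV", "XX"), 20, replace = TRUE),
    lf = sample(lfs, 20, replace = TRUE), source = "s1")))
  got <- generateCandidatePairs(inv)
  rec <- records(inv)
  pn <- normalizeForPairing(rec$lf)
  want <- do.call(rbind, lapply(seq_len(nrow(rec) - 1), function(i) {
    do.call(rbind, lapply((i + 1):nrow(rec), function(j) {
      if (rec$norm_sf[i] != rec$norm_sf[j]) return(NULL)
      score <- oraclePartial(pn[i], pn[j])
      if (score < 0.5) return(NULL)
      data.frame(a = min(rec$record_id[i], rec$record_id[j]),
                 b = max(rec$record_id[i], rec$record_id[j]))
    }))
  }))
  expect_setequal(paste(got$record_id_a, got$record_id_b),
                  paste(want$a, want$b))
})

test_that("blocking excludes identical long forms under different short forms", {
  inv <- mkInv(c("AB", "CD"), c("same phrase", "same phrase"))
  expect_equal(nrow(generateCandidatePairs(inv)), 0)
  # three mutually similar records in one block give all three pairs
  inv2 <- mkInv(c("AS", "as", "A.S."),
                c("aortic stenosis", "aortic stenoses", "aortic stenosis"))
  expect_equal(nrow(generateCandidatePairs(inv2)), 3)
})

test_that("candidate pairs are invariant under record reordering", {
  sf <- c("AS", "as", "MV", "AS", "MV")
  lf <- c("aortic stenosis", "aortic stenoses", "mitral valve",
          "stenosis aortic", "mitral valves")
  inv <- mkInv(sf, lf)
  perm <- c(4, 2, 5, 1, 3)
  invP <- mkInv(sf[perm], lf[perm])
  asContent <- function(inv, pairs) {
    rec <- records(inv)
    key <- function(id) paste(rec$sf[match(id, rec$record_id)],
                              rec$lf[match(id, rec$record_id)])
    apply(cbind(key(pairs$record_id_a), key(pairs$record_id_b)), 1,
          function(r) paste(sort(r), collapse = " | "))
  }
  expect_setequal(asContent(inv, generateCandidatePairs(inv)),
                  asContent(invP, generateCandidatePairs(invP)))
})

test_that("raising either threshold never adds pairs", {
  set.seed(33)
  inv <- mkInv(sample(c("AA", "aa", "BB"), 15, replace = TRUE),
               sample(c("alpha beta", "alpha betas", "alpha gamma",
                        "delta phrase"), 15, replace = TRUE))
  lo <- generateCandidatePairs(inv, partialThreshold = 0.4)
  hi <- generateCandidatePairs(inv, partialThreshold = 0.7)
  expect_true(all(paste(hi$record_id_a, hi$record_id_b) %in%
                    paste(lo$record_id_a, lo$record_id_b)))
  tlo <- generateTrainingCandidates(inv, ratioThreshold = 0.5)
  thi <- generateTrainingCandidates(inv, ratioThreshold = 0.9)
  expect_true(all(paste(thi$positives$record_id_a,
                        thi$positives$record_id_b) %in%
                    paste(tlo$positives$record_id_a,
                          tlo$positives$record_id_b)))
})

test_that("annotation sampling sizes by ceiling and is seed-reproducible", {
  pairs <- data.frame(record_id_a = formatId("R", 1:1000),
                      record_id_b = formatId("R", 1001:2000))
  s1 <- sampleForAnnotation(pairs, 0.01, seed = 4)
  expect_equal(nrow(s1), 10)
  expect_identical(s1, sampleForAnnotation(pairs, 0.01, seed = 4))
  expect_false(identical(s1, sampleForAnnotation(pairs, 0.01, seed = 5)))
  expect_equal(nrow(sampleForAnnotation(pairs, 1.0, seed = 4)), 1000)
  expect_equal(nrow(sampleForAnnotation(pairs[1:5, ], 0.01, seed = 4)), 1)
  expect_equal(nrow(sampleForAnnotation(pairs[0, ], 0.01, seed = 4)), 0)
})
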