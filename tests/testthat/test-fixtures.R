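test_that("concept banks are reproducible and well-formed", {
  b1 <- generateConceptBank(40, seed = 2)
  b2 <- generateConceptBank(40, seed = 2)
  expect_identical(b1, b2)
  b3 <- generateConceptBank(40, seed = 3)
  expect_false(identical(b1$concepts$lf, b3$concepts$lf))
  con <- b1$concepts
  expect_equal(nrow(con), 40)
  expect_equal(anyDuplicated(con$lf), 0L)
  expect_equal(anyDuplicated(con$concept_id), 0L)
  # the abbreviation is always the upper-cased initials of the long form
  inits <- vapply(strsplit(con$lf, " "), function(w)
    toupper(paste(substr(w, 1, 1), collapse = "")), "")
  expect_identical(con$sf, inits)
  expect_true(all(nchar(con$sf) %in% 2:4))
  expect_error(generateConceptBank(0), "at least 1")
  expect_error(generateConceptBank(10, ambiguityRate = 1), "ambiguityRate")
})

test_that("ambiguity rate controls shared abbreviations", {
  # no ambiguity: all abbreviations distinct
  b0 <- generateConceptBank(30, ambiguityRate = 0, seed = 5)
  expect_equal(anyDuplicated(b0$concepts$sf), 0L)
  # high ambiguity: a clear majority of concepts reuse an abbreviation
  b9 <- generateConceptBank(200, ambiguityRate = 0.5, seed = 5)
  reused <- sum(duplicated(b9$concepts$sf))
  # binomial(199, 0.5): expect ~100 reuses, allow 4 sigma (~28)
  expect_gt(reused, 70)
  expect_lt(reused, 130)
})

test_that("generated inventories carry consistent ground truth", {
  bank <- generateConceptBank(30, seed = 7)
  fx <- generateInventories(bank, nSources = 3, seed = 7)
  rec <- records(fx$inventory)
  # first source covers every concept; all sources present in the merge
  expect_setequal(fx$truth$concept_id[grepl("source01", rec$source)],
                  bank$concepts$concept_id)
  expect_setequal(unique(rec$source),
                  c("source01", "source02", "source03"))
  # truth covers every record exactly once
  expect_identical(sort(fx$truth$record_id), sort(rec$record_id))
  # each record's long form is a lexical variant of its concept: the
  # normalized forms still share their word multiset up to plural/genitive
  cid <- fx$truth$concept_id[match(rec$record_id, fx$truth$record_id)]
  canon <- bank$concepts$lf[match(cid, bank$concepts$concept_id)]
  sim <- tokenSetRatio(normalizeForPairing(rec$lf),
                       normalizeForPairing(canon))
  expect_true(all(sim > 0.6))
  # determinism of the whole bundle
  fx2 <- generateInventories(bank, nSources = 3, seed = 7)
  expect_identical(records(fx2$inventory), rec)
  expect_identical(fx2$labeled_pairs, fx$labeled_pairs)
})

test_that("labeled pairs are consistent with the concept truth", {
  bank <- generateConceptBank(25, ambiguityRate = 0.4, seed = 9)
  fx <- generateInventories(bank, seed = 9)
  lp <- fx$labeled_pairs
  cid <- function(id) fx$truth$concept_id[match(id, fx$truth$record_id)]
  expect_true(all((cid(lp$record_id_a) == cid(lp$record_id_b)) ==
                    (lp$label == 1)))
  # both classes present and no duplicated unordered pair
  expect_setequal(unique(lp$label), c(0, 1))
  key <- paste(pmin(lp$record_id_a, lp$record_id_b),
               pmax(lp$record_id_a, lp$record_id_b))
  expect_equal(anyDuplicated(key), 0L)
  # features were computed with the package featurizer
  expect_equal(lp$ratio,
               featurizePairs(lp$lf_a, lp$lf_b)$ratio)
})

test_that("variant and error rates are validated and honored at zero", {
  bank <- generateConceptBank(20, seed = 11)
  expect_error(generateInventories(bank, variantRates = list(case = 2)),
               "rates")
  expect_error(generateInventories(bank, errorRates = list(spelling = -1)),
               "rates")
  # all-zero variants: every record renders its concept verbatim
  fx <- generateInventories(bank, nSources = 2,
                            variantRates = list(case = 0, period = 0,
                                                slash = 0, plural = 0,
                                                genitive = 0, stopword = 0,
                                                swap = 0, misspell = 0),
                            seed = 11)
  rec <- records(fx$inventory)
  cid <- fx$truth$concept_id[match(rec$record_id, fx$truth$record_id)]
  expect_identical(rec$lf, bank$concepts$lf[match(cid,
                                                  bank$concepts$concept_id)])
  expect_identical(rec$sf, bank$concepts$sf[match(cid,
                                                  bank$concepts$concept_id)])
  expect_equal(nrow(fx$injected_errors), 0)
})

test_that("misspelling counts concentrate around the configured rate", {
  bank <- generateConceptBank(60, ambiguityRate = 0, seed = 13)
  rate <- 0.3
  fx <- generateInventories(bank, nSources = 3,
                            variantRates = list(case = 0, period = 0,
                                                plural = 0, genitive = 0,
                                                stopword = 0, swap = 0,
                                                misspell = rate),
                            seed = 13)
  rec <- records(fx$inventory)
  cid <- fx$truth$concept_id[match(rec$record_id, fx$truth$record_id)]
  canon <- bank$concepts$lf[match(cid, bank$concepts$concept_id)]
  hits <- sum(rec$lf != canon)
  n <- nrow(rec)
  # allow 3 sigma around the binomial mean; misspelling can only fail to
  # fire when no token is long enough, which the word bank avoids
  sigma <- sqrt(n * rate * (1 - rate))
  expect_gt(hits, n * rate - 3 * sigma)
  expect_lt(hits, n * rate + 3 * sigma)
})

test_that("injected errors are recorded and detected by the heuristics", {
  bank <- generateConceptBank(40, seed = 15)
  fx <- generateInventories(bank, nSources = 3,
                            errorRates = list(duplicate = 0.05,
                                              punctuation = 0.05,
                                              char_mismatch = 0.05,
                                              spelling = 0.05),
                            seed = 15)
  inj <- fx$injected_errors
  expect_gt(nrow(inj), 0)
  expect_true(all(inj$heuristic %in%
                    c("duplicate", "punctuation", "char_mismatch",
                      "spelling")))
  flags <- runQC(fx$inventory, fx$word_corpus)
  found <- paste(flags$record_id, flags$heuristic)
  want <- paste(inj$record_id, inj$heuristic)
  expect_true(all(want %in% found))  # 100% recall on injected errors
})

test_that("annotated corpora follow the Zipf head and labeled fraction", {
  bank <- generateConceptBank(50, ambiguityRate = 0, seed = 17)
  corpus <- generateAnnotatedCorpus(bank, 4000, labeledFraction = 1,
                                    seed = 17)
  expect_equal(nrow(corpus), 4000)
  counts <- table(factor(corpus$concept_id,
                         levels = bank$concepts$concept_id))
  # with s = 1.5 the first concept dominates the 50th by ~350x
  expect_gt(counts[1], counts[50] * 20)
  expect_true(all(diff(as.numeric(counts[1:3])) <= 0))
  # labels are the normalized canonical long forms
  lab <- corpus$sense[corpus$concept_id == bank$concepts$concept_id[1]]
  expect_true(all(lab == normalizeLongForm(bank$concepts$lf[1])))
  # partial labeling hits the requested fraction
  half <- generateAnnotatedCorpus(bank, 4000, labeledFraction = 0.5,
                                  seed = 17)
  frac <- mean(nzchar(half$sense))
  expect_gt(frac, 0.45); expect_lt(frac, 0.55)
  none <- generateAnnotatedCorpus(bank, 100, labeledFraction = 0, seed = 17)
  expect_false(any(nzchar(none$sense)))
  expect_error(generateAnnotatedCorpus(bank, 10, labeledFraction = 2),
               "labeledFraction")
})

test_that("pairwise F1 matches hand-counted partitions", {
  # identical partitions
  expect_equal(pairwiseF1(c(1, 1, 2), c("a", "a", "b"))$f1, 1)
  # predicted merges everything: truth {1,2},{3}: tp=1, pred=3, true=1
  res <- pairwiseF1(c(1, 1, 1), c(1, 1, 2))
  expect_equal(res$precision, 1 / 3)
  expect_equal(res$recall, 1)
  expect_equal(res$f1, 0.5)
  # predicted splits everything: precision 1 by convention? no pairs at all
  res2 <- pairwiseF1(1:3, c(1, 1, 2))
  expect_equal(res2$precision, 0)
  expect_equal(res2$recall, 0)
  expect_equal(res2$f1, 0)
  # both all-singletons scores 1
  expect_equal(pairwiseF1(1:4, 4:1)$f1, 1)
  expect_error(pairwiseF1(1:3, 1:4), "length")
})
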