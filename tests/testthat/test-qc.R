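test_that("intra-source duplicates are flagged after the first occurrence", {
  inv <- prepareInventory(SenseInventory(data.frame(
    sf = c("MS", "MS", "MS", "MS"),
    lf = c("mitral stenosis", "mitral stenosis", "mitral stenosis",
           "multiple sclerosis"),
    source = c("s1", "s1", "s2", "s1"))))
  f <- flagIntraSourceDuplicates(inv)
  # only the second s1 copy: the s2 copy is cross-source redundancy and
  # the different long form is a different record
  expect_equal(f$record_id, "R000002")
  expect_equal(f$heuristic, "duplicate")
  expect_match(f$detail, "R000001")
  # clean inventory yields zero rows with the right columns
  f0 <- flagIntraSourceDuplicates(prepareInventory(makeToyInventory()))
  expect_equal(nrow(f0), 0)
  expect_equal(colnames(f0), c("record_id", "heuristic", "detail"))
})

test_that("punctuation heuristic allows one trailing period only", {
  expect_false(flagPunctuation("O.C."))
  expect_false(flagPunctuation("MS"))
  expect_true(flagPunctuation("..MS"))
  expect_true(flagPunctuation("MS.."))
  expect_true(flagPunctuation("-MS"))
  expect_true(flagPunctuation("MS-"))
  expect_false(flagPunctuation("D/C"))       # single internal punctuation
  expect_true(flagPunctuation("D//C"))       # internal run
  # sub-rules can be disabled independently
  expect_false(flagPunctuation("-MS", leading = FALSE))
  expect_false(flagPunctuation("MS-", trailing = FALSE))
  expect_false(flagPunctuation("..MS", leading = FALSE, runs = FALSE))
  expect_equal(flagPunctuation(c("OK", "..x")), c(FALSE, TRUE))
})

test_that("character-mismatch heuristic is case-folded set membership", {
  expect_false(flagCharMismatch("MS", "multiple sclerosis"))
  expect_false(flagCharMismatch("OC", "Oral Contraceptives"))
  expect_true(flagCharMismatch("qd", "every day"))
  expect_false(flagCharMismatch("T2", "type 2 diabetes"))
  expect_true(flagCharMismatch("T3", "type 2 diabetes"))
  # punctuation in the short form is ignored; order is not considered
  expect_false(flagCharMismatch("C.O.", "oral contraceptive"))
  expect_false(flagCharMismatch("...", "anything"))
  expect_equal(flagCharMismatch(c("MS", "qd"),
                                c("multiple sclerosis", "every day")),
               c(FALSE, TRUE))
})

test_that("spelling heuristic flags unknown long tokens only", {
  corpus <- c("multiple", "sclerosis", "oral", "contraceptive", "every")
  s <- flagSpelling(c("multiple sclerosis", "multple sclerosis",
                      "oral contraceptive", "a bd ce"), corpus)
  expect_equal(s$flagged, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(s$detail[2], "multple")
  # tokens below minLen or containing digits are never checked
  expect_false(flagSpelling("xyz", corpus)$flagged)
  expect_true(flagSpelling("xyzw", corpus)$flagged)
  expect_false(flagSpelling("ab12cdef", corpus)$flagged)
  expect_false(flagSpelling("EVERY Multiple", corpus)$flagged)
  expect_error(flagSpelling("x", character(0)), "empty")
})

test_that("runQC combines heuristics in record order", {
  inv <- prepareInventory(SenseInventory(data.frame(
    sf = c("MS", "..MS", "qd", "MS"),
    lf = c("mitral stenosis", "mitral stenosis", "evry day",
           "mitral stenosis"),
    source = c("s1", "s1", "s1", "s1"))))
  corpus <- c("mitral", "stenosis", "every")
  f <- runQC(inv, corpus)
  # R000002: punctuation; R000003: char mismatch + unknown token "evry";
  # R000004: duplicate of R000001
  expect_equal(f$record_id, c("R000002", "R000003", "R000003", "R000004"))
  expect_equal(f$heuristic,
               c("punctuation", "char_mismatch", "spelling", "duplicate"))
  # clean toy inventory raises no flags at all
  toyCorpus <- unlist(strsplit(tolower(records(
    prepareInventory(makeToyInventory()))$lf), " "))
  expect_equal(nrow(runQC(prepareInventory(makeToyInventory()), toyCorpus)),
               0)
})

test_that("actions modify in place and retire into a side table", {
  inv <- prepareInventory(makeToyInventory())
  actions <- data.frame(
    record_id = c("R000001", "R000004"),
    action = c("modify", "retire"),
    corrected_sf = c("", ""),
    corrected_lf = c("oral contraceptive", ""))
  res <- applyActions(inv, actions)
  act <- records(res$active)
  ret <- records(res$retired)
  expect_equal(nrow(act), 4)
  expect_equal(nrow(ret), 1)
  expect_equal(ret$record_id, "R000004")
  expect_equal(ret$lf, "mitral stenosis")
  i <- match("R000001", act$record_id)
  expect_equal(act$lf[i], "oral contraceptive")
  expect_equal(act$norm_lf[i], "oral contraceptive")
  expect_equal(act$modified[i], "modified")
  # untouched records keep everything, including their ids
  expect_equal(act$record_id, c("R000001", "R000002", "R000003", "R000005"))
  expect_equal(act$modified[-i], rep("", 3))
})

test_that("action validation rejects malformed requests", {
  inv <- prepareInventory(makeToyInventory())
  expect_error(applyActions(inv, data.frame(record_id = "R000001",
                                            action = "delete")),
               "unknown action")
  expect_error(applyActions(inv, data.frame(record_id = "R009999",
                                            action = "keep")),
               "unknown record id")
  expect_error(applyActions(inv, data.frame(record_id = "R000001",
                                            action = "modify")),
               "must supply")
  # no actions: identity on active, empty retired
  res <- applyActions(inv, NULL)
  expect_identical(records(res$active), records(inv))
  expect_equal(nrow(records(res$retired)), 0)
})
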