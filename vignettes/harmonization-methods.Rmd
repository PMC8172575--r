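---
title: "Methods: harmonizing abbreviation sense inventories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonizing abbreviation sense inventories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(abbrmeta)
```

## The problem

Clinical text is dense with abbreviations ("MS", "OC", "D/C"), and each
abbreviation can stand for many senses ("MS": mitral stenosis, multiple
sclerosis, morphine sulfate, ...). Several public *sense inventories* map
abbreviations (short forms, SFs) to their expansions (long forms, LFs), but
they disagree lexically: the same sense appears as "oral contraceptive",
"oral contraceptives", "Oral Contraceptives", and the same abbreviation as
"OC", "O.C.", "oc". Harmonizing such sources into one *meta-inventory*
requires deciding, at scale, which long-form strings denote the same sense
— a deduplication problem that plain string equality cannot solve and that
is too large for manual review.

This package implements that harmonization pipeline end to end: reading
and merging source inventories, lexical normalization, identifier
assignment, blocked candidate generation, supervised synonym
classification, transitive grouping, rule-based quality control, summary
statistics, and coverage evaluation, plus a synthetic-fixture generator
with ground truth so every stage is testable offline.

## Data model

An inventory is a table of records, one `(SF, LF, Source)` triple per row,
held in an S4 `SenseInventory` object. Ten core columns mirror the
meta-inventory data dictionary: `GroupID`, `RecordID`, `SF`, `SFUI`
(short-form unique identifier), `NormSF`, `LF`, `LFUI`, `NormLF`,
`Source`, `Modified`; any further source columns ride along as auxiliary
fields. Files are UTF-8, tab-separated, minimally quoted; text is
normalized to Unicode NFC on read so identifiers and string metrics do not
depend on the input encoding.

Identifiers are deliberately *non-semantic*: six-digit (widening when
exhausted) serial numbers prefixed `R` (record), `S` (distinct raw short
form), `L` (distinct raw long form), `G` (synonym group), assigned in
first-occurrence order. They carry provenance without encoding any claim
about meaning.

## Normalization

Two independent normalizers serve different purposes.

**Short forms** get a conservative surface cleanup: lower-case, trim,
delete periods, then replace whitespace runs and any remaining
non-alphanumeric character with underscores, so `"O.C."` and `"OC"` both
become `"oc"` while `"D/C"` stays distinct as `"d_c"`. An input reduced to
nothing becomes the marker `"null"`.

**Long forms** pass through a fixed flow — lower-case and strip genitives;
remove stop words; uninflect (plural stripping with exception lists, and
`-ing`/`-ed` removal with length guards); then an optional idempotent
synonym substitution — with *token order preserved*:

```{r}
normalizeLongForm(c("Oral Contraceptives", "coarctation of the aorta",
                    "patient's", "stenosis aortic"))
```

These rules approximate, in plain R, the behavior of dedicated lexical
tools (the specialist/derivational machinery of full lexical variant
generation is out of scope); the exception and substitution lists are
configurable via `normConfig()` or a plain-text file via
`readNormConfig()`. A third, lighter normalizer, `normalizeForPairing()`,
is applied just before similarity scoring: it lower-cases and rewrites
whole tokens by a replacement table (roman numerals to digits, ion symbols
to element names) so that `"Type II"` and `"type 2"` compare as equal.

## Candidate generation and features

All-pairs comparison of 10^5 long forms is infeasible and unnecessary;
synonymy is only meaningful *within* an abbreviation. Records are
therefore blocked on `NormSF`, and within each block every pair of long
forms whose partial ratio reaches 0.5 (an inclusive cut, favoring recall)
becomes a candidate.

Five features describe a candidate pair, all based on the indel edit
distance (insertions/deletions cost 1, substitutions 2) scaled to
`1 - d/(|a|+|b|)`:

* `ratio` — the scaled distance itself;
* `partial_ratio` — best ratio of the shorter string against any
  equal-length window of the longer;
* `token_sort_ratio` — ratio after sorting tokens;
* `token_set_ratio` — set-style comparison of intersection/difference
  token joins, scoring token subsets as 1;
* `numeric_similarity` — multiset Jaccard of digit runs, so "type 1" and
  "type 2" separate even at high lexical similarity.

```{r}
featurizePairs("left ventricular ejection fraction", "ejection fraction")
```

For *training-data* construction the filter is different: within a block,
pairs above a **strict** 0.8 plain ratio are presumptive positives; pairs
above the same cut that span *different* short forms are kept as pertinent
negatives — lexically near-identical strings that are nonetheless not
synonyms of one abbreviation (`generateTrainingCandidates()`); a fraction
can be drawn reproducibly for manual annotation (`sampleForAnnotation()`).

## Classifier, threshold, grouping

`trainClassifier()` fits gradient-boosted trees (xgboost; 100 rounds,
depth 3, learning rate 0.3, single-threaded and seeded, hence
deterministic) on the five features; a logistic-regression backend is
available as a transparent baseline. `crossValidate()` runs stratified
k-fold evaluation (default k = 5) with content-canonical fold assignment,
so the report is invariant to input row order; it also returns
*out-of-fold* probabilities. `selectThreshold()` sweeps those and picks
the smallest threshold whose precision reaches the target (default 0.99):
a high-specificity operating point, because a false positive merges two
distinct senses — a worse failure than leaving lexical variants unmerged.

Classifier decisions are not transitive, so `buildGroups()` takes the
positive pairs as edges and defines synonym groups as connected components
(via igraph), with unlinked records as singleton groups.
`assignGroupIds()` numbers groups by their smallest member record id.
`runHarmonize()` chains all stages under one seed.

## Quality control

Four advisory heuristics (`runQC()`): exact intra-source duplicates;
suspicious punctuation in short forms (leading punctuation, trailing runs
— a single trailing period is ordinary abbreviation style —, internal
runs like `"..MS"`); short-form characters absent from the long form
(case-folded set membership, catching mismatches like `"qd"`/`"every
day"`); and long-form tokens missing from a word corpus (length ≥ 4,
purely alphabetic — shorter tokens are too often legitimate embedded
acronyms). Flags feed a human-reviewed action table applied by
`applyActions()`: modified records keep their identifiers and are marked;
retired records move to a side table, so no information is destroyed.

## Statistics and coverage

`summarizeInventory()` reports the redundancy/ambiguity structure —
records, unique forms, groups, singleton records, senses per abbreviation
(an abbreviation = one normalized short form) — with percentages rounded
half away from zero, and the scan-reduction figure
`100·(1 − groups/records)`. `coverageReport()` evaluates an inventory
against an annotated corpus: abbreviation and sense coverage, each micro
(per instance) and macro (per distinct abbreviation); sense coverage can
credit any lexical variant inside a matching group (`mode = "group"`).

## Synthetic fixtures

Because the real corpora behind the published evaluation are
access-restricted, the package ships a generator that emulates the *shape*
of the problem. `generateConceptBank()` draws concepts (long form = 2–4
words from a bundled vocabulary, abbreviation = its initials), with a
configurable fraction of concepts deliberately reusing an earlier
abbreviation (default 0.25, echoing pervasive real-world ambiguity).
`generateInventories()` renders each concept per source with lexical
quirks at fixed per-record rates (case 0.3, periods 0.2, plural 0.2,
genitive 0.05, stop-word insertion 0.1, word swap 0.1; misspellings and
slashed short forms off by default) and can inject QC errors with recorded
ground truth; `generateAnnotatedCorpus()` samples Zipf-distributed
(exponent 1.5) annotated instances. These defaults are the package's study
conditions — chosen a priori to mimic the documented variant types, not
tuned to any test. Known limitation: slashed short-form variants ("D/C")
normalize to a different `NormSF` than "DC" and thus break blocking;
recovering them would need SF-level variant linking, which is out of
scope, so the slash rate defaults to 0.

Recovery is scored by `pairwiseF1()` — precision/recall over co-grouped
record pairs:

```{r}
bank <- generateConceptBank(30, seed = 7)
fx <- generateInventories(bank, seed = 7)
res <- runHarmonize(fx$inventories, labeledPairs = fx$labeled_pairs,
                    qcCorpus = fx$word_corpus, seed = 7)
truthIds <- fx$truth$concept_id[match(records(res$inventory)$record_id,
                                      fx$truth$record_id)]
pairwiseF1(records(res$inventory)$group_id, truthIds)
```

## Numerical conventions

Edit distances come from `utils::adist()` with costs (1, 1, 2), making the
ratio identical to the usual "indel similarity". Percentages and the
senses-per-abbreviation mean round half away from zero, reproducing the
published derived figures exactly from the published counts:

```{r}
lookupReductionPercent(405543, 183817)  # 55% fewer rows to scan
meanSenses(183817, 104057)              # 1.77 senses per abbreviation
sharePercent(107650, 405543)            # 27% of records have no synonym
```

All stochastic steps (fixture generation, fold shuffling, xgboost) run
under explicit seeds with saved-and-restored RNG state; two runs with the
same inputs and seeds are byte-identical. Problem sizes used in examples
and tests (tens of concepts, a few sources, thousands of corpus
instances) are the package's own choices for desk-scale verification.
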