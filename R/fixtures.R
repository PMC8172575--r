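# Load the bundled word bank, indexed by initial letter.
.wordBank <- function() {
  path <- system.file("extdata", "wordbank.txt", package = "abbrmeta")
  words <- readLines(path, encoding = "UTF-8")
  words <- words[nzchar(words) & !startsWith(words, "#")]
  split(words, substr(words, 1, 1))
}

#' Generate a bank of synthetic abbreviation concepts
#'
#' Each concept is one (abbreviation, long form, concept id) triple: the
#' long form is a 2–4 word phrase drawn from a bundled vocabulary and the
#' abbreviation is its upper-cased initials. A fraction of concepts
#' deliberately reuse another concept's abbreviation with a different long
#' form, emulating the pervasive ambiguity of real clinical abbreviations
#' (the same short form meaning many things).
#'
#' @param nConcepts number of concepts, at least 1.
#' @param ambiguityRate fraction in [0, 1) of concepts that share their
#'   abbreviation with an earlier concept.
#' @param zipfExponent exponent of the Zipf law used when instances are
#'   later sampled from this bank; default 1.5.
#' @param seed integer RNG seed; generation is fully reproducible.
#' @return list of class \code{"ConceptBank"} with \code{concepts}
#'   (data.frame \code{concept_id}, \code{sf}, \code{lf}) and
#'   \code{zipf_exponent}.
#' @export
generateConceptBank <- function(nConcepts, ambiguityRate = 0.25,
                                zipfExponent = 1.5, seed = 1L) {
  if (nConcepts < 1) stop("nConcepts must be at least 1")
  if (ambiguityRate < 0 || ambiguityRate >= 1)
    stop("ambiguityRate must be in [0, 1)")
  bank <- .wordBank()
  letters_ <- names(bank)
  .withSeed(seed, {
    sfs <- character(nConcepts)
    lfs <- character(nConcepts)
    for (i in seq_len(nConcepts)) {
      ambiguous <- i > 1 && stats::runif(1) < ambiguityRate
      for (try in 1:50) {
        if (ambiguous) {
          donor <- sample.int(i - 1L, 1L)
          inits <- strsplit(tolower(sfs[donor]), "")[[1]]
        } else {
          k <- sample(2:4, 1L)
          inits <- sample(letters_, k, replace = TRUE)
        }
        words <- vapply(inits, function(l) sample(bank[[l]], 1L), "")
        lf <- paste(words, collapse = " ")
        sf <- toupper(paste(inits, collapse = ""))
        clash <- lf %in% lfs[seq_len(i - 1)] ||
          (!ambiguous && ambiguityRate == 0 && sf %in% sfs[seq_len(i - 1)])
        if (!clash) break
      }
      sfs[i] <- sf
      lfs[i] <- lf
    }
    structure(list(concepts = data.frame(
      concept_id = sprintf("C%04d", seq_len(nConcepts)),
      sf = sfs, lf = lfs),
      zipf_exponent = zipfExponent), class = "ConceptBank")
  })
}

.defaultVariantRates <- function() {
  list(case = 0.3, period = 0.2, slash = 0, plural = 0.2, genitive = 0.05,
       stopword = 0.1, swap = 0.1, misspell = 0)
}

.defaultErrorRates <- function() {
  list(duplicate = 0, punctuation = 0, char_mismatch = 0, spelling = 0)
}

.sfVariant <- function(sf, rates) {
  if (stats::runif(1) < rates$case) sf <- tolower(sf)
  if (grepl("^[A-Za-z]+$", sf)) {
    if (stats::runif(1) < rates$period)
      sf <- paste0(paste(strsplit(sf, "")[[1]], collapse = "."), ".")
    else if (stats::runif(1) < rates$slash)
      sf <- paste(strsplit(sf, "")[[1]], collapse = "/")
  }
  sf
}

.lfVariant <- function(lf, rates) {
  toks <- .tokens(lf)
  n <- length(toks)
  last <- toks[n]
  if (stats::runif(1) < rates$plural && grepl("[a-rt-z]$", last))
    toks[n] <- paste0(last, "s")
  if (stats::runif(1) < rates$genitive && grepl("[a-z]$", toks[1]))
    toks[1] <- paste0(toks[1], "'s")
  if (n >= 2 && stats::runif(1) < rates$stopword)
    toks <- append(toks, "of", after = 1L)
  if (n >= 2 && stats::runif(1) < rates$swap)
    toks[1:2] <- toks[2:1]
  if (stats::runif(1) < rates$misspell) {
    cand <- which(nchar(toks) >= 5 & grepl("^[a-z]+$", toks))
    if (length(cand)) {
      j <- cand[sample.int(length(cand), 1L)]
      w <- toks[j]
      pos <- sample(3:(nchar(w) - 1L), 1L)  # keep initial letter intact
      toks[j] <- paste0(substr(w, 1, pos - 1), substr(w, pos + 1, nchar(w)))
    }
  }
  paste(toks, collapse = " ")
}

#' Generate multi-source inventories with ground truth
#'
#' Emulates the situation harmonization addresses: several source
#' inventories describe overlapping sets of concepts, each rendering short
#' and long forms with its own lexical quirks (case and period variants of
#' abbreviations; plural, genitive, inserted stop-word, word-order and
#' misspelling variants of long forms). The first source covers every
#' concept; later sources cover a random subset. Quality-control errors
#' can additionally be injected at controlled per-record rates, with
#' ground truth recorded so detector recall is measurable.
#'
#' @param bank a \code{"ConceptBank"}.
#' @param nSources number of source inventories, at least 1.
#' @param variantRates named list of per-record lexical variant
#'   probabilities (\code{case}, \code{period}, \code{slash},
#'   \code{plural}, \code{genitive}, \code{stopword}, \code{swap},
#'   \code{misspell}); missing entries take the defaults of
#'   \code{.defaultVariantRates}.
#' @param errorRates named list of per-record QC-error probabilities
#'   (\code{duplicate}, \code{punctuation}, \code{char_mismatch},
#'   \code{spelling}); default all 0 (clean fixture).
#' @param sourceCoverage fraction of concepts covered by sources after the
#'   first, default 0.7.
#' @param seed integer RNG seed.
#' @return list of class \code{"FixtureBundle"}: \code{inventories}
#'   (per-source [SenseInventory-class]), \code{inventory} (merged,
#'   normalized, R/S/L ids assigned), \code{truth} (data.frame
#'   \code{record_id}, \code{concept_id}), \code{labeled_pairs} (features
#'   + 0/1 label), \code{injected_errors} (data.frame \code{record_id},
#'   \code{heuristic}), \code{word_corpus} (character vector for the
#'   spelling heuristic), and the generating \code{bank}.
#' @export
generateInventories <- function(bank, nSources = 3L,
                                variantRates = list(), errorRates = list(),
                                sourceCoverage = 0.7, seed = 1L) {
  stopifnot(inherits(bank, "ConceptBank"), nSources >= 1)
  vr <- utils::modifyList(.defaultVariantRates(), variantRates)
  er <- utils::modifyList(.defaultErrorRates(), errorRates)
  if (any(unlist(vr) < 0 | unlist(vr) > 1) ||
      any(unlist(er) < 0 | unlist(er) > 1))
    stop("rates must be in [0, 1]")
  con <- bank$concepts
  .withSeed(seed, {
    srcNames <- sprintf("source%02d", seq_len(nSources))
    tabs <- vector("list", nSources)
    for (s in seq_len(nSources)) {
      pick <- if (s == 1) seq_len(nrow(con))
              else sort(sample.int(nrow(con),
                                   max(1L, round(sourceCoverage * nrow(con)))))
      sf <- vapply(con$sf[pick], .sfVariant, "", rates = vr,
                   USE.NAMES = FALSE)
      lf <- vapply(con$lf[pick], .lfVariant, "", rates = vr,
                   USE.NAMES = FALSE)
      tabs[[s]] <- data.frame(sf = sf, lf = lf, source = srcNames[s],
                              concept_id = con$concept_id[pick],
                              injected = "")
    }
    # the spell-check corpus reflects the clean (pre-injection) language
    wordCorpus <- sort(unique(c(
      unlist(.wordBank(), use.names = FALSE),
      unlist(lapply(tabs, function(t)
        unlist(strsplit(gsub("[^a-z ]", " ", tolower(t$lf)), "\\s+")))))))
    wordCorpus <- wordCorpus[nzchar(wordCorpus)]
    for (s in seq_len(nSources)) {
      t <- tabs[[s]]
      dupRows <- integer(0)
      for (r in seq_len(nrow(t))) {
        errs <- character(0)
        if (stats::runif(1) < er$punctuation) {
          t$sf[r] <- paste0("..", t$sf[r])
          errs <- c(errs, "punctuation")
        }
        if (stats::runif(1) < er$spelling) {
          toks <- .tokens(t$lf[r])
          j <- which(nchar(toks) >= 4 & grepl("^[a-z]+$", toks))
          if (length(j)) {
            j <- j[sample.int(length(j), 1L)]
            toks[j] <- paste0(toks[j], "qz")  # guaranteed non-corpus token
            t$lf[r] <- paste(toks, collapse = " ")
            errs <- c(errs, "spelling")
          }
        }
        # after the spelling injection, so the "absent" letter cannot be
        # re-introduced into the long form by the appended qz token
        if (stats::runif(1) < er$char_mismatch) {
          absent <- setdiff(c("q", "z", "x", "j", "w", "k"),
                            strsplit(tolower(t$lf[r]), "")[[1]])
          if (length(absent)) {
            t$sf[r] <- paste0(t$sf[r], toupper(absent[1]))
            errs <- c(errs, "char_mismatch")
          }
        }
        if (stats::runif(1) < er$duplicate) dupRows <- c(dupRows, r)
        t$injected[r] <- paste(errs, collapse = ",")
      }
      if (length(dupRows)) {
        copies <- t[dupRows, , drop = FALSE]
        copies$injected <- "duplicate"
        t <- rbind(t, copies)
      }
      tabs[[s]] <- t
    }
    invs <- lapply(tabs, function(t)
      SenseInventory(t[, c("sf", "lf", "source")]))
    merged <- mergeSources(invs)
    merged <- assignRecordIds(merged)
    merged <- assignStringIds(merged, "short_form")
    merged <- assignStringIds(merged, "long_form")
    merged <- normalizeInventory(merged)
    flat <- do.call(rbind, tabs)
    rec <- records(merged)
    truth <- data.frame(record_id = rec$record_id,
                        concept_id = flat$concept_id)
    injected <- do.call(rbind, lapply(which(nzchar(flat$injected)),
      function(r) data.frame(
        record_id = rec$record_id[r],
        heuristic = strsplit(flat$injected[r], ",", fixed = TRUE)[[1]])))
    if (is.null(injected))
      injected <- data.frame(record_id = character(0),
                             heuristic = character(0))
    labeled <- .labeledPairsFromTruth(merged, truth)
    structure(list(inventories = invs, inventory = merged, truth = truth,
                   labeled_pairs = labeled, injected_errors = injected,
                   word_corpus = wordCorpus, bank = bank,
                   variant_rates = vr, error_rates = er),
              class = "FixtureBundle")
  })
}

# Truth-consistent labeled pairs: every within-concept pair is positive
# (transitively complete); negatives are all same-short-form cross-concept
# pairs plus an equal number of random cross-concept pairs.
.labeledPairsFromTruth <- function(inv, truth) {
  rec <- records(inv)
  cid <- truth$concept_id[match(rec$record_id, truth$record_id)]
  pos <- do.call(rbind, lapply(split(seq_len(nrow(rec)), cid), function(ix) {
    if (length(ix) < 2) return(NULL)
    cmb <- utils::combn(ix, 2)
    data.frame(i = cmb[1, ], j = cmb[2, ])
  }))
  negBlock <- do.call(rbind, lapply(split(seq_len(nrow(rec)), rec$norm_sf),
    function(ix) {
      if (length(ix) < 2) return(NULL)
      cmb <- utils::combn(ix, 2)
      keep <- cid[cmb[1, ]] != cid[cmb[2, ]]
      if (!any(keep)) return(NULL)
      data.frame(i = cmb[1, keep], j = cmb[2, keep])
    }))
  nRand <- if (is.null(pos)) 50L else nrow(pos)
  i <- sample.int(nrow(rec), nRand * 2L, replace = TRUE)
  j <- sample.int(nrow(rec), nRand * 2L, replace = TRUE)
  keep <- i != j & cid[i] != cid[j]
  negRand <- data.frame(i = i[keep], j = j[keep])
  all <- rbind(
    if (!is.null(pos)) cbind(pos, label = 1),
    if (!is.null(negBlock)) cbind(negBlock, label = 0),
    if (nrow(negRand)) cbind(negRand, label = 0))
  if (is.null(all) || !nrow(all)) stop("fixture produced no labeled pairs")
  key <- paste(pmin(all$i, all$j), pmax(all$i, all$j))
  all <- all[!duplicated(key), , drop = FALSE]
  out <- data.frame(record_id_a = rec$record_id[all$i],
                    record_id_b = rec$record_id[all$j],
                    lf_a = rec$lf[all$i], lf_b = rec$lf[all$j],
                    label = all$label)
  cbind(out, featurizePairs(out$lf_a, out$lf_b))
}

#' Generate a Zipf-distributed annotated corpus
#'
#' Samples abbreviation instances from a concept bank with Zipf weights
#' (frequency of the k-th concept proportional to k^-s, s the bank's
#' \code{zipf_exponent}), mirroring the heavy-tailed frequency of
#' abbreviations in clinical notes. A fraction of instances carry a sense
#' label (the normalized canonical long form), as produced by manual
#' annotation of a sample.
#'
#' @param bank a \code{"ConceptBank"}.
#' @param nInstances number of instances, at least 1.
#' @param labeledFraction fraction in [0, 1] of instances annotated with a
#'   sense; default 1.
#' @param seed integer RNG seed.
#' @param cfg a \code{"NormalizationConfig"}.
#' @return data.frame with columns \code{surface}, \code{norm_sf},
#'   \code{sense} (empty string = unlabeled), \code{concept_id}.
#' @export
generateAnnotatedCorpus <- function(bank, nInstances, labeledFraction = 1,
                                    seed = 1L, cfg = normConfig()) {
  stopifnot(inherits(bank, "ConceptBank"), nInstances >= 1)
  if (labeledFraction < 0 || labeledFraction > 1)
    stop("labeledFraction must be in [0, 1]")
  con <- bank$concepts
  w <- seq_len(nrow(con))^(-bank$zipf_exponent)
  .withSeed(seed, {
    pick <- sample.int(nrow(con), nInstances, replace = TRUE,
                       prob = w / sum(w))
    sense <- normalizeLongForm(con$lf[pick], cfg)
    unlab <- stats::runif(nInstances) >= labeledFraction
    sense[unlab] <- ""
    data.frame(surface = con$sf[pick],
               norm_sf = normalizeShortForm(con$sf[pick]),
               sense = sense, concept_id = con$concept_id[pick])
  })
}

#' Pairwise F1 between a predicted and a true partition
#'
#' Treats each partition as the set of unordered record pairs it places in
#' a common group, and scores the predicted pair set against the true one.
#' The universal measure for grouping quality: precision penalizes merges
#' across true senses, recall penalizes failures to merge variants. When
#' both partitions are all singletons (no positive pairs anywhere), the
#' score is 1.
#'
#' @param predicted,truth character vectors of group labels, aligned
#'   elementwise on the same records.
#' @return list with \code{precision}, \code{recall}, \code{f1}.
#' @export
pairwiseF1 <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  nPairs <- function(n) n * (n - 1) / 2
  predPairs <- sum(nPairs(table(predicted)))
  truePairs <- sum(nPairs(table(truth)))
  tp <- sum(nPairs(table(paste(predicted, truth, sep = "\r"))))
  if (predPairs == 0 && truePairs == 0)
    return(list(precision = 1, recall = 1, f1 = 1))
  p <- if (predPairs > 0) tp / predPairs else 0
  r <- if (truePairs > 0) tp / truePairs else 0
  list(precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}
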