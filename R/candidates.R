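# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

# order a two-column id pair canonically (a < b) and drop self/duplicate pairs
.canonicalPairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- a != b & !duplicated(paste(a, b, sep = "\r"))
  data.frame(record_id_a = a[keep], record_id_b = b[keep])
}

#' Generate training-annotation candidates by global similarity filtering
#'
#' Computes the plain Levenshtein ratio between the long forms of every
#' record pair. Pairs with ratio strictly above \code{ratioThreshold}
#' (default 0.8) and the same normalized short form are returned as
#' potential positives (likely synonyms); equally similar pairs with
#' different short forms are pertinent negatives — similar but not
#' synonymous, the hard negative examples a classifier needs.
#'
#' @param inv a [SenseInventory-class] with \code{norm_sf} populated and
#'   record ids assigned.
#' @param ratioThreshold similarity cut-off, default 0.8 (strict
#'   inequality).
#' @return list with data.frames \code{positives} and
#'   \code{pertinent_negatives}, each with columns \code{record_id_a},
#'   \code{record_id_b}, \code{lf_a}, \code{lf_b},
#'   \code{same_short_form}, \code{prefilter_score}.
#' @export
generateTrainingCandidates <- function(inv, ratioThreshold = 0.8) {
  stopifnot(is(inv, "SenseInventory"))
  rec <- records(inv)
  empty <- data.frame(record_id_a = character(0), record_id_b = character(0),
                      lf_a = character(0), lf_b = character(0),
                      same_short_form = logical(0),
                      prefilter_score = numeric(0))
  if (nrow(rec) < 2)
    return(list(positives = empty, pertinent_negatives = empty))
  if (any(!nzchar(rec$record_id))) stop("assign record identifiers first")
  if (any(!nzchar(rec$norm_sf))) stop("normalize the inventory first")
  lf <- rec$lf
  d <- utils::adist(lf, lf, costs = list(ins = 1, del = 1, sub = 2))
  tot <- outer(nchar(lf), nchar(lf), `+`)
  ratio <- ifelse(tot > 0, 1 - d / tot, 1)
  idx <- which(upper.tri(ratio) & ratio > ratioThreshold, arr.ind = TRUE)
  out <- data.frame(
    record_id_a = rec$record_id[idx[, 1]],
    record_id_b = rec$record_id[idx[, 2]],
    lf_a = lf[idx[, 1]], lf_b = lf[idx[, 2]],
    same_short_form = rec$norm_sf[idx[, 1]] == rec$norm_sf[idx[, 2]],
    prefilter_score = ratio[idx])
  swap <- out$record_id_a > out$record_id_b
  if (any(swap)) {
    out[swap, c("record_id_a", "record_id_b", "lf_a", "lf_b")] <-
      out[swap, c("record_id_b", "record_id_a", "lf_b", "lf_a")]
  }
  out <- out[order(out$record_id_a, out$record_id_b), , drop = FALSE]
  rownames(out) <- NULL
  list(positives = out[out$same_short_form, , drop = FALSE],
       pertinent_negatives = out[!out$same_short_form, , drop = FALSE])
}

#' Sample candidate pairs for manual annotation
#'
#' Uniform random sample without replacement of
#' \code{ceiling(fraction * nrow(pairs))} pairs, reproducible under
#' \code{seed}. The ceiling guarantees small strata are never sampled
#' empty.
#'
#' @param pairs data.frame of candidate pairs.
#' @param fraction sampling fraction in (0, 1]; default 0.01.
#' @param seed integer RNG seed.
#' @return data.frame subset of \code{pairs}.
#' @export
sampleForAnnotation <- function(pairs, fraction = 0.01, seed) {
  stopifnot(is.data.frame(pairs), fraction > 0, fraction <= 1)
  if (!nrow(pairs)) return(pairs)
  k <- ceiling(fraction * nrow(pairs))
  idx <- .withSeed(seed, sample.int(nrow(pairs), k))
  out <- pairs[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate prediction-time candidate pairs by blocking
#'
#' Records are blocked on the normalized short form — only records that
#' could be senses of the same abbreviation are ever compared — and
#' within each block every pair whose pairing-normalized long forms reach
#' a partial Levenshtein ratio of \code{partialThreshold} (default 0.5,
#' inclusive) becomes a candidate for the synonym classifier.
#'
#' @param inv a [SenseInventory-class] with \code{norm_sf} populated and
#'   record ids assigned.
#' @param partialThreshold partial-ratio cut-off, default 0.5 (inclusive).
#' @param cfg a \code{"NormalizationConfig"} for pre-pairing replacement.
#' @return data.frame with columns \code{record_id_a}, \code{record_id_b},
#'   \code{norm_sf}, \code{lf_a}, \code{lf_b}, \code{prefilter_score},
#'   pairs in canonical order (\code{record_id_a < record_id_b}).
#' @export
generateCandidatePairs <- function(inv, partialThreshold = 0.5,
                                   cfg = normConfig()) {
  stopifnot(is(inv, "SenseInventory"))
  rec <- records(inv)
  empty <- data.frame(record_id_a = character(0), record_id_b = character(0),
                      norm_sf = character(0), lf_a = character(0),
                      lf_b = character(0), prefilter_score = numeric(0))
  if (nrow(rec) < 2) return(empty)
  if (any(!nzchar(rec$record_id))) stop("assign record identifiers first")
  if (any(!nzchar(rec$norm_sf))) stop("normalize the inventory first")
  pn <- normalizeForPairing(rec$lf, cfg)
  blocks <- split(seq_len(nrow(rec)), rec$norm_sf)
  res <- lapply(blocks, function(ix) {
    if (length(ix) < 2) return(NULL)
    cmb <- utils::combn(ix, 2)
    i <- cmb[1, ]; j <- cmb[2, ]
    score <- partialRatio(pn[i], pn[j])
    keep <- score >= partialThreshold
    if (!any(keep)) return(NULL)
    i <- i[keep]; j <- j[keep]; score <- score[keep]
    swap <- rec$record_id[i] > rec$record_id[j]
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    data.frame(record_id_a = rec$record_id[i], record_id_b = rec$record_id[j],
               norm_sf = rec$norm_sf[i], lf_a = rec$lf[i], lf_b = rec$lf[j],
               prefilter_score = score)
  })
  out <- do.call(rbind, c(res, list(empty)))
  out <- out[order(out$record_id_a, out$record_id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
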