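# Indel edit distance (insert/delete cost 1, substitution cost 2),
# elementwise over two equal-length vectors.
.indelDist <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!length(a)) return(numeric(0))
  vapply(seq_along(a), function(i)
    as.numeric(utils::adist(a[i], b[i],
                            costs = list(ins = 1, del = 1, sub = 2))),
    0)
}

#' Levenshtein similarity ratio
#'
#' Normalized indel similarity: \code{1 - d(a, b) / (nchar(a) + nchar(b))},
#' where \code{d} is the edit distance with insertions and deletions
#' costing 1 and substitutions 2. This is the convention of the
#' partial/token-sort/token-set ratio family; two empty strings score 1.
#'
#' @param a,b character vectors (recycled elementwise like arithmetic).
#' @return numeric vector of ratios in \eqn{[0, 1]}.
#' @examples
#' levenshteinRatio("oral contraceptive", "oral contraceptives")
#' @export
levenshteinRatio <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  tot <- nchar(a) + nchar(b)
  out <- rep(1, n)
  nz <- tot > 0
  out[nz] <- 1 - .indelDist(a[nz], b[nz]) / tot[nz]
  out
}

#' Partial (best-window) Levenshtein ratio
#'
#' The maximum [levenshteinRatio()] between the shorter string and every
#' contiguous window of the longer string having the shorter string's
#' length. Scores 1 whenever the shorter string is a substring of the
#' longer one.
#'
#' @inheritParams levenshteinRatio
#' @return numeric vector of ratios in \eqn{[0, 1]}.
#' @examples
#' partialRatio("cat", "the cat sat")
#' @export
partialRatio <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) {
    s <- a[i]; l <- b[i]
    if (nchar(s) > nchar(l)) { tmp <- s; s <- l; l <- tmp }
    ns <- nchar(s); nl <- nchar(l)
    if (ns == nl) return(levenshteinRatio(s, l))
    if (ns == 0) return(1)
    starts <- seq_len(nl - ns + 1L)
    wins <- substring(l, starts, starts + ns - 1L)
    d <- as.numeric(utils::adist(s, wins,
                                 costs = list(ins = 1, del = 1, sub = 2)))
    max(1 - d / (ns + ns))
  }, 0)
}

.sortTokens <- function(x) {
  paste(sort(.tokens(x), method = "radix"), collapse = " ")
}

#' Token-sort Levenshtein ratio
#'
#' [levenshteinRatio()] applied after whitespace-tokenizing both strings,
#' sorting the tokens lexicographically (C locale), and re-joining with
#' single spaces; word order therefore does not matter.
#'
#' @inheritParams levenshteinRatio
#' @return numeric vector of ratios in \eqn{[0, 1]}.
#' @examples
#' tokenSortRatio("oral contraceptive", "contraceptive oral")
#' @export
tokenSortRatio <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  levenshteinRatio(vapply(a, .sortTokens, "", USE.NAMES = FALSE),
                   vapply(b, .sortTokens, "", USE.NAMES = FALSE))
}

#' Token-set Levenshtein ratio
#'
#' With \code{t0} the sorted intersection of the two token sets, \code{t1}
#' = \code{t0} plus the sorted tokens unique to the first string, and
#' \code{t2} = \code{t0} plus those unique to the second (each
#' space-joined), returns the maximum of the three pairwise
#' [levenshteinRatio()] values. Shared tokens thus never penalize the
#' score: a string whose tokens are a subset of the other's scores 1.
#'
#' @inheritParams levenshteinRatio
#' @return numeric vector of ratios in \eqn{[0, 1]}.
#' @examples
#' tokenSetRatio("left ventricular ejection fraction", "ejection fraction")
#' @export
tokenSetRatio <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) {
    ta <- unique(.tokens(a[i])); tb <- unique(.tokens(b[i]))
    int <- sort(intersect(ta, tb), method = "radix")
    da <- sort(setdiff(ta, tb), method = "radix")
    db <- sort(setdiff(tb, ta), method = "radix")
    t0 <- paste(int, collapse = " ")
    t1 <- paste(c(int, da), collapse = " ")
    t2 <- paste(c(int, db), collapse = " ")
    max(levenshteinRatio(t0, t1), levenshteinRatio(t0, t2),
        levenshteinRatio(t1, t2))
  }, 0)
}

.digitRuns <- function(x) {
  m <- gregexpr("[0-9]+", x)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(x, gregexpr("[0-9]+", x))[[1]]
}

#' Numeric similarity of two strings
#'
#' Extracts the multisets of maximal digit runs from each string and
#' returns their multiset Jaccard index (intersection count over union
#' count). Two strings with no digits at all score 1, keeping the feature
#' neutral for numeric-free pairs while separating e.g. "type 1" from
#' "type 2".
#'
#' @inheritParams levenshteinRatio
#' @return numeric vector of ratios in \eqn{[0, 1]}.
#' @examples
#' numericSimilarity("type 2 diabetes", "diabetes type 2")
#' numericSimilarity("type 1", "type 2")
#' @export
numericSimilarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) {
    ra <- .digitRuns(a[i]); rb <- .digitRuns(b[i])
    if (!length(ra) && !length(rb)) return(1)
    elems <- unique(c(ra, rb))
    ca <- vapply(elems, function(e) sum(ra == e), 0L)
    cb <- vapply(elems, function(e) sum(rb == e), 0L)
    sum(pmin(ca, cb)) / sum(pmax(ca, cb))
  }, 0)
}

#' Compute the five classifier features for long-form pairs
#'
#' Applies [normalizeForPairing()] to both strings, then computes the five
#' similarity features used by the synonym classifier: plain, partial,
#' token-sort and token-set Levenshtein ratios, and numeric similarity.
#'
#' @param lfA,lfB character vectors of long forms (elementwise pairs).
#' @param cfg a \code{"NormalizationConfig"}.
#' @return data.frame with columns \code{ratio}, \code{partial_ratio},
#'   \code{token_sort_ratio}, \code{token_set_ratio},
#'   \code{numeric_similarity}, one row per pair.
#' @export
featurizePairs <- function(lfA, lfB, cfg = normConfig()) {
  n <- max(length(lfA), length(lfB))
  a <- normalizeForPairing(rep_len(as.character(lfA), n), cfg)
  b <- normalizeForPairing(rep_len(as.character(lfB), n), cfg)
  data.frame(ratio = levenshteinRatio(a, b),
             partial_ratio = partialRatio(a, b),
             token_sort_ratio = tokenSortRatio(a, b),
             token_set_ratio = tokenSetRatio(a, b),
             numeric_similarity = numericSimilarity(a, b))
}

.FEATURE_COLS <- c("ratio", "partial_ratio", "token_sort_ratio",
                   "token_set_ratio", "numeric_similarity")
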