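.checkCorpus <- function(corpus) {
  stopifnot(is.data.frame(corpus))
  need <- setdiff(c("surface", "norm_sf"), colnames(corpus))
  if (length(need))
    stop("corpus lacks column(s): ", paste(need, collapse = ", "))
  if (!nrow(corpus)) stop("empty corpus")
  if (is.null(corpus$sense)) corpus$sense <- character(nrow(corpus))
  corpus$sense[is.na(corpus$sense)] <- ""
  corpus
}

#' Abbreviation coverage of an inventory over an annotated corpus
#'
#' An instance is covered when its normalized short form occurs among the
#' inventory's normalized short forms. Micro-coverage is the covered
#' fraction of all instances (frequency-weighted); macro-coverage averages
#' the 0/1 covered indicator over the distinct abbreviations, weighting a
#' rare abbreviation the same as a ubiquitous one.
#'
#' @param corpus data.frame of annotated instances with columns
#'   \code{surface}, \code{norm_sf} and optionally \code{sense}.
#' @param inv a [SenseInventory-class] with \code{norm_sf} populated.
#' @return list with \code{macro} and \code{micro} ratios in [0, 1].
#' @export
abbreviationCoverage <- function(corpus, inv) {
  corpus <- .checkCorpus(corpus)
  stopifnot(is(inv, "SenseInventory"))
  known <- unique(records(inv)$norm_sf)
  covered <- corpus$norm_sf %in% known
  perSf <- vapply(split(covered, corpus$norm_sf), any, logical(1))
  list(macro = mean(perSf), micro = mean(covered))
}

#' Sense coverage of an inventory over an annotated corpus
#'
#' Restricted to sense-labeled instances. An instance is covered when some
#' inventory record shares its normalized short form and matches its sense
#' label: by normalized-long-form string equality, or — with
#' \code{mode = "group"} and group ids assigned — when the record belongs
#' to the synonym group of any record whose normalized long form equals
#' the label, so lexical variants of a sense count as covered.
#' Micro-coverage is the covered fraction over all labeled instances;
#' macro-coverage averages each abbreviation's per-instance covered
#' fraction over the distinct abbreviations.
#'
#' @inheritParams abbreviationCoverage
#' @param mode \code{"normlf"} (string equality, default) or
#'   \code{"group"}.
#' @return list with \code{macro} and \code{micro} ratios in [0, 1].
#' @export
senseCoverage <- function(corpus, inv, mode = c("normlf", "group")) {
  corpus <- .checkCorpus(corpus)
  stopifnot(is(inv, "SenseInventory"))
  mode <- match.arg(mode)
  lab <- corpus[nzchar(corpus$sense), , drop = FALSE]
  if (!nrow(lab)) stop("corpus carries no sense labels")
  rec <- records(inv)
  key <- paste(rec$norm_sf, rec$norm_lf, sep = "\r")
  if (mode == "group") {
    if (any(!nzchar(rec$group_id)))
      stop("group mode requires assigned group identifiers")
    # expand each group to every (norm_sf, norm_lf) combination it holds,
    # so any lexical variant of a grouped sense matches the label
    byGroup <- split(seq_len(nrow(rec)), rec$group_id)
    key <- unique(unlist(lapply(byGroup, function(ix) {
      as.vector(outer(rec$norm_sf[ix], unique(rec$norm_lf[ix]),
                      paste, sep = "\r"))
    })))
  }
  covered <- paste(lab$norm_sf, lab$sense, sep = "\r") %in% key
  perSf <- vapply(split(covered, lab$norm_sf), mean, 0)
  list(macro = mean(perSf), micro = mean(covered))
}

#' Full coverage report
#'
#' Computes all four coverage metrics — abbreviation and sense coverage,
#' each macro and micro. Sense metrics are \code{NA} when the corpus has
#' no sense labels.
#'
#' @inheritParams senseCoverage
#' @return list with \code{abbrev_macro}, \code{abbrev_micro},
#'   \code{sense_macro}, \code{sense_micro}.
#' @export
coverageReport <- function(corpus, inv, mode = c("normlf", "group")) {
  corpus <- .checkCorpus(corpus)
  ab <- abbreviationCoverage(corpus, inv)
  hasSense <- any(nzchar(corpus$sense))
  se <- if (hasSense) senseCoverage(corpus, inv, mode)
        else list(macro = NA_real_, micro = NA_real_)
  list(abbrev_macro = ab$macro, abbrev_micro = ab$micro,
       sense_macro = se$macro, sense_micro = se$micro)
}
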