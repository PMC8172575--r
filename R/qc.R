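.emptyFlags <- function() {
  data.frame(record_id = character(0), heuristic = character(0),
             detail = character(0))
}

#' Flag exact duplicates within a source
#'
#' For every (source, short form, long form) triple occurring more than
#' once, all occurrences after the first are flagged; identical rows in
#' different sources are legitimate cross-source redundancy and are never
#' flagged. Matching is on the raw strings — these are exact duplicates.
#'
#' @param inv a [SenseInventory-class] with record ids assigned.
#' @return data.frame of flags (\code{record_id}, \code{heuristic},
#'   \code{detail}).
#' @export
flagIntraSourceDuplicates <- function(inv) {
  stopifnot(is(inv, "SenseInventory"))
  rec <- records(inv)
  if (nrow(rec) && any(!nzchar(rec$record_id)))
    stop("assign record identifiers first")
  key <- paste(rec$source, rec$sf, rec$lf, sep = "\r")
  dup <- duplicated(key)
  if (!any(dup)) return(.emptyFlags())
  first <- rec$record_id[match(key[dup], key)]
  data.frame(record_id = rec$record_id[dup], heuristic = "duplicate",
             detail = paste0("duplicate of ", first, " in source ",
                             rec$source[dup]))
}

# punctuation here: any character that is not alphanumeric or whitespace
.PUNCT <- "[^[:alnum:][:space:]]"

#' Flag excessive or misplaced punctuation in a short form
#'
#' A short form is flagged when it starts with punctuation, ends with a
#' punctuation run other than a single period (trailing periods are
#' ordinary abbreviation style, as in \code{"O.C."}), or contains two or
#' more consecutive punctuation characters anywhere (as in \code{"..MS"}).
#' Each sub-rule can be disabled.
#'
#' @param sf character vector of short forms.
#' @param leading,trailing,runs enable the three sub-rules.
#' @return logical vector: \code{TRUE} where flagged.
#' @export
flagPunctuation <- function(sf, leading = TRUE, trailing = TRUE,
                            runs = TRUE) {
  x <- trimws(sf)
  out <- rep(FALSE, length(x))
  if (leading) out <- out | grepl(paste0("^", .PUNCT), x)
  if (trailing) {
    # a single trailing period is allowed (ordinary abbreviation style)
    trail <- grepl(paste0(.PUNCT, "$"), x) &
      !(grepl("\\.$", x) & !grepl(paste0(.PUNCT, "{2}$"), x))
    out <- out | trail
  }
  if (runs) out <- out | grepl(paste0(.PUNCT, "{2,}"), x)
  out
}

#' Flag short-form characters missing from the long form
#'
#' Case-folded character-membership check: flags when any alphanumeric
#' character of the short form does not occur anywhere in the long form
#' (order is not considered). Catches mismatched records such as
#' \code{"qd"} / \code{"every day"}; initialisms whose letters all appear,
#' like \code{"MS"} / \code{"multiple sclerosis"}, pass.
#'
#' @param sf,lf character vectors (elementwise pairs).
#' @return logical vector: \code{TRUE} where flagged.
#' @export
flagCharMismatch <- function(sf, lf) {
  n <- max(length(sf), length(lf))
  sf <- rep_len(tolower(sf), n)
  lf <- rep_len(tolower(lf), n)
  vapply(seq_len(n), function(i) {
    chars <- unique(strsplit(gsub("[^a-z0-9]", "", sf[i]), "")[[1]])
    if (!length(chars)) return(FALSE)
    lfChars <- strsplit(lf[i], "")[[1]]
    !all(chars %in% lfChars)
  }, logical(1))
}

#' Flag possible spelling errors in a long form
#'
#' Compares each purely alphabetic token of length at least \code{minLen}
#' (default 4; shorter tokens are too often legitimate abbreviations or
#' acronyms embedded in the long form) against a word corpus, flagging the
#' long form when any such token is absent. Advisory only: corrections are
#' a human decision.
#'
#' @param lf character vector of long forms.
#' @param corpus character vector of known words (case-insensitive).
#' @param minLen minimum token length checked, default 4.
#' @return list with logical \code{flagged} and character \code{detail}
#'   (offending tokens, comma-separated).
#' @export
flagSpelling <- function(lf, corpus, minLen = 4L) {
  if (!length(corpus)) stop("word corpus is empty")
  corpus <- unique(tolower(corpus))
  res <- lapply(lf, function(x) {
    toks <- .tokens(tolower(x))
    toks <- toks[grepl("^[a-z]+$", toks) & nchar(toks) >= minLen]
    bad <- unique(toks[!(toks %in% corpus)])
    bad
  })
  list(flagged = lengths(res) > 0,
       detail = vapply(res, paste, "", collapse = ", "))
}

#' Run all four quality-control heuristics
#'
#' Applies, in record order and in a fixed heuristic order (duplicate,
#' punctuation, character mismatch, spelling), the four error-detection
#' rules and returns every flag raised; a record can be flagged by several
#' heuristics. Flags are advisory — [applyActions()] performs the actual
#' modify/retire step after review.
#'
#' @param inv a [SenseInventory-class] with record ids assigned.
#' @param corpus word corpus for the spelling heuristic.
#' @param minLen minimum token length for the spelling heuristic.
#' @return data.frame of flags (\code{record_id}, \code{heuristic},
#'   \code{detail}).
#' @export
runQC <- function(inv, corpus, minLen = 4L) {
  stopifnot(is(inv, "SenseInventory"))
  rec <- records(inv)
  dup <- flagIntraSourceDuplicates(inv)
  punct <- flagPunctuation(rec$sf)
  mism <- flagCharMismatch(rec$sf, rec$lf)
  sp <- flagSpelling(rec$lf, corpus, minLen)
  mkFlags <- function(ids, heuristic, detail) {
    data.frame(record_id = ids, heuristic = rep(heuristic, length(ids)),
               detail = rep_len(detail, length(ids)))
  }
  flags <- rbind(
    dup,
    mkFlags(rec$record_id[punct], "punctuation",
            paste0("short form \"", rec$sf[punct], "\"")),
    mkFlags(rec$record_id[mism], "char_mismatch",
            paste0("short form characters missing from \"",
                   rec$lf[mism], "\"")),
    mkFlags(rec$record_id[sp$flagged], "spelling",
            paste0("unknown token(s): ", sp$detail[sp$flagged])))
  ordH <- match(flags$heuristic,
                c("duplicate", "punctuation", "char_mismatch", "spelling"))
  flags <- flags[order(.idIndex(flags$record_id), ordH), , drop = FALSE]
  rownames(flags) <- NULL
  flags
}

#' Apply modify/retire actions to an inventory
#'
#' Retired records are removed from the active inventory into a retired
#' one with their original fields intact (a side table, so no information
#' is lost); modified records get their corrected short/long forms, have
#' normalized forms recomputed, and are marked \code{"modified"}. Record
#' identifiers never change, preserving source transparency. Records
#' without an action are kept untouched.
#'
#' @param inv a [SenseInventory-class].
#' @param actions data.frame with columns \code{record_id}, \code{action}
#'   (\code{"keep"}, \code{"modify"}, \code{"retire"}), and optional
#'   \code{corrected_sf}, \code{corrected_lf} (empty string = unchanged; a
#'   modify action must correct at least one field).
#' @param cfg a \code{"NormalizationConfig"} for re-normalization.
#' @return list with \code{active} and \code{retired}
#'   [SenseInventory-class] objects.
#' @export
applyActions <- function(inv, actions, cfg = normConfig()) {
  stopifnot(is(inv, "SenseInventory"))
  rec <- records(inv)
  if (is.null(actions) || !nrow(actions)) {
    return(list(active = inv,
                retired = SenseInventory(rec[0, , drop = FALSE],
                                         sourceOrder = sourceOrder(inv),
                                         auxSchema = auxSchema(inv))))
  }
  if (!all(actions$action %in% c("keep", "modify", "retire")))
    stop("unknown action value(s)")
  ix <- match(actions$record_id, rec$record_id)
  if (any(is.na(ix)))
    stop("action references unknown record id(s): ",
         paste(actions$record_id[is.na(ix)], collapse = ", "))
  csf <- if (is.null(actions$corrected_sf)) character(nrow(actions))
         else ifelse(is.na(actions$corrected_sf), "", actions$corrected_sf)
  clf <- if (is.null(actions$corrected_lf)) character(nrow(actions))
         else ifelse(is.na(actions$corrected_lf), "", actions$corrected_lf)
  mod <- actions$action == "modify"
  if (any(mod & !nzchar(csf) & !nzchar(clf)))
    stop("modify action must supply corrected_sf and/or corrected_lf")
  for (k in which(mod)) {
    i <- ix[k]
    if (nzchar(csf[k])) rec$sf[i] <- csf[k]
    if (nzchar(clf[k])) rec$lf[i] <- clf[k]
    rec$norm_sf[i] <- normalizeShortForm(rec$sf[i])
    rec$norm_lf[i] <- normalizeLongForm(rec$lf[i], cfg)
    rec$modified[i] <- "modified"
  }
  retireIx <- ix[actions$action == "retire"]
  active <- if (length(retireIx)) rec[-retireIx, , drop = FALSE] else rec
  retired <- rec[retireIx, , drop = FALSE]
  list(active = SenseInventory(active, sourceOrder = sourceOrder(inv),
                               auxSchema = auxSchema(inv)),
       retired = SenseInventory(retired, sourceOrder = sourceOrder(inv),
                                auxSchema = auxSchema(inv)))
}
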