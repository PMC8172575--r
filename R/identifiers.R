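#' Format a non-semantic unique identifier
#'
#' Identifiers are a prefix letter plus a zero-padded index: \code{"R"} for
#' records, \code{"S"} for unique short forms, \code{"L"} for unique long
#' forms and \code{"G"} for synonym groups (e.g. \code{R000001}). Indices
#' beyond 999,999 widen the digit field rather than wrap.
#'
#' @param prefix single character, one of \code{"R"}, \code{"S"},
#'   \code{"L"}, \code{"G"}.
#' @param n positive integer index (vectorised).
#' @return character vector of identifiers.
#' @examples
#' formatId("R", 1:3)
#' formatId("L", 1000000)
#' @export
formatId <- function(prefix, n) {
  stopifnot(length(prefix) == 1L, prefix %in% c("R", "S", "L", "G"))
  if (length(n) && (any(is.na(n)) || any(n < 1) || any(n != floor(n))))
    stop("index must be a positive integer")
  sprintf("%s%06.0f", prefix, n)
}

# numeric part of an identifier (NA for empty strings)
.idIndex <- function(id) {
  out <- suppressWarnings(as.numeric(sub("^[RSLG]", "", id)))
  out[!nzchar(id)] <- NA_real_
  out
}

#' Assign record identifiers in inventory order
#'
#' Record k (1-based, in inventory order) receives \code{formatId("R", k)}.
#' Because source order is preserved by [mergeSources()], this reproduces
#' assignment "in the original order of the source". Existing identifiers
#' are never silently overwritten.
#'
#' @param inv a [SenseInventory-class].
#' @param force overwrite existing record identifiers? Default \code{FALSE}.
#' @return The inventory with \code{record_id} populated.
#' @export
assignRecordIds <- function(inv, force = FALSE) {
  stopifnot(is(inv, "SenseInventory"))
  rec <- records(inv)
  if (!force && any(nzchar(rec$record_id)))
    stop("records already carry identifiers; use force = TRUE to reassign")
  rec$record_id <- if (nrow(rec)) formatId("R", seq_len(nrow(rec))) else character(0)
  .setRecords(inv, rec)
}

#' Assign unique short-form or long-form identifiers
#'
#' Each distinct raw string (the short form for \code{which = "short_form"},
#' the long form otherwise) receives one identifier, numbered by first
#' occurrence in record order; every record carrying that string shares it.
#' Uniqueness is keyed on the raw string, not the normalized one: the data
#' dictionary gives \code{"O.C."} its own SFUI while \code{"oc"} is a
#' separate normalized field.
#'
#' @param inv a [SenseInventory-class] whose records carry record ids.
#' @param which \code{"short_form"} or \code{"long_form"}.
#' @return The inventory with \code{sfui} (resp. \code{lfui}) populated.
#' @export
assignStringIds <- function(inv, which = c("short_form", "long_form")) {
  stopifnot(is(inv, "SenseInventory"))
  which <- match.arg(which)
  rec <- records(inv)
  if (nrow(rec) && any(!nzchar(rec$record_id)))
    stop("assign record identifiers first")
  key <- if (which == "short_form") rec$sf else rec$lf
  idx <- match(key, unique(key))
  ids <- if (nrow(rec)) formatId(if (which == "short_form") "S" else "L", idx)
         else character(0)
  if (which == "short_form") rec$sfui <- ids else rec$lfui <- ids
  .setRecords(inv, rec)
}
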