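#' @import methods
NULL

# Internal column names of the record table, in core on-disk order.
.CORE_COLS <- c("group_id", "record_id", "sf", "sfui", "norm_sf",
                "lf", "lfui", "norm_lf", "source", "modified")

# On-disk header names (data-dictionary style), same order.
.CORE_HEADERS <- c("GroupID", "RecordID", "SF", "SFUI", "NormSF",
                   "LF", "LFUI", "NormLF", "Source", "Modified")

# Marker used where lexical normalization yields an empty result.
.NULL_MARKER <- "null"

#' SenseInventory: a table of abbreviation sense records
#'
#' An ordered collection of records, each linking one short form (an
#' abbreviation such as \code{"MS"}) to one long form (a spelled-out sense
#' such as \code{"multiple sclerosis"}) in one source inventory. Records
#' additionally carry lexically normalized forms, non-semantic unique
#' identifiers (\code{R}/\code{S}/\code{L} prefixes), a synonym-group
#' identifier (\code{G} prefix) once cross-mapping has run, and a
#' \code{modified} flag set by the quality-control workflow.
#'
#' @slot records data.frame with the ten core character columns
#'   (\code{group_id}, \code{record_id}, \code{sf}, \code{sfui},
#'   \code{norm_sf}, \code{lf}, \code{lfui}, \code{norm_lf}, \code{source},
#'   \code{modified}) followed by any auxiliary columns declared in
#'   \code{auxSchema}. Row order is meaningful and preserved by all
#'   operations.
#' @slot sourceOrder character vector of source inventory names in input
#'   order; every record's \code{source} must appear here.
#' @slot auxSchema named list mapping each source name to the character
#'   vector of auxiliary column names that source contributes (auxiliary
#'   fields are unique to a single source).
#'
#' @seealso [SenseInventory()] for the constructor, [readInventory()],
#'   [writeInventory()], [mergeSources()].
#' @export
setClass("SenseInventory",
  representation(records = "data.frame",
                 sourceOrder = "character",
                 auxSchema = "list"))

setValidity("SenseInventory", function(object) {
  rec <- object@records
  msgs <- character(0)
  missing <- setdiff(.CORE_COLS, colnames(rec))
  if (length(missing))
    msgs <- c(msgs, paste0("records lacks core column(s): ",
                           paste(missing, collapse = ", ")))
  if (!length(msgs)) {
    if (!all(vapply(rec, is.character, logical(1))))
      msgs <- c(msgs, "all record columns must be character")
    if (nrow(rec)) {
      if (any(!nzchar(trimws(rec$sf))) || any(!nzchar(trimws(rec$lf))))
        msgs <- c(msgs, "every record must have non-empty SF and LF")
      bad <- setdiff(unique(rec$source), object@sourceOrder)
      if (length(bad))
        msgs <- c(msgs, paste0("source(s) not in sourceOrder: ",
                               paste(bad, collapse = ", ")))
      chk <- function(col, pref) {
        v <- rec[[col]]
        v <- v[nzchar(v)]
        if (length(v) && !all(grepl(paste0("^", pref, "[0-9]{6,}$"), v)))
          paste0(col, " values must match ^", pref, "[0-9]{6,}$ or be empty")
      }
      msgs <- c(msgs,
                unlist(mapply(chk, c("group_id", "record_id", "sfui", "lfui"),
                              c("G", "R", "S", "L"), SIMPLIFY = FALSE)))
    }
    aux <- setdiff(colnames(rec), .CORE_COLS)
    declared <- unique(unlist(object@auxSchema, use.names = FALSE))
    extra <- setdiff(aux, declared)
    if (length(extra))
      msgs <- c(msgs, paste0("undeclared auxiliary column(s): ",
                             paste(extra, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

.emptyRecords <- function(aux = character(0)) {
  cols <- c(.CORE_COLS, aux)
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}

#' Construct a SenseInventory
#'
#' @param records data.frame holding at least \code{sf}, \code{lf} and
#'   \code{source} columns (character). Missing core columns are added
#'   empty; any other columns are treated as auxiliary fields.
#' @param sourceOrder character vector of source names; defaults to the
#'   order of first appearance in \code{records}.
#' @param auxSchema named list source -> auxiliary column names; defaults
#'   to attributing every auxiliary column to every source that has a
#'   non-empty value in it.
#' @return A validated [SenseInventory-class] object.
#' @examples
#' inv <- SenseInventory(data.frame(sf = "O.C.", lf = "oral contraceptives",
#'                                  source = "ADAM"))
#' nrow(records(inv))
#' @export
SenseInventory <- function(records = .emptyRecords(),
                           sourceOrder = NULL, auxSchema = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- setdiff(c("sf", "lf", "source"), colnames(records))
  if (length(need) && nrow(records))
    stop("records must contain column(s): ", paste(need, collapse = ", "))
  for (col in .CORE_COLS)
    if (is.null(records[[col]])) records[[col]] <- rep("", nrow(records))
  records[] <- lapply(records, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  aux <- setdiff(colnames(records), .CORE_COLS)
  records <- records[, c(.CORE_COLS, aux), drop = FALSE]
  rownames(records) <- NULL
  if (is.null(sourceOrder))
    sourceOrder <- unique(records$source)
  if (is.null(auxSchema)) {
    auxSchema <- lapply(setNames(nm = sourceOrder), function(src) {
      if (!length(aux)) return(character(0))
      has <- vapply(aux, function(a)
        any(nzchar(records[[a]][records$source == src])), logical(1))
      # a column with no non-empty value anywhere is attributed to all
      if (!any(unlist(lapply(aux, function(a) any(nzchar(records[[a]])))))) {
        aux
      } else aux[has]
    })
    # make sure every aux column is declared somewhere
    undeclared <- setdiff(aux, unique(unlist(auxSchema)))
    if (length(undeclared) && length(sourceOrder))
      auxSchema[[1]] <- c(auxSchema[[1]], undeclared)
  }
  new("SenseInventory", records = records,
      sourceOrder = as.character(sourceOrder), auxSchema = auxSchema)
}

#' @describeIn SenseInventory-class record table accessor
#' @param x,object a \code{SenseInventory}
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname SenseInventory-class
#' @export
setMethod("records", "SenseInventory", function(x) x@records)

#' @describeIn SenseInventory-class source names in input order
#' @export
setGeneric("sourceOrder", function(x) standardGeneric("sourceOrder"))

#' @rdname SenseInventory-class
#' @export
setMethod("sourceOrder", "SenseInventory", function(x) x@sourceOrder)

#' @describeIn SenseInventory-class auxiliary-field schema (source -> columns)
#' @export
setGeneric("auxSchema", function(x) standardGeneric("auxSchema"))

#' @rdname SenseInventory-class
#' @export
setMethod("auxSchema", "SenseInventory", function(x) x@auxSchema)

#' @describeIn SenseInventory-class number of records
#' @export
setMethod("length", "SenseInventory", function(x) nrow(x@records))

#' @rdname SenseInventory-class
#' @export
setMethod("show", "SenseInventory", function(object) {
  rec <- object@records
  cat("SenseInventory with", nrow(rec), "record(s) from",
      length(object@sourceOrder), "source(s)\n")
  if (length(object@sourceOrder))
    cat("sources:", paste(object@sourceOrder, collapse = ", "), "\n")
  aux <- setdiff(colnames(rec), .CORE_COLS)
  if (length(aux))
    cat("auxiliary fields:", paste(aux, collapse = ", "), "\n")
  if (nrow(rec)) {
    n <- min(5L, nrow(rec))
    print(utils::head(rec[, c("record_id", "sf", "norm_sf", "lf",
                              "norm_lf", "source", "group_id")], n))
    if (nrow(rec) > n) cat("... and", nrow(rec) - n, "more\n")
  }
  invisible(NULL)
})

# internal: replace the record table, keeping class metadata
.setRecords <- function(inv, records) {
  rownames(records) <- NULL
  initialize(inv, records = records)
}
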