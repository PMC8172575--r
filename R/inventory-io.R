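#' Read a sense inventory from a delimited text file
#'
#' Parses a tab-separated inventory table with a header row. Core columns
#' are recognised by their data-dictionary names (\code{GroupID},
#' \code{RecordID}, \code{SF}, \code{SFUI}, \code{NormSF}, \code{LF},
#' \code{LFUI}, \code{NormLF}, \code{Source}, \code{Modified}); \code{SF},
#' \code{LF} and \code{Source} are mandatory, the others default to empty.
#' Any unrecognised column is carried along as an auxiliary field of the
#' sources that populate it. Text is decoded as UTF-8 and normalized to
#' Unicode NFC so that identifier assignment and string metrics are stable
#' across input encodings.
#'
#' @param path path to the file.
#' @param sep field delimiter, default tab.
#' @return A [SenseInventory-class] with one record per data row, in file
#'   order.
#' @export
readInventory <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  df[] <- lapply(df, function(x) stringi::stri_trans_nfc(x))
  hdr <- colnames(df)
  mandatory <- c("SF", "LF", "Source")
  miss <- setdiff(mandatory, hdr)
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  known <- intersect(.CORE_HEADERS, hdr)
  out <- as.data.frame(setNames(
    lapply(known, function(h) df[[h]]),
    .CORE_COLS[match(known, .CORE_HEADERS)]), stringsAsFactors = FALSE)
  badRows <- which(!nzchar(trimws(out$sf)) | !nzchar(trimws(out$lf)))
  if (length(badRows))
    stop("empty SF or LF in data row(s): ",
         paste(utils::head(badRows, 10), collapse = ", "))
  aux <- setdiff(hdr, .CORE_HEADERS)
  for (a in aux) out[[a]] <- df[[a]]
  SenseInventory(out)
}

# quote a field only when the dialect requires it (embedded tab, newline,
# quote, or a leading quote that would be misread)
.quoteField <- function(x, sep = "\t") {
  need <- grepl(sep, x, fixed = TRUE) | grepl("[\n\r\"]", x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

#' Write a sense inventory to a delimited text file
#'
#' Emits a UTF-8, tab-separated table with a header row and minimal
#' quoting: only fields containing a delimiter, newline or quote character
#' are quoted. The ten core columns are always written; auxiliary columns
#' are appended after \code{Modified} when \code{includeAux} is \code{TRUE}
#' (the "auxiliary version" of the table).
#'
#' @param inv a [SenseInventory-class].
#' @param path output file path.
#' @param includeAux append auxiliary columns? Default \code{TRUE}.
#' @param sep field delimiter, default tab.
#' @return \code{path}, invisibly.
#' @export
writeInventory <- function(inv, path, includeAux = TRUE, sep = "\t") {
  stopifnot(is(inv, "SenseInventory"))
  rec <- records(inv)
  aux <- setdiff(colnames(rec), .CORE_COLS)
  cols <- .CORE_COLS
  hdrs <- .CORE_HEADERS
  if (includeAux && length(aux)) {
    cols <- c(cols, aux)
    hdrs <- c(hdrs, aux)
  }
  lines <- paste(hdrs, collapse = sep)
  if (nrow(rec)) {
    body <- do.call(paste, c(lapply(rec[cols], .quoteField, sep = sep),
                             sep = sep))
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

#' Concatenate inventories from distinct sources
#'
#' Appends the record tables of several inventories, preserving
#' within-source record order and the order of the inputs. Auxiliary
#' schemas are unioned per source; a source name occurring in more than
#' one input is an error because record provenance would become ambiguous.
#'
#' @param inventories non-empty list of [SenseInventory-class] objects.
#' @return A single merged [SenseInventory-class].
#' @export
mergeSources <- function(inventories) {
  if (!length(inventories)) stop("need at least one inventory")
  stopifnot(all(vapply(inventories, is, logical(1), "SenseInventory")))
  srcs <- unlist(lapply(inventories, sourceOrder))
  if (anyDuplicated(srcs))
    stop("duplicate source name across inputs: ",
         paste(unique(srcs[duplicated(srcs)]), collapse = ", "))
  allAux <- unique(unlist(lapply(inventories, function(i)
    setdiff(colnames(records(i)), .CORE_COLS))))
  tabs <- lapply(inventories, function(i) {
    rec <- records(i)
    for (a in setdiff(allAux, colnames(rec))) rec[[a]] <- rep("", nrow(rec))
    rec[, c(.CORE_COLS, allAux), drop = FALSE]
  })
  merged <- do.call(rbind, tabs)
  schema <- do.call(c, lapply(inventories, auxSchema))
  SenseInventory(merged, sourceOrder = srcs, auxSchema = schema)
}
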