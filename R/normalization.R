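#' Normalization configuration
#'
#' Bundles the rule tables driving long-form normalization and pre-pairing
#' text replacement. Long-form normalization follows a fixed flow —
#' genitive removal, plural stripping, punctuation replacement, stop-word
#' removal, lowercasing, uninflection, synonym substitution — with token
#' order preserved throughout (no alphabetical sorting). The flow order is
#' the contract; the rule tables here are deliberately small, deterministic
#' approximations of a full lexical-variant generator and can be replaced
#' wholesale.
#'
#' @param stopWords words removed during normalization (matched
#'   case-insensitively as whole tokens).
#' @param pluralExceptions alphabetic tokens never de-pluralized.
#' @param synonymMap named character vector mapping a word to its canonical
#'   form; applied after all other steps. Must be idempotent (canonical
#'   words map to themselves or are absent).
#' @param replacementTable named character vector used by
#'   [normalizeForPairing()]: whole lowercase tokens matching a name are
#'   replaced by the value. The default maps roman numerals i–x to arabic
#'   digits and five common ion symbols to their element/ion names.
#' @return A list of class \code{"NormalizationConfig"}.
#' @export
normConfig <- function(stopWords = c("a", "an", "the", "of", "and", "with",
                                     "for", "in", "on", "to", "by"),
                       pluralExceptions = c("gas", "lens", "aids", "diabetes",
                                            "herpes", "pancreas", "this",
                                            "has", "its", "was"),
                       synonymMap = character(0),
                       replacementTable = c(
                         i = "1", ii = "2", iii = "3", iv = "4", v = "5",
                         vi = "6", vii = "7", viii = "8", ix = "9", x = "10",
                         "na+" = "sodium", "k+" = "potassium",
                         "ca2+" = "calcium", "cl-" = "chloride",
                         "mg2+" = "magnesium")) {
  if (length(synonymMap)) {
    canon <- unname(synonymMap)
    mapped <- synonymMap[canon[canon %in% names(synonymMap)]]
    if (length(mapped) && !all(mapped == names(mapped)))
      stop("synonymMap must be idempotent")
  }
  structure(list(stopWords = tolower(stopWords),
                 pluralExceptions = tolower(pluralExceptions),
                 synonymMap = synonymMap,
                 replacementTable = replacementTable),
            class = "NormalizationConfig")
}

#' Read a normalization configuration from a plain-text file
#'
#' One rule per line, tab-separated: \code{stopword<TAB>word},
#' \code{plural_exception<TAB>word}, \code{synonym<TAB>word<TAB>canonical},
#' \code{replacement<TAB>token<TAB>text}. Lines starting with \code{#} are
#' ignored. Omitted rule kinds fall back to the defaults of [normConfig()].
#'
#' @param path file path.
#' @return A \code{"NormalizationConfig"} list.
#' @export
readNormConfig <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(parts, `[`, "", 1L)
  pick2 <- function(k) vapply(parts[kind == k], `[`, "", 2L)
  pick3 <- function(k) {
    p <- parts[kind == k]
    setNames(vapply(p, `[`, "", 3L), vapply(p, `[`, "", 2L))
  }
  dflt <- normConfig()
  normConfig(
    stopWords = if (any(kind == "stopword")) pick2("stopword") else dflt$stopWords,
    pluralExceptions = if (any(kind == "plural_exception"))
      pick2("plural_exception") else dflt$pluralExceptions,
    synonymMap = if (any(kind == "synonym")) pick3("synonym") else dflt$synonymMap,
    replacementTable = if (any(kind == "replacement"))
      pick3("replacement") else dflt$replacementTable)
}

#' Normalize a short form
#'
#' Lowercases, strips leading/trailing whitespace, deletes periods, replaces
#' every remaining non-alphanumeric non-space character with an underscore,
#' and collapses internal whitespace runs to a single underscore. A short
#' form that vanishes entirely (all periods/whitespace) yields the literal
#' marker \code{"null"}. Idempotent.
#'
#' @param sf character vector of raw short forms.
#' @return character vector of normalized short forms.
#' @examples
#' normalizeShortForm(c("O.C.", " D/C ", "MS"))
#' @export
normalizeShortForm <- function(sf) {
  x <- tolower(trimws(sf))
  x <- gsub(".", "", x, fixed = TRUE)
  x <- gsub("\\s+", "_", x)
  x <- gsub("[^a-z0-9_ ]", "_", x)
  x[!nzchar(x)] <- .NULL_MARKER
  x
}

# split on whitespace runs; "" -> character(0)
.tokens <- function(x) {
  t <- strsplit(trimws(x), "\\s+")[[1]]
  t[nzchar(t)]
}

.stripPlural <- function(tok, exceptions) {
  low <- tolower(tok)
  if (!grepl("^[a-z]+$", low) || low %in% exceptions) return(tok)
  n <- nchar(low)
  if (n > 4 && endsWith(low, "ies")) return(paste0(substr(tok, 1, n - 3), "y"))
  if (n > 4 && grepl("(ses|xes|zes|ches|shes)$", low))
    return(substr(tok, 1, n - 2))
  if (n > 3 && endsWith(low, "s") &&
      !grepl("(ss|us|is)$", low)) return(substr(tok, 1, n - 1))
  tok
}

.uninflect <- function(tok) {
  if (!grepl("^[a-z]+$", tok)) return(tok)
  n <- nchar(tok)
  stem <- NULL
  if (n >= 6 && endsWith(tok, "ing")) stem <- substr(tok, 1, n - 3)
  else if (n >= 5 && endsWith(tok, "ied")) stem <- paste0(substr(tok, 1, n - 3), "y")
  else if (n >= 5 && endsWith(tok, "ed") && !endsWith(tok, "eed"))
    stem <- substr(tok, 1, n - 2)
  if (is.null(stem)) return(tok)
  m <- nchar(stem)
  if (m >= 2 && substr(stem, m, m) == substr(stem, m - 1, m - 1) &&
      !grepl("[aeiou]", substr(stem, m, m)))
    stem <- substr(stem, 1, m - 1)
  stem
}

#' Normalize a long form
#'
#' Applies, in order: genitive removal, plural stripping, punctuation
#' replacement (punctuation becomes a space), stop-word removal,
#' lowercasing, uninflection, and synonym substitution. Token order is
#' preserved — the flow deliberately avoids alphabetical sorting so that
#' normalized long forms remain readable phrases. The flow is iterated to
#' a fixed point, making the function idempotent even when one step
#' exposes material for an earlier one. An empty result yields the marker
#' \code{"null"}.
#'
#' @param lf character vector of raw long forms.
#' @param cfg a \code{"NormalizationConfig"}; default [normConfig()].
#' @return character vector of normalized long forms (or \code{"null"}).
#' @examples
#' normalizeLongForm("oral contraceptives")
#' normalizeLongForm("coarctation of the aorta")
#' @export
normalizeLongForm <- function(lf, cfg = normConfig()) {
  onePass <- function(x) {
    # g: genitives
    x <- gsub("'s(?=\\s|$)", "", x, perl = TRUE)
    x <- gsub("s'(?=\\s|$)", "s", x, perl = TRUE)
    # rs: plural stripping, token-wise
    toks <- .tokens(x)
    toks <- vapply(toks, .stripPlural, "", exceptions = cfg$pluralExceptions)
    x <- paste(toks, collapse = " ")
    # o: punctuation -> space
    x <- gsub("[^a-zA-Z0-9 ]", " ", x)
    # t: stop words (case-insensitive whole tokens)
    toks <- .tokens(x)
    toks <- toks[!(tolower(toks) %in% cfg$stopWords)]
    # l: lowercase
    toks <- tolower(toks)
    # B: uninflection
    toks <- vapply(toks, .uninflect, "")
    # Ct: synonyms
    if (length(cfg$synonymMap)) {
      hit <- toks %in% names(cfg$synonymMap)
      toks[hit] <- unname(cfg$synonymMap[toks[hit]])
    }
    paste(toks, collapse = " ")
  }
  vapply(lf, function(x) {
    # iterate the flow to its fixed point: a later step (e.g. punctuation
    # removal) can expose material for an earlier one (e.g. a plural
    # hidden behind a trailing hyphen), so a single pass would not be
    # idempotent; after the first pass each iteration can only shorten
    # the string, so this terminates
    repeat {
      out <- onePass(x)
      if (identical(out, x)) break
      x <- out
    }
    if (!nzchar(out)) .NULL_MARKER else out
  }, "", USE.NAMES = FALSE)
}

#' Pre-pairing text normalization
#'
#' Lowercases, splits on whitespace, and replaces whole tokens found in the
#' configuration's replacement table (roman numerals, ion symbols) with
#' their spelled-out or digit forms, so that pairs like "type ii" / "type 2"
#' compare as equal. Everything else is left unchanged apart from
#' whitespace collapsing.
#'
#' @param text character vector.
#' @param cfg a \code{"NormalizationConfig"}.
#' @return character vector of pairing-normalized text.
#' @examples
#' normalizeForPairing(c("type II", "Ca2+ channel"))
#' @export
normalizeForPairing <- function(text, cfg = normConfig()) {
  tab <- cfg$replacementTable
  vapply(text, function(x) {
    toks <- .tokens(tolower(x))
    hit <- toks %in% names(tab)
    toks[hit] <- unname(tab[toks[hit]])
    paste(toks, collapse = " ")
  }, "", USE.NAMES = FALSE)
}

#' Recompute normalized forms on an inventory
#'
#' Fills the \code{norm_sf} and \code{norm_lf} columns from the raw
#' \code{sf}/\code{lf} fields.
#'
#' @param inv a [SenseInventory-class].
#' @param cfg a \code{"NormalizationConfig"}.
#' @return The inventory with normalized columns populated.
#' @export
normalizeInventory <- function(inv, cfg = normConfig()) {
  stopifnot(is(inv, "SenseInventory"))
  rec <- records(inv)
  rec$norm_sf <- normalizeShortForm(rec$sf)
  rec$norm_lf <- normalizeLongForm(rec$lf, cfg)
  .setRecords(inv, rec)
}
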