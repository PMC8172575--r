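# round half away from zero (matches how the summary percentages print)
.roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Integer percentage share
#'
#' \code{round(100 * numerator / denominator)} with halves rounded away
#' from zero.
#'
#' @param numerator,denominator counts; denominator must be positive.
#' @return integer percent.
#' @examples
#' sharePercent(107650, 405543)
#' @export
sharePercent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  as.integer(.roundHalfUp(100 * numerator / denominator))
}

#' Mean number of senses per abbreviation
#'
#' Ratio of synonym groups to unique short forms, rounded to
#' \code{decimals} places: after cross-mapping, each group is one sense,
#' so this is the average ambiguity of an abbreviation.
#'
#' @param nGroups number of synonym groups.
#' @param nUniqueSf number of unique short forms; must be positive.
#' @param decimals decimal places, default 2.
#' @return numeric.
#' @examples
#' meanSenses(183817, 104057)
#' @export
meanSenses <- function(nGroups, nUniqueSf, decimals = 2L) {
  if (any(nUniqueSf <= 0)) stop("nUniqueSf must be positive")
  .roundHalfUp(nGroups / nUniqueSf, decimals)
}

#' Processing-time reduction from using groups instead of records
#'
#' Integer percentage \code{100 * (1 - nGroups / nRecords)}: the share of
#' linear scanning work saved when downstream tasks iterate over synonym
#' groups rather than raw records.
#'
#' @param nRecords record count; must satisfy
#'   \code{nRecords >= nGroups > 0}.
#' @param nGroups group count.
#' @return integer percent.
#' @examples
#' lookupReductionPercent(405543, 183817)
#' @export
lookupReductionPercent <- function(nRecords, nGroups) {
  if (any(nGroups <= 0) || any(nRecords < nGroups))
    stop("need nRecords >= nGroups > 0")
  as.integer(.roundHalfUp(100 * (1 - nGroups / nRecords)))
}

#' Summary statistics of a harmonized inventory
#'
#' Tabulates the redundancy and ambiguity structure of an inventory after
#' cross-mapping: record/short-form/long-form/pair counts, group counts,
#' how many records have no synonym (singleton groups), and the
#' distribution of senses (groups) per normalized short form.
#'
#' @param inv a [SenseInventory-class] with group ids assigned.
#' @return list of class \code{"InventoryStats"}: \code{n_records},
#'   \code{n_unique_sf}, \code{n_unique_lf}, \code{n_unique_pairs},
#'   \code{n_groups}, \code{n_records_without_synonyms},
#'   \code{mean_senses_per_sf}, \code{max_senses}, \code{argmax_sf},
#'   \code{n_sf_multi_sense}, \code{n_sf_four_plus},
#'   \code{pct_without_synonyms}, \code{pct_multi_sense},
#'   \code{pct_four_plus}, \code{lookup_reduction_pct}.
#' @export
summarizeInventory <- function(inv) {
  stopifnot(is(inv, "SenseInventory"))
  rec <- records(inv)
  if (!nrow(rec)) stop("empty inventory")
  if (any(!nzchar(rec$group_id)))
    stop("assign group identifiers first")
  groupSize <- table(rec$group_id)
  sensesPerSf <- vapply(split(rec$group_id, rec$norm_sf),
                        function(g) length(unique(g)), 0L)
  nGroups <- length(groupSize)
  nSf <- length(sensesPerSf)
  maxIx <- which.max(sensesPerSf)
  # "abbreviation" means normalized short form throughout: lexical variants
  # like "O.C." and "OC" are one abbreviation
  out <- list(
    n_records = nrow(rec),
    n_unique_sf = nSf,
    n_unique_lf = length(unique(rec$lf)),
    n_unique_pairs = length(unique(paste(rec$sf, rec$lf, sep = "\r"))),
    n_groups = nGroups,
    n_records_without_synonyms =
      sum(rec$group_id %in% names(groupSize)[groupSize == 1]),
    mean_senses_per_sf = meanSenses(nGroups, nSf),
    max_senses = unname(sensesPerSf[maxIx]),
    argmax_sf = names(sensesPerSf)[maxIx],
    n_sf_multi_sense = sum(sensesPerSf > 1),
    n_sf_four_plus = sum(sensesPerSf >= 4))
  out$pct_without_synonyms <-
    sharePercent(out$n_records_without_synonyms, out$n_records)
  out$pct_multi_sense <- sharePercent(out$n_sf_multi_sense, nSf)
  out$pct_four_plus <- sharePercent(out$n_sf_four_plus, nSf)
  out$lookup_reduction_pct <- lookupReductionPercent(out$n_records, nGroups)
  structure(out, class = "InventoryStats")
}

#' @export
print.InventoryStats <- function(x, ...) {
  cat("Inventory summary\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
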