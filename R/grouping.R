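#' Build synonym groups from positive pairs
#'
#' Partitions the records into synonym groups: nodes are records, edges
#' are classifier-positive pairs, and groups are the connected components
#' of that graph. Classifier non-transitivity is thereby resolved by
#' closure (if A~B and B~C, then A, B, C share one group), and records
#' without any synonym become singleton groups. Pairs are required to stay
#' within one normalized-short-form block, since a group represents one
#' sense of one abbreviation.
#'
#' @param inv a [SenseInventory-class] with record ids and \code{norm_sf}
#'   assigned.
#' @param positivePairs data.frame with \code{record_id_a},
#'   \code{record_id_b} (e.g. the positive subset of [predictPairs()]
#'   output), or NULL/empty for no links.
#' @return list of groups, each a list with \code{member_record_ids}
#'   (character, sorted by record index) and \code{norm_sf}.
#' @export
buildGroups <- function(inv, positivePairs = NULL) {
  stopifnot(is(inv, "SenseInventory"))
  rec <- records(inv)
  if (nrow(rec) && any(!nzchar(rec$record_id)))
    stop("assign record identifiers first")
  ids <- rec$record_id
  if (is.null(positivePairs) || !nrow(positivePairs)) {
    membership <- seq_along(ids)
  } else {
    a <- match(positivePairs$record_id_a, ids)
    b <- match(positivePairs$record_id_b, ids)
    if (any(is.na(a)) || any(is.na(b)))
      stop("pair references record id(s) absent from the inventory")
    bad <- rec$norm_sf[a] != rec$norm_sf[b]
    if (any(bad))
      stop("pair(s) span different normalized short forms: ",
           paste(utils::head(paste(positivePairs$record_id_a[bad],
                                   positivePairs$record_id_b[bad]), 5),
                 collapse = "; "))
    g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(ids) - igraph::vcount(g)))
    membership <- igraph::components(g)$membership[seq_along(ids)]
  }
  idxByGroup <- split(seq_along(ids), membership)
  lapply(unname(idxByGroup), function(ix)
    list(member_record_ids = ids[ix], norm_sf = rec$norm_sf[ix[1]]))
}

#' Assign group identifiers and write them onto the inventory
#'
#' Orders groups by their smallest member record identifier (numeric
#' part), numbers them \code{G000001} upward, and sets every member
#' record's \code{group_id} field. Deterministic for a given partition.
#'
#' @param inv a [SenseInventory-class].
#' @param groups list of groups from [buildGroups()].
#' @return list with \code{inventory} (group ids written into the record
#'   table) and \code{groups} (each group gaining a \code{group_id}).
#' @export
assignGroupIds <- function(inv, groups) {
  stopifnot(is(inv, "SenseInventory"))
  rec <- records(inv)
  if (!length(groups)) {
    rec$group_id <- character(nrow(rec))
    return(list(inventory = .setRecords(inv, rec), groups = groups))
  }
  minIdx <- vapply(groups, function(g)
    min(.idIndex(g$member_record_ids)), 0)
  ord <- order(minIdx)
  groups <- groups[ord]
  for (k in seq_along(groups)) groups[[k]]$group_id <- formatId("G", k)
  gid <- character(nrow(rec))
  for (g in groups)
    gid[match(g$member_record_ids, rec$record_id)] <- g$group_id
  rec$group_id <- gid
  list(inventory = .setRecords(inv, rec), groups = groups)
}
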