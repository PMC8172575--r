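#' Harmonize source sense inventories into a concept-oriented meta-inventory
#'
#' Runs the full harmonization pipeline: merge the sources, normalize
#' short and long forms, assign record/short-form/long-form identifiers,
#' flag quality-control errors (applying modify/retire actions when
#' supplied), generate blocked candidate pairs, score them with the
#' synonym classifier, build synonym groups by transitive closure of the
#' positive pairs, assign group identifiers and summarize the result.
#'
#' The classifier is either passed in ready-trained, or trained here from
#' labeled pairs; in the latter case the decision threshold is selected on
#' out-of-fold cross-validation predictions at the requested precision
#' target, so the threshold is never tuned on predictions of a model that
#' has seen the pairs.
#'
#' @param sources list of [SenseInventory-class] objects, or paths to
#'   inventory TSV files.
#' @param labeledPairs data.frame of labeled pairs (features + 0/1
#'   \code{label}) used to train the classifier; ignored when
#'   \code{model} is given.
#' @param model optional pre-trained \code{"synonymModel"}.
#' @param threshold optional fixed probability threshold; when missing it
#'   is selected at \code{targetPrecision} from out-of-fold predictions.
#' @param qcCorpus word corpus for the spelling heuristic; \code{NULL}
#'   skips the spelling heuristic (the other three always run).
#' @param qcActions optional data.frame of modify/retire actions (see
#'   [applyActions()]).
#' @param trainingRatioThreshold Levenshtein ratio cut-off for the
#'   training-candidate filter, default 0.8 (strict).
#' @param partialThreshold partial-ratio cut-off for candidate blocking,
#'   default 0.5 (inclusive).
#' @param targetPrecision precision target for threshold selection,
#'   default 0.99.
#' @param kFolds folds for cross-validation, default 5.
#' @param seed integer seed controlling all randomness.
#' @param cfg a \code{"NormalizationConfig"}.
#' @param params classifier backend parameters (see [trainClassifier()]).
#' @return list of class \code{"HarmonizationResult"}: \code{inventory}
#'   (harmonized, grouped), \code{retired}, \code{flags}, \code{groups},
#'   \code{pairs} (scored candidates), \code{model}, \code{threshold},
#'   \code{cv} (cross-validation report or NULL), \code{stats}.
#' @export
runHarmonize <- function(sources, labeledPairs = NULL, model = NULL,
                         threshold = NULL, qcCorpus = NULL,
                         qcActions = NULL, trainingRatioThreshold = 0.8,
                         partialThreshold = 0.5, targetPrecision = 0.99,
                         kFolds = 5L, seed = 1L, cfg = normConfig(),
                         params = list()) {
  if (is(sources, "SenseInventory")) sources <- list(sources)
  sources <- lapply(sources, function(s)
    if (is.character(s)) readInventory(s) else s)
  inv <- mergeSources(sources)
  inv <- normalizeInventory(inv, cfg)
  inv <- assignRecordIds(inv, force = TRUE)
  inv <- assignStringIds(inv, "short_form")
  inv <- assignStringIds(inv, "long_form")

  flags <- if (!is.null(qcCorpus)) runQC(inv, qcCorpus)
           else {
             rec <- records(inv)
             ids1 <- rec$record_id[flagPunctuation(rec$sf)]
             ids2 <- rec$record_id[flagCharMismatch(rec$sf, rec$lf)]
             f <- rbind(flagIntraSourceDuplicates(inv),
                        data.frame(record_id = ids1,
                                   heuristic = rep("punctuation",
                                                   length(ids1)),
                                   detail = rep("", length(ids1))),
                        data.frame(record_id = ids2,
                                   heuristic = rep("char_mismatch",
                                                   length(ids2)),
                                   detail = rep("", length(ids2))))
             f[order(.idIndex(f$record_id)), , drop = FALSE]
           }
  retired <- NULL
  if (!is.null(qcActions)) {
    res <- applyActions(inv, qcActions, cfg)
    inv <- res$active
    retired <- res$retired
  }

  cv <- NULL
  if (is.null(model)) {
    if (is.null(labeledPairs))
      stop("supply either a trained model or labeled training pairs")
    cv <- crossValidate(labeledPairs, k = kFolds, seed = seed,
                        params = params)
    model <- trainClassifier(labeledPairs, params = params, seed = seed)
    if (is.null(threshold))
      threshold <- selectThreshold(NULL, cv$oof, targetPrecision)
  }
  if (is.null(threshold)) threshold <- 0.5

  pairs <- generateCandidatePairs(inv, partialThreshold, cfg)
  pairs <- predictPairs(model, pairs, threshold, cfg)
  groups <- buildGroups(inv, pairs[pairs$is_synonym, , drop = FALSE])
  g <- assignGroupIds(inv, groups)

  structure(list(inventory = g$inventory, retired = retired, flags = flags,
                 groups = g$groups, pairs = pairs, model = model,
                 threshold = threshold, cv = cv,
                 stats = summarizeInventory(g$inventory)),
            class = "HarmonizationResult")
}

#' @export
print.HarmonizationResult <- function(x, ...) {
  cat("Harmonization result\n")
  cat("  records:      ", x$stats$n_records, "\n")
  cat("  groups:       ", x$stats$n_groups, "\n")
  cat("  candidates:   ", nrow(x$pairs),
      " (positive: ", sum(x$pairs$is_synonym), ")\n", sep = "")
  cat("  threshold:    ", format(x$threshold, digits = 4), "\n")
  if (nrow(x$flags)) {
    tab <- table(x$flags$heuristic)
    cat("  QC flags:     ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  } else cat("  QC flags:      none\n")
  invisible(x)
}
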