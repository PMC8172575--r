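.featureMatrix <- function(data) {
  miss <- setdiff(.FEATURE_COLS, colnames(data))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(data[, .FEATURE_COLS, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("features must be finite")
  m
}

.checkLabels <- function(label) {
  if (!length(label)) stop("no training data")
  if (!all(label %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(label)) < 2)
    stop("training data must contain both classes")
}

#' Train a binary synonym classifier on pair features
#'
#' Fits a model predicting the probability that two long forms of the same
#' abbreviation are synonyms, from the five string-similarity features.
#' The default backend is gradient-boosted trees (xgboost, single thread,
#' fixed seed, hence deterministic); a plain logistic regression backend is
#' available as a fast, fully transparent baseline.
#'
#' @param data data.frame with the five feature columns (see
#'   [featurizePairs()]) and a 0/1 \code{label} column.
#' @param params list of backend settings: \code{backend}
#'   (\code{"xgboost"} or \code{"logistic"}), and for xgboost
#'   \code{nrounds}, \code{max_depth}, \code{eta}.
#' @param seed integer RNG seed for the backend.
#' @return A \code{"synonymModel"} handle usable with [predictPairs()],
#'   [selectThreshold()].
#' @export
trainClassifier <- function(data, params = list(), seed = 1L) {
  .checkLabels(data$label)
  X <- .featureMatrix(data)
  y <- as.numeric(data$label)
  p <- utils::modifyList(list(backend = "xgboost", nrounds = 100L,
                              max_depth = 3L, eta = 0.3), params)
  fit <- if (p$backend == "xgboost") {
    d <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = p$max_depth,
                    eta = p$eta, nthread = 1, seed = as.integer(seed)),
      data = d, nrounds = p$nrounds, verbose = 0)
  } else if (p$backend == "logistic") {
    df <- as.data.frame(X); df$label <- y
    suppressWarnings(stats::glm(label ~ ., data = df,
                                family = stats::binomial()))
  } else stop("unknown backend: ", p$backend)
  structure(list(backend = p$backend, fit = fit, params = p,
                 features = .FEATURE_COLS, seed = as.integer(seed)),
            class = "synonymModel")
}

# probability of the positive class for each row of a feature table
.predictProb <- function(model, data) {
  stopifnot(inherits(model, "synonymModel"))
  X <- .featureMatrix(data)
  if (model$backend == "xgboost") {
    as.numeric(stats::predict(model$fit,
                              xgboost::xgb.DMatrix(X, nthread = 1)))
  } else {
    as.numeric(stats::predict(model$fit, newdata = as.data.frame(X),
                              type = "response"))
  }
}

.prf <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Stratified k-fold cross-validation of the synonym classifier
#'
#' Splits the labeled pairs into \code{k} folds stratified on the label
#' (shuffled under \code{seed}), trains on k-1 folds and scores the
#' held-out fold at probability threshold 0.5. Out-of-fold probabilities
#' are returned as well, for downstream threshold selection without
#' optimistic bias.
#'
#' @inheritParams trainClassifier
#' @param k number of folds, default 5; each class must have at least
#'   \code{k} members.
#' @return list with \code{per_fold} (data.frame of fold precision, recall
#'   and F1), \code{mean_precision}, \code{mean_recall}, \code{mean_f1},
#'   and \code{oof} (data.frame of row index, label, out-of-fold
#'   probability).
#' @export
crossValidate <- function(data, k = 5L, seed = 1L, params = list()) {
  .checkLabels(data$label)
  if (k < 2) stop("k must be at least 2")
  y <- as.numeric(data$label)
  if (min(table(y)) < k)
    stop("each class must have at least k members for stratified folds")
  # canonical content order makes folds (and thus the whole report)
  # invariant to the input row order
  X <- .featureMatrix(data)
  canon <- do.call(order, c(list(y), lapply(seq_len(ncol(X)),
                                            function(j) X[, j])))
  yC <- y[canon]
  foldC <- integer(length(y))
  for (cls in c(0, 1)) {
    pos <- which(yC == cls)
    pos <- .withSeed(seed + cls, sample(pos))
    foldC[pos] <- rep_len(seq_len(k), length(pos))
  }
  fold <- integer(length(y))
  fold[canon] <- foldC
  oofProb <- numeric(length(y))
  perFold <- t(vapply(seq_len(k), function(f) {
    trIdx <- canon[foldC != f]
    teIdx <- canon[foldC == f]
    m <- trainClassifier(data[trIdx, , drop = FALSE], params = params,
                         seed = seed)
    prob <- .predictProb(m, data[teIdx, , drop = FALSE])
    oofProb[teIdx] <<- prob
    .prf(y[teIdx], as.integer(prob >= 0.5))
  }, c(precision = 0, recall = 0, f1 = 0)))
  list(per_fold = as.data.frame(perFold),
       mean_precision = mean(perFold[, "precision"]),
       mean_recall = mean(perFold[, "recall"]),
       mean_f1 = mean(perFold[, "f1"]),
       oof = data.frame(row = seq_len(length(y)), label = y,
                        probability = oofProb, fold = fold))
}

#' Select a high-specificity probability threshold
#'
#' Sweeps the observed predicted probabilities on a validation set and
#' returns the smallest threshold whose precision reaches
#' \code{targetPrecision} (default 0.99): the operating point keeping
#' recall as high as possible while making false synonym links — which
#' would merge distinct senses — very unlikely. When the target is
#' unattainable, the precision-maximizing threshold is returned with a
#' warning.
#'
#' @param model a \code{"synonymModel"}, or \code{NULL} if
#'   \code{validation} already carries a \code{probability} column (e.g.
#'   out-of-fold predictions from [crossValidate()]).
#' @param validation data.frame with \code{label} and either feature
#'   columns or a \code{probability} column; must contain both classes.
#' @param targetPrecision required precision in [0, 1], default 0.99.
#' @return numeric threshold in [0, 1].
#' @export
selectThreshold <- function(model, validation, targetPrecision = 0.99) {
  if (!nrow(validation)) stop("empty validation set")
  .checkLabels(validation$label)
  prob <- if (!is.null(validation$probability)) validation$probability
          else .predictProb(model, validation)
  y <- as.numeric(validation$label)
  cand <- sort(unique(prob))
  prec <- vapply(cand, function(t) {
    pos <- prob >= t
    if (!any(pos)) 1 else sum(y[pos] == 1) / sum(pos)
  }, 0)
  ok <- which(prec >= targetPrecision)
  if (length(ok)) return(cand[ok[1]])
  warning("target precision ", targetPrecision,
          " unattainable on validation; returning precision-maximizing threshold")
  cand[which.max(prec)]
}

#' Classify candidate pairs as synonyms
#'
#' Scores each candidate pair with the trained model and applies the
#' decision threshold; output rows align with input rows. If the pair
#' table lacks feature columns but has \code{lf_a}/\code{lf_b}, features
#' are computed on the fly.
#'
#' @param model a \code{"synonymModel"}.
#' @param pairs data.frame of candidate pairs (see
#'   [generateCandidatePairs()]), with feature columns or
#'   \code{lf_a}/\code{lf_b}.
#' @param threshold probability threshold in [0, 1].
#' @param cfg a \code{"NormalizationConfig"} used if features must be
#'   computed.
#' @return \code{pairs} with \code{probability} and logical
#'   \code{is_synonym} columns appended.
#' @export
predictPairs <- function(model, pairs, threshold = 0.5, cfg = normConfig()) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]")
  if (!nrow(pairs)) {
    pairs$probability <- numeric(0)
    pairs$is_synonym <- logical(0)
    return(pairs)
  }
  if (!all(.FEATURE_COLS %in% colnames(pairs))) {
    if (is.null(pairs$lf_a) || is.null(pairs$lf_b))
      stop("pairs need feature columns or lf_a/lf_b")
    pairs <- cbind(pairs, featurizePairs(pairs$lf_a, pairs$lf_b, cfg))
  }
  prob <- .predictProb(model, pairs)
  pairs$probability <- prob
  pairs$is_synonym <- prob >= threshold
  pairs
}
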