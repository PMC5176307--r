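#' Prevalence-calibrated vote-share cutoff
#'
#' A random forest classifies by majority vote (cutoff 0.5) by default; when
#' the training classes are unbalanced the cutoff is instead set to the
#' non-case class fraction, so the vote threshold reflects the training
#' prevalence. With 601 cases among 1162 children this is 561/1162 = 0.483.
#'
#' @param nCase number of case children in training.
#' @param nTotal total training children; requires `0 < nCase < nTotal`.
#' @return the cutoff `(nTotal - nCase) / nTotal`, in (0, 1).
#' @examples
#' computeCutoff(601, 1162)  # 0.483
#' @export
computeCutoff <- function(nCase, nTotal) {
  if (!(nCase > 0 && nCase < nTotal))
    stop("training data must contain both classes (0 < nCase < nTotal)")
  (nTotal - nCase) / nTotal
}

.checkLabels <- function(labels) {
  labels <- as.character(labels)
  bad <- !labels %in% c("case", "noncase")
  if (any(bad))
    stop("labels must be 'case'/'noncase'; found: ",
         paste(unique(labels[bad]), collapse = ", "))
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class; cannot train")
  factor(labels, levels = c("noncase", "case"))
}

#' Train a random forest on a term-document matrix
#'
#' Fits a classification forest of `nTrees` trees on the children x terms
#' weights, with all other hyperparameters at the `randomForest`
#' classification defaults. Per-child out-of-bag scores — the fraction of
#' trees for which the child was out-of-bag that voted "case" — come with
#' the fit and are the basis of honest training-set evaluation and of
#' permutation importance.
#'
#' @param tdm a [TermDocumentMatrix-class] (children are columns).
#' @param labels character/factor of `"case"`/`"noncase"` per child, in
#'   column order (or named by child id).
#' @param nTrees number of trees (>= 1).
#' @param seed integer seed; fixed seed gives identical forests and scores.
#' @param importance compute permutation importance during training
#'   (needed by [permutationImportance()]).
#' @return list with `forest` (the `randomForest` fit), `oobScores` (named
#'   numeric, OOB case-vote fraction per child) and `oobAccuracy`.
#' @export
trainForest <- function(tdm, labels, nTrees = 3000L, seed = 1L,
                        importance = FALSE) {
  stopifnot(is(tdm, "TermDocumentMatrix"), nTrees >= 1L)
  if (!is.null(names(labels))) labels <- labels[colnames(tdm)]
  if (length(labels) != ncol(tdm))
    stop("labels must align with the matrix children")
  y <- .checkLabels(labels)
  x <- asChildTermMatrix(tdm)
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = x, y = y, ntree = as.integer(nTrees),
                                   importance = importance,
                                   keep.forest = TRUE)
  oob <- rf$votes[, "case"]
  names(oob) <- rownames(x)
  list(forest = rf,
       oobScores = oob,
       oobAccuracy = 1 - rf$err.rate[rf$ntree, "OOB"][[1L]])
}

#' Permutation-based variable importance ranking
#'
#' Ranks terms by mean decrease in out-of-bag classification accuracy: for
#' each tree, accuracy on its out-of-bag children is compared before and
#' after randomly permuting one term's values, and the decreases are
#' averaged over the forest (unscaled). The fit must have been made with
#' `importance = TRUE` ([trainForest()]). Ties are broken lexicographically
#' so the ranking is a deterministic permutation of the vocabulary.
#'
#' @param fit result of [trainForest()] (or a bare `randomForest` object)
#'   trained with importance.
#' @return data.frame with columns `term`, `importance`, `rank`, sorted by
#'   decreasing importance.
#' @export
permutationImportance <- function(fit) {
  rf <- if (is.list(fit) && !is.null(fit$forest) &&
            inherits(fit$forest, "randomForest")) fit$forest else fit
  if (!inherits(rf, "randomForest")) stop("not a trained forest")
  if (is.null(rf$importance) ||
      !"MeanDecreaseAccuracy" %in% colnames(rf$importance))
    stop("forest was trained without importance = TRUE")
  imp <- randomForest::importance(rf, type = 1L, scale = FALSE)[, 1L]
  term <- names(imp)
  ord <- order(-imp, term, method = "radix")
  data.frame(term = term[ord], importance = unname(imp[ord]),
             rank = seq_along(imp), stringsAsFactors = FALSE)
}

#' Select a reduced term subset by nested out-of-bag search
#'
#' Starting from the importance ranking, refits forests on the nested
#' top-k subsets (k = `kStep`, 2 `kStep`, ..., `kCandidates`) and measures
#' each refit's out-of-bag accuracy. The smallest k whose accuracy is within
#' `tolerance` of the best observed wins: the reduced model keeps the
#' accuracy of the full candidate pool with as few terms as possible. The
#' whole k-versus-accuracy trace is returned for audit.
#'
#' @param ranking importance ranking from [permutationImportance()].
#' @param tdm,labels training matrix and labels as in [trainForest()].
#' @param config a [ForestConfig-class]; refits use `nTreesFinal` trees and
#'   per-k seeds derived from `seed`.
#' @return list with `terms` (selected character vector), `k`, and `trace`
#'   (data.frame `k`, `oob_accuracy`).
#' @export
selectFeatures <- function(ranking, tdm, labels, config = forestConfig()) {
  if (!nrow(ranking)) stop("empty importance ranking")
  if (config@kCandidates > nrow(ranking))
    stop("kCandidates exceeds the number of ranked terms")
  ks <- unique(c(seq.int(config@kStep, config@kCandidates, config@kStep),
                 config@kCandidates))
  acc <- vapply(ks, function(k) {
    sub <- tdm[ranking$term[seq_len(k)], , drop = FALSE]
    trainForest(sub, labels, nTrees = config@nTreesFinal,
                seed = .stageSeed(config@seed, paste0("select", k)))$oobAccuracy
  }, numeric(1))
  best <- max(acc)
  k <- ks[which(acc >= best - config@tolerance)[1L]]
  list(terms = ranking$term[seq_len(k)], k = k,
       trace = data.frame(k = ks, oob_accuracy = acc))
}

#' Fit the full surveillance text-classification pipeline
#'
#' Composes the whole training path on a labeled corpus: aggregate each
#' child's evaluations, tokenize and stem, build the 1-3-gram vocabulary
#' under the minimum document-frequency filter, weight by TF-IDF, grow the
#' large selection forest, rank terms by permutation importance, search the
#' nested top-k subsets for the reduced model, refit on the selected terms,
#' and calibrate the vote cutoff to the training class prevalence. The
#' training summary reports out-of-bag metrics of the final refit, the
#' honest (non-resubstitution) training estimate.
#'
#' @param corpus training [SurveillanceCorpus-class]; every child must be
#'   labeled `case` or `noncase`.
#' @param spec a [VocabularySpec-class].
#' @param config a [ForestConfig-class].
#' @return a [TrainedClassifier-class]
#' @seealso [predictScores()], [evaluateScores()]
#' @export
fitPipeline <- function(corpus, spec = vocabularySpec(),
                        config = forestConfig()) {
  stopifnot(is(corpus, "SurveillanceCorpus"))
  st <- childStatus(corpus)
  unk <- names(st)[!st %in% c("case", "noncase")]
  if (length(unk))
    stop("training corpus has children without case/noncase status: ",
         paste(utils::head(unk, 10L), collapse = ", "),
         if (length(unk) > 10L) ", ...")
  tdm <- buildTdm(corpus, spec, weighting = "tfidf")
  labels <- st[colnames(tdm)]
  selfit <- trainForest(tdm, labels, nTrees = config@nTreesSelection,
                        seed = .stageSeed(config@seed, "selection"),
                        importance = TRUE)
  ranking <- permutationImportance(selfit)
  kc <- min(config@kCandidates, nrow(ranking))
  cfg <- config
  cfg@kCandidates <- as.integer(kc)
  sel <- selectFeatures(ranking, tdm, labels, cfg)
  final <- trainForest(tdm[sel$terms, , drop = FALSE], labels,
                       nTrees = config@nTreesFinal,
                       seed = .stageSeed(config@seed, "final"))
  cutoff <- computeCutoff(sum(labels == "case"), length(labels))
  oobPred <- ifelse(final$oobScores >= cutoff, "case", "noncase")
  cc <- confusionCounts(oobPred, labels)
  summ <- performanceSummary(cc)
  summ$auc <- rocAuc(final$oobScores, labels)
  summ$oob_accuracy <- final$oobAccuracy
  new("TrainedClassifier",
      vocabularySpec = spec,
      vocabulary = tdmVocabulary(tdm),
      selectedTerms = sel$terms,
      forest = final$forest,
      cutoff = cutoff,
      importanceRanking = ranking,
      selectionTrace = sel$trace,
      trainingSummary = summ,
      forestConfig = config)
}

#' Score a corpus with a trained classifier
#'
#' Vectorizes the corpus through the frozen training pipeline — training
#' vocabulary, document frequencies and document count, restricted to the
#' selected terms — and returns each child's classification score (fraction
#' of trees voting "case") and predicted status (`case` iff score >=
#' cutoff). Clinician labels are not required. Children whose documents
#' contain no in-vocabulary term are still scored (on an all-zero feature
#' row) and flagged in the `oov` column.
#'
#' @param classifier a [TrainedClassifier-class].
#' @param corpus a [SurveillanceCorpus-class].
#' @return data.frame (`child_id`, `score`, `predicted`, `oov`), one row per
#'   child in corpus order.
#' @export
predictScores <- function(classifier, corpus) {
  stopifnot(is(classifier, "TrainedClassifier"),
            is(corpus, "SurveillanceCorpus"))
  tdm <- buildTdm(corpus, classifier@vocabularySpec,
                  vocabulary = classifier@vocabulary, weighting = "tfidf")
  x <- asChildTermMatrix(tdm[classifier@selectedTerms, , drop = FALSE])
  train_order <- rownames(classifier@forest$importance)
  x <- x[, train_order, drop = FALSE]
  oov <- Matrix::colSums(tdmWeights(tdm)) == 0
  if (any(oov))
    message(sum(oov), " child(ren) with no in-vocabulary terms scored on ",
            "empty features: ",
            paste(utils::head(colnames(tdm)[oov], 5L), collapse = ", "))
  votes <- stats::predict(classifier@forest, newdata = x, type = "vote",
                          norm.votes = TRUE)
  score <- votes[, "case"]
  data.frame(child_id = colnames(tdm), score = unname(score),
             predicted = ifelse(score >= classifier@cutoff, "case", "noncase"),
             oov = unname(oov), stringsAsFactors = FALSE)
}
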