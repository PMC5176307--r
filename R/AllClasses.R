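#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.STATUS_LEVELS <- c("case", "noncase", "unknown")
.SOURCE_LEVELS <- c("school", "health")

#' Surveillance corpus of children and their developmental evaluations
#'
#' A `SurveillanceCorpus` holds one surveillance year's worth of children,
#' each with at least one free-text developmental evaluation. Children carry
#' the clinician-assigned surveillance case status (`case`, `noncase`, or
#' `unknown` for prediction-only corpora) plus the demographic and
#' record-review metadata used in concordance profiling.
#'
#' @slot surveillanceYear integer(1) surveillance year the corpus covers.
#' @slot children data.frame with one row per child: `child_id`, `status`,
#'   `sex`, `race_eth`, `iq_le_70` (logical, may be `NA`), `prior_asd_dx`,
#'   `prior_asd_sped`, `secondary_review` (logical, may be `NA`).
#' @slot evaluations data.frame with one row per evaluation: `child_id`,
#'   `source` (`school` or `health`), `age_months`, `text`.
#'
#' @seealso [readCorpus()], [writeCorpus()], [aggregateChildText()],
#'   [generateCorpus()]
#' @export
setClass("SurveillanceCorpus",
  slots = c(
    surveillanceYear = "integer",
    children = "data.frame",
    evaluations = "data.frame"
  )
)

.CHILD_COLS <- c("child_id", "status", "sex", "race_eth", "iq_le_70",
                 "prior_asd_dx", "prior_asd_sped", "secondary_review")
.EVAL_COLS <- c("child_id", "source", "age_months", "text")

setValidity("SurveillanceCorpus", function(object) {
  ch <- object@children
  ev <- object@evaluations
  msgs <- character()
  if (length(object@surveillanceYear) != 1L || is.na(object@surveillanceYear))
    msgs <- c(msgs, "surveillanceYear must be a single non-NA integer")
  miss <- setdiff(.CHILD_COLS, names(ch))
  if (length(miss))
    return(paste("children is missing columns:", paste(miss, collapse = ", ")))
  miss <- setdiff(.EVAL_COLS, names(ev))
  if (length(miss))
    return(paste("evaluations is missing columns:", paste(miss, collapse = ", ")))
  dup <- ch$child_id[duplicated(ch$child_id)]
  if (length(dup))
    msgs <- c(msgs, paste0("duplicate child_id: ",
                           paste(unique(dup), collapse = ", ")))
  bad <- !ch$status %in% .STATUS_LEVELS
  if (any(bad))
    msgs <- c(msgs, paste0("invalid status value(s): ",
                           paste(unique(ch$status[bad]), collapse = ", ")))
  if (nrow(ev)) {
    orphan <- setdiff(ev$child_id, ch$child_id)
    if (length(orphan))
      msgs <- c(msgs, paste0("evaluations reference unknown child_id: ",
                             paste(orphan, collapse = ", ")))
    bad <- !ev$source %in% .SOURCE_LEVELS
    if (any(bad))
      msgs <- c(msgs, "evaluation source must be 'school' or 'health'")
    if (any(is.na(ev$age_months)) || any(ev$age_months < 0))
      msgs <- c(msgs, "age_months must be a non-negative integer")
    if (any(!nzchar(trimws(ev$text))))
      msgs <- c(msgs, "evaluation text must be non-empty")
  }
  noeval <- setdiff(ch$child_id, ev$child_id)
  if (length(noeval))
    msgs <- c(msgs, paste0("children without evaluations: ",
                           paste(noeval, collapse = ", ")))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a SurveillanceCorpus
#'
#' @param surveillanceYear integer(1) surveillance year.
#' @param children data.frame of child-level rows (see
#'   [SurveillanceCorpus-class]); missing metadata columns are filled with
#'   `NA`/`FALSE` defaults.
#' @param evaluations data.frame of evaluation-level rows.
#' @return A validated [SurveillanceCorpus-class] object.
#' @examples
#' ch <- data.frame(child_id = "c1", status = "case")
#' ev <- data.frame(child_id = "c1", source = "school",
#'                  age_months = 40L, text = "poor eye contact")
#' SurveillanceCorpus(2008L, ch, ev)
#' @export
SurveillanceCorpus <- function(surveillanceYear, children, evaluations) {
  children <- as.data.frame(children, stringsAsFactors = FALSE)
  evaluations <- as.data.frame(evaluations, stringsAsFactors = FALSE)
  fill <- function(df, name, default) {
    if (!name %in% names(df)) df[[name]] <- rep(default, nrow(df))
    df
  }
  children <- fill(children, "status", "unknown")
  children <- fill(children, "sex", NA_character_)
  children <- fill(children, "race_eth", NA_character_)
  children <- fill(children, "iq_le_70", NA)
  children <- fill(children, "prior_asd_dx", FALSE)
  children <- fill(children, "prior_asd_sped", FALSE)
  children <- fill(children, "secondary_review", NA)
  children$child_id <- as.character(children$child_id)
  children$iq_le_70 <- as.logical(children$iq_le_70)
  children$secondary_review <- as.logical(children$secondary_review)
  if (nrow(evaluations)) {
    evaluations$child_id <- as.character(evaluations$child_id)
    evaluations$age_months <- as.integer(evaluations$age_months)
    evaluations$text <- as.character(evaluations$text)
  }
  rownames(children) <- NULL
  rownames(evaluations) <- NULL
  new("SurveillanceCorpus",
      surveillanceYear = as.integer(surveillanceYear),
      children = children[, .CHILD_COLS, drop = FALSE],
      evaluations = evaluations[, .EVAL_COLS, drop = FALSE])
}

#' @describeIn SurveillanceCorpus-class number of children in the corpus
#' @param x,object a `SurveillanceCorpus`
#' @export
nChildren <- function(x) nrow(x@children)

#' @describeIn SurveillanceCorpus-class total number of evaluations
#' @export
nEvaluations <- function(x) nrow(x@evaluations)

#' @describeIn SurveillanceCorpus-class child identifiers
#' @export
childIds <- function(x) x@children$child_id

#' @describeIn SurveillanceCorpus-class named vector of clinician statuses
#' @export
childStatus <- function(x) {
  stats::setNames(x@children$status, x@children$child_id)
}

#' @describeIn SurveillanceCorpus-class child-level metadata data.frame
#' @export
childData <- function(x) x@children

#' @describeIn SurveillanceCorpus-class evaluation-level data.frame
#' @export
evaluationData <- function(x) x@evaluations

#' @describeIn SurveillanceCorpus-class surveillance year
#' @export
corpusYear <- function(x) x@surveillanceYear

setMethod("show", "SurveillanceCorpus", function(object) {
  st <- table(factor(object@children$status, levels = .STATUS_LEVELS))
  cat("SurveillanceCorpus (year ", object@surveillanceYear, ")\n",
      "  children:    ", nrow(object@children),
      " (", st[["case"]], " case / ", st[["noncase"]], " noncase / ",
      st[["unknown"]], " unknown)\n",
      "  evaluations: ", nrow(object@evaluations), "\n", sep = "")
})

#' Vocabulary of stemmed n-gram terms with document frequencies
#'
#' The vocabulary retained after the minimum document-frequency filter,
#' together with the per-term document frequency and the number of
#' child-level documents it was computed on. Frozen into a
#' [TrainedClassifier-class] so later surveillance years are vectorized with
#' training-time statistics.
#'
#' @slot terms character vector of stemmed n-grams, unique, lexicographically
#'   sorted.
#' @slot df integer vector, per-term count of documents containing the term.
#' @slot nDocuments integer(1), number of documents the frequencies refer to.
#' @export
setClass("Vocabulary",
  slots = c(terms = "character", df = "integer", nDocuments = "integer"))

setValidity("Vocabulary", function(object) {
  msgs <- character()
  if (length(object@terms) != length(object@df))
    msgs <- c(msgs, "terms and df must have equal length")
  if (anyDuplicated(object@terms))
    msgs <- c(msgs, "terms must be unique")
  if (!identical(object@terms, sort(object@terms, method = "radix")))
    msgs <- c(msgs, "terms must be sorted (C-locale order)")
  if (length(object@df) && any(object@df < 1L))
    msgs <- c(msgs, "document frequencies must be >= 1")
  if (length(object@df) && any(object@df > object@nDocuments))
    msgs <- c(msgs, "document frequency cannot exceed nDocuments")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn Vocabulary-class vocabulary terms
#' @param x,object a `Vocabulary`
#' @export
vocabTerms <- function(x) x@terms

#' @describeIn Vocabulary-class per-term document frequency (named)
#' @export
documentFrequency <- function(x) stats::setNames(x@df, x@terms)

#' @describeIn Vocabulary-class number of documents the vocabulary was built on
#' @export
vocabNDocuments <- function(x) x@nDocuments

setMethod("show", "Vocabulary", function(object) {
  cat("Vocabulary: ", length(object@terms), " stemmed n-gram terms over ",
      object@nDocuments, " documents\n", sep = "")
  if (length(object@terms)) {
    k <- min(6L, length(object@terms))
    cat("  e.g.", paste(utils::head(object@terms, k), collapse = ", "), "\n")
  }
})

#' Term-document matrix of child-level documents
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with terms as rows (features) and children as columns (samples). The
#' single assay `weights` holds either raw term counts or TF-IDF weights;
#' `rowData` carries the training document frequency of each term and
#' `metadata` the weighting scheme and document count.
#'
#' @seealso [buildCountMatrix()], [applyTfidf()], [buildTdm()]
#' @export
setClass("TermDocumentMatrix", contains = "SummarizedExperiment")

setValidity("TermDocumentMatrix", function(object) {
  msgs <- character()
  w <- metadata(object)$weighting
  if (is.null(w) || !w %in% c("count", "tfidf"))
    msgs <- c(msgs, "metadata()$weighting must be 'count' or 'tfidf'")
  if (!"weights" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'weights' is required")
  else if (min(SummarizedExperiment::assay(object, "weights")) < 0)
    msgs <- c(msgs, "weights must be non-negative")
  if (!"df" %in% names(rowData(object)))
    msgs <- c(msgs, "rowData()$df (document frequency) is required")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

.newTdm <- function(weights, vocabulary, childIds, weighting) {
  se <- SummarizedExperiment(
    assays = list(weights = weights),
    rowData = DataFrame(df = vocabulary@df, row.names = vocabulary@terms),
    colData = DataFrame(child_id = childIds, row.names = childIds),
    metadata = list(weighting = weighting,
                    nDocuments = vocabulary@nDocuments))
  new("TermDocumentMatrix", se)
}

#' @describeIn TermDocumentMatrix-class weighting scheme, `"count"` or
#'   `"tfidf"`
#' @param x,object a `TermDocumentMatrix`
#' @export
tdmWeighting <- function(x) metadata(x)$weighting

#' @describeIn TermDocumentMatrix-class the weights assay (terms x children,
#'   sparse)
#' @export
tdmWeights <- function(x) SummarizedExperiment::assay(x, "weights")

#' @describeIn TermDocumentMatrix-class reconstruct the [Vocabulary-class]
#'   the matrix was built with
#' @export
tdmVocabulary <- function(x) {
  new("Vocabulary", terms = rownames(x), df = as.integer(rowData(x)$df),
      nDocuments = as.integer(metadata(x)$nDocuments))
}

#' @describeIn TermDocumentMatrix-class dense children-by-terms matrix
#'   (the orientation classifiers expect)
#' @export
asChildTermMatrix <- function(x) {
  m <- t(as.matrix(SummarizedExperiment::assay(x, "weights")))
  rownames(m) <- colnames(x)
  m
}

setMethod("show", "TermDocumentMatrix", function(object) {
  cat("TermDocumentMatrix: ", nrow(object), " terms x ", ncol(object),
      " children (", metadata(object)$weighting, " weighting)\n", sep = "")
})

#' Trained surveillance text classifier
#'
#' The frozen artifact produced by [fitPipeline()]: vocabulary and IDF
#' statistics from the training year, the selected term subset, the fitted
#' random forest, and the vote-share cutoff calibrated to the training class
#' prevalence. Applying it to a new surveillance year ([predictScores()])
#' vectorizes the new documents with these frozen statistics.
#'
#' @slot vocabularySpec the [VocabularySpec-class] used at fit time.
#' @slot vocabulary frozen training [Vocabulary-class] (terms, df, N).
#' @slot selectedTerms character, terms retained by feature selection.
#' @slot forest fitted `randomForest` object (trained on selected terms).
#' @slot cutoff numeric(1) vote-share cutoff in (0,1); predicted case iff
#'   score >= cutoff.
#' @slot importanceRanking data.frame (`term`, `importance`, `rank`) from the
#'   selection forest.
#' @slot selectionTrace data.frame (`k`, `oob_accuracy`) from the nested
#'   subset search.
#' @slot trainingSummary list of out-of-bag performance metrics on the
#'   training year.
#' @slot forestConfig the [ForestConfig-class] used.
#' @export
setClass("TrainedClassifier",
  slots = c(
    vocabularySpec = "ANY",
    vocabulary = "Vocabulary",
    selectedTerms = "character",
    forest = "ANY",
    cutoff = "numeric",
    importanceRanking = "data.frame",
    selectionTrace = "data.frame",
    trainingSummary = "list",
    forestConfig = "ANY"
  )
)

setValidity("TrainedClassifier", function(object) {
  msgs <- character()
  if (length(object@cutoff) != 1L || object@cutoff <= 0 || object@cutoff >= 1)
    msgs <- c(msgs, "cutoff must be a single value in (0, 1)")
  extra <- setdiff(object@selectedTerms, object@vocabulary@terms)
  if (length(extra))
    msgs <- c(msgs, "selectedTerms must be a subset of the vocabulary")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn TrainedClassifier-class terms retained by feature selection
#' @param x,object a `TrainedClassifier`
#' @export
selectedTerms <- function(x) x@selectedTerms

#' @describeIn TrainedClassifier-class calibrated vote-share cutoff
#' @export
voteCutoff <- function(x) x@cutoff

#' @describeIn TrainedClassifier-class out-of-bag training performance list
#' @export
trainingSummary <- function(x) x@trainingSummary

setMethod("show", "TrainedClassifier", function(object) {
  cat("TrainedClassifier\n",
      "  vocabulary:     ", length(object@vocabulary@terms), " terms (training N = ",
      object@vocabulary@nDocuments, ")\n",
      "  selected terms: ", length(object@selectedTerms), "\n",
      "  forest:         ", object@forest$ntree, " trees\n",
      "  vote cutoff:    ", sprintf("%.3f", object@cutoff), "\n", sep = "")
  ts <- object@trainingSummary
  if (length(ts) && !is.null(ts$agreement))
    cat("  OOB agreement:  ", sprintf("%.1f%%", ts$agreement), "\n", sep = "")
})
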