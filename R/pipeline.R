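#' Save / load a trained classifier as a model artifact directory
#'
#' The artifact directory holds the frozen pipeline in inspectable form:
#' `vocabulary.tsv` (term, document frequency), `selected_terms.tsv`,
#' `importance.tsv`, `selection_trace.tsv`, `forest.rds` (the serialized
#' ensemble) and `manifest.json` (vocabulary spec, forest config, cutoff,
#' training summary, software versions).
#'
#' @param classifier a [TrainedClassifier-class].
#' @param dir artifact directory (created if needed).
#' @return `dir` (`saveClassifier`) or the re-assembled
#'   [TrainedClassifier-class] (`loadClassifier`).
#' @export
saveClassifier <- function(classifier, dir) {
  stopifnot(is(classifier, "TrainedClassifier"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  v <- classifier@vocabulary
  wt(data.frame(term = v@terms, df = v@df), "vocabulary.tsv")
  wt(data.frame(term = classifier@selectedTerms), "selected_terms.tsv")
  wt(classifier@importanceRanking, "importance.tsv")
  wt(classifier@selectionTrace, "selection_trace.tsv")
  saveRDS(classifier@forest, file.path(dir, "forest.rds"))
  sp <- classifier@vocabularySpec
  fc <- classifier@forestConfig
  manifest <- list(
    vocabulary_spec = list(ngram_min = sp@ngramMin, ngram_max = sp@ngramMax,
                           min_df_fraction = sp@minDfFraction,
                           stemmer = sp@stemmer),
    forest_config = list(n_trees_selection = fc@nTreesSelection,
                         n_trees_final = fc@nTreesFinal,
                         k_candidates = fc@kCandidates, k_step = fc@kStep,
                         tolerance = fc@tolerance, seed = fc@seed),
    cutoff = classifier@cutoff,
    n_training_documents = v@nDocuments,
    training_summary = classifier@trainingSummary[
      setdiff(names(classifier@trainingSummary), "raw")],
    versions = list(
      asdsurv = as.character(utils::packageVersion("asdsurv")),
      randomForest = as.character(utils::packageVersion("randomForest")),
      R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  voc <- utils::read.table(file.path(dir, "vocabulary.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  sel <- utils::read.table(file.path(dir, "selected_terms.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  imp <- utils::read.table(file.path(dir, "importance.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  tra <- utils::read.table(file.path(dir, "selection_trace.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  sp <- man$vocabulary_spec
  fc <- man$forest_config
  new("TrainedClassifier",
      vocabularySpec = vocabularySpec(sp$ngram_min, sp$ngram_max,
                                      sp$min_df_fraction, sp$stemmer),
      vocabulary = new("Vocabulary", terms = voc$term,
                       df = as.integer(voc$df),
                       nDocuments = as.integer(man$n_training_documents)),
      selectedTerms = sel$term,
      forest = readRDS(file.path(dir, "forest.rds")),
      cutoff = man$cutoff,
      importanceRanking = imp,
      selectionTrace = tra,
      trainingSummary = as.list(man$training_summary),
      forestConfig = forestConfig(fc$n_trees_selection, fc$n_trees_final,
                                  fc$k_candidates, fc$k_step, fc$tolerance,
                                  fc$seed))
}

.asCorpus <- function(x) {
  if (is(x, "SurveillanceCorpus")) x else readCorpus(x)
}

#' Run the full surveillance workflow end to end
#'
#' Fits the pipeline on the training corpus, scores and evaluates the test
#' corpus, and writes a report bundle to `outDir`: the model artifact
#' (`model/`), `scores.csv` (child id, score, predicted status),
#' `metrics.json`, `confusion.csv`, `sweep.csv`, `profile.csv`,
#' `histogram.csv` and a `manifest.json` recording the resolved
#' configuration. The output directory must be empty (or absent) unless
#' `force = TRUE`.
#'
#' @param train,test training and testing corpora: either
#'   [SurveillanceCorpus-class] objects or paths to JSON-lines files. Test
#'   children without clinician labels are scored but excluded from the
#'   evaluation tables.
#' @param outDir output directory for the report bundle.
#' @param spec a [VocabularySpec-class].
#' @param config a [ForestConfig-class].
#' @param sweepGrid cutoff grid for the threshold sweep.
#' @param force overwrite a non-empty `outDir`.
#' @return (invisibly) list with `classifier`, `scores`, `evaluation`.
#' @export
runEndToEnd <- function(train, test, outDir, spec = vocabularySpec(),
                        config = forestConfig(),
                        sweepGrid = seq(0, 1, by = 0.05), force = FALSE) {
  if (dir.exists(outDir) && length(dir(outDir)) && !force)
    stop("output directory ", outDir, " is not empty (use force = TRUE)")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  train <- .asCorpus(train)
  test <- .asCorpus(test)

  classifier <- fitPipeline(train, spec, config)
  saveClassifier(classifier, file.path(outDir, "model"))
  scores <- predictScores(classifier, test)
  utils::write.csv(scores, file.path(outDir, "scores.csv"),
                   row.names = FALSE)

  truth <- childStatus(test)
  labeled <- names(truth)[truth %in% c("case", "noncase")]
  out <- list(classifier = classifier, scores = scores, evaluation = NULL)
  if (length(labeled) && length(unique(truth[labeled])) == 2L) {
    sc <- scores[scores$child_id %in% labeled, , drop = FALSE]
    ev <- evaluateScores(sc, truth[labeled])
    out$evaluation <- ev
    cc <- ev$confusion
    utils::write.csv(data.frame(tp = cc[["tp"]], fp = cc[["fp"]],
                                fn = cc[["fn"]], tn = cc[["tn"]]),
                     file.path(outDir, "confusion.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(ev$summary[setdiff(names(ev$summary), "raw")],
        list(training = classifier@trainingSummary[
          setdiff(names(classifier@trainingSummary), "raw")])),
      file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    utils::write.csv(cutoffSweep(sc, truth[labeled], sweepGrid),
                     file.path(outDir, "sweep.csv"), row.names = FALSE)
    lab_corpus <- test[labeled]
    utils::write.csv(concordanceProfile(lab_corpus, sc),
                     file.path(outDir, "profile.csv"), row.names = FALSE)
    utils::write.csv(scoreHistogramData(sc, truth[labeled]),
                     file.path(outDir, "histogram.csv"), row.names = FALSE)
  }
  manifest <- list(
    surveillance_year_train = corpusYear(train),
    surveillance_year_test = corpusYear(test),
    n_train = nChildren(train), n_test = nChildren(test),
    vocabulary_size = length(classifier@vocabulary@terms),
    n_selected_terms = length(classifier@selectedTerms),
    cutoff = classifier@cutoff,
    seed = config@seed)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Subset a corpus to a set of children
#'
#' @param x a [SurveillanceCorpus-class]
#' @param i character vector of child ids (or logical/integer index on
#'   corpus order).
#' @return a [SurveillanceCorpus-class] with the selected children.
#' @export
setMethod("[", c("SurveillanceCorpus", "ANY", "ANY"),
  function(x, i, j, ..., drop = TRUE) {
    ids <- if (is.character(i)) i else x@children$child_id[i]
    ch <- x@children[match(ids, x@children$child_id), , drop = FALSE]
    ev <- x@evaluations[x@evaluations$child_id %in% ids, , drop = FALSE]
    SurveillanceCorpus(x@surveillanceYear, ch, ev)
  })
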