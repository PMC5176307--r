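#' Vocabulary-building specification
#'
#' Parameters controlling tokenization and vocabulary construction: the
#' n-gram order range, the minimum document-frequency fraction, and the
#' stemmer identifier. The defaults reproduce the standard surveillance
#' configuration: 1-3-grams kept when present in at least 3% of child-level
#' documents, with Porter stemming.
#'
#' @slot ngramMin integer(1), smallest n-gram order (default 1).
#' @slot ngramMax integer(1), largest n-gram order (default 3).
#' @slot minDfFraction numeric(1) in (0, 1], minimum fraction of documents a
#'   term must appear in (default 0.03).
#' @slot stemmer character(1), stemming algorithm id: `"porter"` or
#'   `"none"`.
#' @export
setClass("VocabularySpec",
  slots = c(ngramMin = "integer", ngramMax = "integer",
            minDfFraction = "numeric", stemmer = "character"))

setValidity("VocabularySpec", function(object) {
  msgs <- character()
  if (object@ngramMin < 1L || object@ngramMin > object@ngramMax)
    msgs <- c(msgs, "need 1 <= ngramMin <= ngramMax")
  if (object@minDfFraction <= 0 || object@minDfFraction > 1)
    msgs <- c(msgs, "minDfFraction must be in (0, 1]")
  if (!object@stemmer %in% c("porter", "none"))
    msgs <- c(msgs, "stemmer must be 'porter' or 'none'")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn VocabularySpec-class constructor
#' @param ngramMin,ngramMax n-gram order bounds.
#' @param minDfFraction minimum document-frequency fraction in (0, 1].
#' @param stemmer stemmer identifier, `"porter"` (default) or `"none"`.
#' @return a validated `VocabularySpec`
#' @examples
#' vocabularySpec()                      # 1-3-grams, 3% DF filter, Porter
#' vocabularySpec(ngramMax = 1)          # unigrams only
#' @export
vocabularySpec <- function(ngramMin = 1L, ngramMax = 3L,
                           minDfFraction = 0.03, stemmer = "porter") {
  new("VocabularySpec", ngramMin = as.integer(ngramMin),
      ngramMax = as.integer(ngramMax),
      minDfFraction = as.numeric(minDfFraction),
      stemmer = as.character(stemmer))
}

setMethod("show", "VocabularySpec", function(object) {
  cat("VocabularySpec: ", object@ngramMin, "-", object@ngramMax,
      "-grams, min df ", object@minDfFraction * 100, "%, stemmer = ",
      object@stemmer, "\n", sep = "")
})

#' Random-forest training configuration
#'
#' Tree counts for the two forest stages (a large forest for permutation-
#' importance feature selection and smaller forests for the reduced-feature
#' refits), the candidate pool size and search grid for nested feature
#' selection, and the master seed. All other forest hyperparameters follow
#' the classification defaults of the underlying `randomForest`
#' implementation.
#'
#' @slot nTreesSelection integer(1), trees in the feature-selection forest
#'   (default 10000).
#' @slot nTreesFinal integer(1), trees in reduced-feature refits and the
#'   final model (default 3000).
#' @slot kCandidates integer(1), size of the top-importance candidate pool
#'   (default 175).
#' @slot kStep integer(1), step of the nested subset grid k = kStep, 2*kStep,
#'   ..., kCandidates (default 5).
#' @slot tolerance numeric(1), absolute OOB-accuracy tolerance for choosing
#'   the smallest competitive subset (default 0.005).
#' @slot seed integer(1), master seed fanned out to each stochastic stage.
#' @export
setClass("ForestConfig",
  slots = c(nTreesSelection = "integer", nTreesFinal = "integer",
            kCandidates = "integer", kStep = "integer",
            tolerance = "numeric", seed = "integer"))

setValidity("ForestConfig", function(object) {
  msgs <- character()
  if (object@nTreesSelection < 1L || object@nTreesFinal < 1L)
    msgs <- c(msgs, "tree counts must be >= 1")
  if (object@kCandidates < 1L || object@kStep < 1L)
    msgs <- c(msgs, "kCandidates and kStep must be >= 1")
  if (object@tolerance < 0)
    msgs <- c(msgs, "tolerance must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn ForestConfig-class constructor
#' @param nTreesSelection,nTreesFinal forest sizes for the selection stage
#'   and the reduced-feature refits.
#' @param kCandidates,kStep,tolerance nested feature-selection search
#'   parameters.
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @return a validated `ForestConfig`
#' @examples
#' forestConfig(seed = 1)
#' forestConfig(nTreesSelection = 300, nTreesFinal = 300, seed = 7)
#' @export
forestConfig <- function(nTreesSelection = 10000L, nTreesFinal = 3000L,
                         kCandidates = 175L, kStep = 5L, tolerance = 0.005,
                         seed = 1L) {
  new("ForestConfig", nTreesSelection = as.integer(nTreesSelection),
      nTreesFinal = as.integer(nTreesFinal),
      kCandidates = as.integer(kCandidates), kStep = as.integer(kStep),
      tolerance = as.numeric(tolerance), seed = as.integer(seed))
}

setMethod("show", "ForestConfig", function(object) {
  cat("ForestConfig: ", object@nTreesSelection, " selection trees, ",
      object@nTreesFinal, " final trees, top-", object@kCandidates,
      " candidates (step ", object@kStep, ", tol ", object@tolerance,
      "), seed ", object@seed, "\n", sep = "")
})

# Derive a reproducible per-stage seed from the master seed. Stage names are
# fixed strings, so the fan-out is stable across sessions; results stay
# below 2^31.
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
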