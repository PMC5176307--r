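#' Normalize and tokenize free text
#'
#' Applies the bag-of-words preprocessing to one document: letters are
#' lower-cased, digits and punctuation are deleted (hyphens and apostrophes
#' included), the text is split on runs of non-letter characters, and each
#' token is stemmed. An empty document yields an empty token vector.
#'
#' @param text character(1) free text.
#' @param stemmer `"porter"` (default) or `"none"`.
#' @return character vector of normalized tokens.
#' @examples
#' normalizeTokens("Eye contact!!")            # "eye" "contact"
#' normalizeTokens("3 words: playing, played") # "word" "play" "play"
#' @export
normalizeTokens <- function(text, stemmer = "porter") {
  stopifnot(length(text) == 1L)
  .tokenizeDocs(text, stemmer)[[1L]]
}

# vectorized tokenizer; stems each unique surface token once
.tokenizeDocs <- function(texts, stemmer = "porter") {
  txt <- tolower(gsub("[^[:alpha:]]+", " ", as.character(texts)))
  toks <- strsplit(trimws(txt), " ", fixed = TRUE)
  toks <- lapply(toks, function(t) t[nzchar(t)])
  if (identical(stemmer, "none")) return(toks)
  if (!identical(stemmer, "porter")) stop("unknown stemmer: ", stemmer)
  flat <- unlist(toks, use.names = FALSE)
  if (!length(flat)) return(toks)
  stemmed <- porterStem(flat)
  utils::relist(stemmed, toks)
}

#' Extract contiguous n-grams from a token stream
#'
#' Emits every contiguous run of `ngramMin` to `ngramMax` tokens as a
#' space-joined term, in document order (all n-grams of order 1 first, then
#' order 2, and so on). N-grams never span document boundaries because each
#' call covers one document.
#'
#' @param tokens character vector of tokens (one document).
#' @param ngramMin,ngramMax n-gram order bounds, `1 <= ngramMin <= ngramMax`.
#' @return character vector of n-gram terms (a multiset: repeats preserved).
#' @examples
#' extractNgrams(c("a", "b", "c"), 1, 3)
#' @export
extractNgrams <- function(tokens, ngramMin = 1L, ngramMax = 3L) {
  stopifnot(ngramMin >= 1L, ngramMin <= ngramMax)
  n_tok <- length(tokens)
  out <- vector("list", ngramMax - ngramMin + 1L)
  for (n in seq.int(ngramMin, ngramMax)) {
    m <- n_tok - n + 1L
    if (m < 1L) next
    if (n == 1L) {
      out[[n - ngramMin + 1L]] <- tokens
    } else {
      parts <- lapply(seq_len(n) - 1L, function(k) tokens[(1L + k):(m + k)])
      out[[n - ngramMin + 1L]] <- do.call(paste, parts)
    }
  }
  unlist(out, use.names = FALSE) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimum document-frequency count
#'
#' The smallest number of documents a term must appear in to satisfy a
#' minimum document-frequency fraction: `ceiling(nDocuments * fraction)`
#' (guarded against floating-point noise on exact products). With 1162
#' documents and a 3% threshold this is 35.
#'
#' @param nDocuments number of documents (>= 1).
#' @param minDfFraction fraction in (0, 1].
#' @return integer count >= 1.
#' @examples
#' minDfCount(1162, 0.03)  # 35
#' @export
minDfCount <- function(nDocuments, minDfFraction) {
  stopifnot(nDocuments >= 1L, minDfFraction > 0, minDfFraction <= 1)
  max(1L, as.integer(ceiling(round(nDocuments * minDfFraction, 9L))))
}

#' Build the n-gram vocabulary of a document collection
#'
#' Collects every 1..n-gram of the tokenized documents and keeps exactly
#' those whose document frequency (number of distinct documents containing
#' the term at least once) reaches [minDfCount()]. Terms are stored sorted.
#'
#' @param documents list of token vectors (one per child-level document),
#'   e.g. from [aggregateChildText()] + [normalizeTokens()].
#' @param spec a [VocabularySpec-class].
#' @return a [Vocabulary-class]
#' @export
buildVocabulary <- function(documents, spec = vocabularySpec()) {
  stopifnot(is.list(documents), length(documents) >= 1L)
  validObject(spec)
  perdoc <- lapply(documents, function(t)
    unique(extractNgrams(t, spec@ngramMin, spec@ngramMax)))
  all_terms <- unlist(perdoc, use.names = FALSE)
  if (!length(all_terms))
    return(new("Vocabulary", terms = character(0), df = integer(0),
               nDocuments = length(documents)))
  f <- factor(all_terms)
  df <- tabulate(f, nbins = nlevels(f))
  keep <- df >= minDfCount(length(documents), spec@minDfFraction)
  terms <- levels(f)[keep]
  ord <- order(terms, method = "radix")
  new("Vocabulary", terms = terms[ord], df = as.integer(df[keep][ord]),
      nDocuments = length(documents))
}

#' Build the term count matrix for a document collection
#'
#' Counts occurrences of each vocabulary term in each document; terms
#' outside the vocabulary are ignored. The vocabulary may come from a
#' different (training) corpus, which is how later surveillance years are
#' vectorized with frozen training statistics.
#'
#' @param documents list of token vectors, named by child id.
#' @param vocabulary a [Vocabulary-class] (non-empty).
#' @param spec the [VocabularySpec-class] defining the n-gram range.
#' @return a [TermDocumentMatrix-class] with `count` weighting (sparse,
#'   terms x children).
#' @export
buildCountMatrix <- function(documents, vocabulary, spec = vocabularySpec()) {
  stopifnot(is.list(documents), length(documents) >= 1L)
  if (!length(vocabulary@terms)) stop("vocabulary is empty")
  ids <- names(documents) %||% as.character(seq_along(documents))
  trip <- lapply(seq_along(documents), function(j) {
    ng <- extractNgrams(documents[[j]], spec@ngramMin, spec@ngramMax)
    idx <- match(ng, vocabulary@terms)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(NULL)
    tab <- table(idx)
    cbind(i = as.integer(names(tab)), j = j, x = as.integer(tab))
  })
  trip <- do.call(rbind, trip)
  if (is.null(trip)) trip <- matrix(numeric(0), ncol = 3L,
                                    dimnames = list(NULL, c("i", "j", "x")))
  w <- Matrix::sparseMatrix(
    i = trip[, "i"], j = trip[, "j"], x = as.numeric(trip[, "x"]),
    dims = c(length(vocabulary@terms), length(documents)),
    dimnames = list(vocabulary@terms, ids))
  .newTdm(w, vocabulary, ids, "count")
}

#' Apply TF-IDF weighting to a count matrix
#'
#' Converts term counts to term-frequency-inverse-document-frequency
#' weights, the weighting that considers both how often a term occurs in a
#' child's records and how many children have the term at all:
#' `weight(term, child) = (count / total counts for that child) *
#' log2(N / df(term))`. `N` and the document frequencies come from
#' `dfSource` — the frozen training vocabulary when transforming a new
#' surveillance year. Children with no in-vocabulary terms get all-zero
#' columns.
#'
#' @param counts a [TermDocumentMatrix-class] with `count` weighting.
#' @param dfSource [Vocabulary-class] supplying `N` and document
#'   frequencies; defaults to the vocabulary stored in `counts`.
#' @return a [TermDocumentMatrix-class] with `tfidf` weighting.
#' @export
applyTfidf <- function(counts, dfSource = tdmVocabulary(counts)) {
  stopifnot(is(counts, "TermDocumentMatrix"))
  if (!identical(tdmWeighting(counts), "count"))
    stop("applyTfidf expects a count-weighted matrix")
  if (!identical(rownames(counts), dfSource@terms))
    stop("dfSource vocabulary does not match matrix terms")
  if (length(dfSource@df) && any(dfSource@df < 1L))
    stop("document frequency of 0 in dfSource")
  w <- tdmWeights(counts)
  tot <- Matrix::colSums(w)
  inv <- ifelse(tot > 0, 1 / tot, 0)
  idf <- log2(dfSource@nDocuments / dfSource@df)
  out <- Matrix::Diagonal(x = idf) %*% w %*% Matrix::Diagonal(x = inv)
  out <- methods::as(out, "CsparseMatrix")
  dimnames(out) <- dimnames(w)
  .newTdm(Matrix::drop0(out), dfSource, colnames(w), "tfidf")
}

#' Aggregate, tokenize and vectorize a corpus in one step
#'
#' Convenience wrapper running [aggregateChildText()], tokenization,
#' vocabulary construction (unless a frozen `vocabulary` is supplied),
#' [buildCountMatrix()] and optionally [applyTfidf()].
#'
#' @param corpus a [SurveillanceCorpus-class].
#' @param spec a [VocabularySpec-class].
#' @param vocabulary optional frozen training [Vocabulary-class]; when given,
#'   both the column space and the IDF statistics come from it.
#' @param weighting `"tfidf"` (default) or `"count"`.
#' @return a [TermDocumentMatrix-class]
#' @export
buildTdm <- function(corpus, spec = vocabularySpec(), vocabulary = NULL,
                     weighting = c("tfidf", "count")) {
  weighting <- match.arg(weighting)
  docs <- .tokenizeDocs(aggregateChildText(corpus), spec@stemmer)
  names(docs) <- corpus@children$child_id
  if (is.null(vocabulary)) vocabulary <- buildVocabulary(docs, spec)
  counts <- buildCountMatrix(docs, vocabulary, spec)
  if (weighting == "count") counts else applyTfidf(counts, vocabulary)
}

#' Serialize a term-document matrix as MatrixMarket plus label sidecars
#'
#' Writes `<stem>.mtx` (sparse MatrixMarket), `<stem>.terms.tsv` (term,
#' document frequency) and `<stem>.children.tsv` (child ids), a plain-text
#' representation loadable by any sparse-matrix tool.
#'
#' @param tdm a [TermDocumentMatrix-class].
#' @param stem output path stem (directory must exist).
#' @return the three file paths, invisibly.
#' @export
writeTdm <- function(tdm, stem) {
  stopifnot(is(tdm, "TermDocumentMatrix"))
  paths <- paste0(stem, c(".mtx", ".terms.tsv", ".children.tsv"))
  Matrix::writeMM(methods::as(tdmWeights(tdm), "generalMatrix"), paths[1L])
  utils::write.table(
    data.frame(term = rownames(tdm), df = rowData(tdm)$df),
    paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(child_id = colnames(tdm)), paths[3L],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
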