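# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (nested loops, no shared code with the package
# internals) so they can arbitrate the vectorized implementations.

# every contiguous n-gram of a token vector, by explicit index loops
oracleNgrams <- function(tokens, nmin, nmax) {
  out <- character(0)
  for (n in nmin:nmax) {
    if (length(tokens) < n) next
    for (i in seq_len(length(tokens) - n + 1L)) {
      out <- c(out, paste(tokens[i:(i + n - 1L)], collapse = " "))
    }
  }
  out
}

# vocabulary as a set comprehension over all n-grams with df >= threshold
oracleVocabulary <- function(docs, nmin, nmax, minDfFrac) {
  allterms <- sort(unique(unlist(lapply(docs, oracleNgrams, nmin, nmax))))
  df <- sapply(allterms, function(tm)
    sum(sapply(docs, function(d) tm %in% oracleNgrams(d, nmin, nmax))))
  thr <- ceiling(round(length(docs) * minDfFrac, 9))
  keep <- df >= max(1, thr)
  list(terms = allterms[keep], df = unname(df[keep]))
}

# counts by nested loops: docs x terms
oracleCounts <- function(docs, terms, nmin, nmax) {
  m <- matrix(0, length(terms), length(docs),
              dimnames = list(terms, names(docs)))
  for (j in seq_along(docs)) {
    ng <- oracleNgrams(docs[[j]], nmin, nmax)
    for (i in seq_along(terms)) m[i, j] <- sum(ng == terms[i])
  }
  m
}

# tf-idf straight from the stated formula
oracleTfidf <- function(counts, df, n_docs) {
  w <- counts
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[, j])
    for (i in seq_len(nrow(counts))) {
      w[i, j] <- if (tot > 0)
        counts[i, j] / tot * log2(n_docs / df[i]) else 0
    }
  }
  w
}

# AUC by exhaustive all-pairs comparison, ties at half credit
oracleAuc <- function(scores, truth) {
  cs <- scores[truth == "case"]
  ns <- scores[truth == "noncase"]
  tot <- 0
  for (a in cs) for (b in ns)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ns))
}

# tiny handmade corpus used across io/textprep tests
toyCorpus <- function() {
  ch <- data.frame(
    child_id = c("c1", "c2", "c3"),
    status = c("case", "noncase", "case"),
    sex = c("male", "female", "male"),
    race_eth = c("white_nh", "black_nh", "hispanic"),
    iq_le_70 = c(TRUE, FALSE, NA),
    prior_asd_dx = c(TRUE, FALSE, FALSE),
    prior_asd_sped = c(TRUE, FALSE, TRUE),
    secondary_review = c(FALSE, TRUE, NA),
    stringsAsFactors = FALSE)
  ev <- data.frame(
    child_id = c("c1", "c1", "c2", "c3"),
    source = c("school", "health", "school", "health"),
    age_months = c(53L, 40L, 48L, 36L),
    text = c("Poor eye contact observed.", "Autism suspected; playing alone.",
             "Typical development, plays well.", "Hand flapping noted. Autism."),
    stringsAsFactors = FALSE)
  SurveillanceCorpus(2008L, ch, ev)
}

# corpus with one perfectly separating planted token among noise
separableCorpus <- function(n = 80, seed = 99) {
  set.seed(seed)
  status <- rep(c("case", "noncase"), length.out = n)
  filler <- c("motor", "speech", "therapi", "teacher", "report", "delai",
              "grade", "class", "home", "parent")
  texts <- vapply(seq_len(n), function(i) {
    toks <- sample(filler, 25, replace = TRUE)
    if (status[i] == "case") toks <- c(toks, rep("markerterm", 3))
    paste(toks, collapse = " ")
  }, character(1))
  ch <- data.frame(child_id = sprintf("k%03d", seq_len(n)), status = status,
                   stringsAsFactors = FALSE)
  ev <- data.frame(child_id = ch$child_id, source = "school",
                   age_months = 48L, text = texts, stringsAsFactors = FALSE)
  SurveillanceCorpus(2008L, ch, ev)
}
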