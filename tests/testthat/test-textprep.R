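# frozen word/stem pairs from the worked examples published with the Porter
# algorithm (end-to-end outputs), plus the revised short-word behavior
.porter_pairs <- c(
  caresses = "caress", ponies = "poni", ties = "ti", caress = "caress",
  cats = "cat", feed = "feed", agreed = "agre", plastered = "plaster",
  bled = "bled", motoring = "motor", sing = "sing", conflated = "conflat",
  troubled = "troubl", sized = "size", hopping = "hop", tanned = "tan",
  falling = "fall", hissing = "hiss", fizzed = "fizz", failing = "fail",
  filing = "file", happy = "happi", sky = "sky", relational = "relat",
  conditional = "condit", rational = "ration", valenci = "valenc",
  hesitanci = "hesit", digitizer = "digit", radicalli = "radic",
  differentli = "differ", vileli = "vile", analogousli = "analog",
  vietnamization = "vietnam", predication = "predic", operator = "oper",
  feudalism = "feudal", decisiveness = "decis", hopefulness = "hope",
  callousness = "callous", formaliti = "formal", sensitiviti = "sensit",
  sensibiliti = "sensibl", triplicate = "triplic", formative = "form",
  formalize = "formal", electriciti = "electr", electrical = "electr",
  hopeful = "hope", goodness = "good", revival = "reviv",
  allowance = "allow", inference = "infer", airliner = "airlin",
  gyroscopic = "gyroscop", adjustable = "adjust", defensible = "defens",
  irritant = "irrit", replacement = "replac", adjustment = "adjust",
  dependent = "depend", adoption = "adopt", communism = "commun",
  activate = "activ", angulariti = "angular", homologous = "homolog",
  effective = "effect", bowdlerize = "bowdler", probate = "probat",
  rate = "rate", cease = "ceas", controlling = "control", rolling = "roll",
  playing = "play", played = "play", plays = "play", words = "word",
  autism = "autism", contact = "contact", eye = "eye",
  interaction = "interact", repetitive = "repetit", behaviors = "behavior",
  stereotyped = "stereotyp", evaluations = "evalu")

test_that("Porter stemmer reproduces the published example stems", {
  expect_identical(porterStem(names(.porter_pairs)),
                   unname(.porter_pairs))
})

test_that("stemming is idempotent on short and already-stemmed words", {
  expect_identical(porterStem(c("a", "at", "is")), c("a", "at", "is"))
  stems <- unique(unname(.porter_pairs))
  restemmed <- porterStem(stems)
  # the large majority of stems are fixed points; none may grow
  expect_gt(mean(restemmed == stems), 0.9)
  expect_true(all(nchar(restemmed) <= nchar(stems)))
})

test_that("normalization lower-cases, strips digits/punctuation, stems", {
  expect_identical(normalizeTokens("Eye contact!!"), c("eye", "contact"))
  expect_identical(normalizeTokens("3 words: playing, played"),
                   c("word", "play", "play"))
  expect_identical(normalizeTokens(""), character(0))
  expect_identical(normalizeTokens("42 -- 17 ..."), character(0))
  # hyphens and apostrophes split tokens
  expect_identical(normalizeTokens("self-help don't", stemmer = "none"),
                   c("self", "help", "don", "t"))
  expect_false(any(grepl("[^a-z ]", normalizeTokens("Mixed CASE 9 text?"))))
})

test_that("n-gram extraction enumerates all contiguous runs", {
  expect_setequal(extractNgrams(c("a", "b", "c"), 1, 3),
                  c("a", "b", "c", "a b", "b c", "a b c"))
  expect_identical(extractNgrams("a", 1, 3), "a")
  expect_identical(extractNgrams(character(0), 1, 3), character(0))
  set.seed(7)
  toks <- sample(letters, 12, replace = TRUE)
  ng <- extractNgrams(toks, 1, 3)
  expect_length(ng, 12 + 11 + 10)
  expect_setequal(ng, oracleNgrams(toks, 1, 3))
})

test_that("minimum document-frequency count follows the ceiling rule", {
  expect_identical(minDfCount(1162, 0.03), 35L)
  expect_identical(minDfCount(100, 0.03), 3L)
  expect_identical(minDfCount(33, 0.03), 1L)
  expect_identical(minDfCount(1, 1), 1L)
  expect_error(minDfCount(0, 0.03))
})

test_that("vocabulary keeps exactly the terms at or above the threshold", {
  # df boundary: a term in 34 of 1162 docs is excluded, in 35 included
  n <- 1162
  docs <- lapply(seq_len(n), function(i) {
    d <- c("alpha", "beta")
    if (i <= 34) d <- c(d, "borderline")
    if (i <= 35) d <- c(d, "keeper")
    d
  })
  v <- buildVocabulary(docs, vocabularySpec(minDfFraction = 0.03))
  expect_false("borderline" %in% vocabTerms(v))
  expect_true("keeper" %in% vocabTerms(v))
  expect_equal(unname(documentFrequency(v)["keeper"]), 35L)
})

test_that("three identical documents keep every n-gram of the document", {
  doc <- c("autism", "ey", "contact")
  docs <- list(doc, doc, doc)
  v <- buildVocabulary(docs, vocabularySpec(minDfFraction = 0.03))
  expect_setequal(vocabTerms(v), oracleNgrams(doc, 1, 3))
  expect_true(all(documentFrequency(v) == 3L))
})

test_that("vocabulary, counts and tf-idf match brute-force oracles", {
  set.seed(31)
  vocab_pool <- c("autism", "ey", "contact", "social", "plai", "delai",
                  "speech", "motor")
  for (rep in 1:3) {
    nd <- sample(4:10, 1)
    docs <- lapply(seq_len(nd), function(i)
      sample(vocab_pool, sample(5:30, 1), replace = TRUE))
    names(docs) <- paste0("d", seq_len(nd))
    spec <- vocabularySpec(minDfFraction = 0.3)
    orc <- oracleVocabulary(docs, 1, 3, 0.3)
    v <- buildVocabulary(docs, spec)
    expect_identical(vocabTerms(v), orc$terms)
    expect_identical(unname(documentFrequency(v)), as.integer(orc$df))

    counts <- buildCountMatrix(docs, v, spec)
    expect_equal(as.matrix(tdmWeights(counts)),
                 oracleCounts(docs, vocabTerms(v), 1, 3))

    w <- applyTfidf(counts)
    expect_equal(as.matrix(tdmWeights(w)),
                 oracleTfidf(oracleCounts(docs, vocabTerms(v), 1, 3),
                             orc$df, nd))
  }
})

test_that("tf-idf implements relative frequency times log2(N/df)", {
  # 2 documents, term count 2 in a 4-token row, df = 1 -> 0.5
  docs <- list(d1 = c("rare", "rare", "x", "x"), d2 = c("x", "x"))
  v <- buildVocabulary(docs, vocabularySpec(ngramMax = 1,
                                            minDfFraction = 0.5))
  w <- applyTfidf(buildCountMatrix(docs, v, vocabularySpec(ngramMax = 1)))
  expect_equal(tdmWeights(w)["rare", "d1"], (2 / 4) * log2(2 / 1))
  # ubiquitous term annihilates: df = N -> zero column
  expect_true(all(tdmWeights(w)["x", ] == 0))
})

test_that("zero-count rows stay zero under tf-idf and oov docs are zero", {
  docs <- list(d1 = c("alpha", "beta"), d2 = c("alpha", "beta"),
               d3 = c("gamma"))
  spec <- vocabularySpec(ngramMax = 1, minDfFraction = 0.6)
  v <- buildVocabulary(docs, spec)   # only alpha, beta survive df >= 2
  counts <- buildCountMatrix(docs, v, spec)
  expect_equal(sum(tdmWeights(counts)[, "d3"]), 0)
  w <- applyTfidf(counts)
  expect_equal(sum(tdmWeights(w)[, "d3"]), 0)
  expect_identical(tdmWeights(w) == 0, tdmWeights(counts) == 0)
})

test_that("raising the df threshold never adds vocabulary terms", {
  set.seed(17)
  docs <- lapply(1:20, function(i)
    sample(letters[1:12], sample(3:15, 1), replace = TRUE))
  fracs <- c(0.05, 0.15, 0.3, 0.6, 1)
  vocabs <- lapply(fracs, function(f)
    vocabTerms(buildVocabulary(docs, vocabularySpec(minDfFraction = f))))
  for (i in seq_len(length(fracs) - 1)) {
    expect_true(all(vocabs[[i + 1]] %in% vocabs[[i]]))
  }
})

test_that("frozen-vocabulary transform equals fit-and-transform", {
  corp <- separableCorpus(30)
  spec <- vocabularySpec()
  fitted <- buildTdm(corp, spec)
  frozen <- buildTdm(corp, spec, vocabulary = tdmVocabulary(fitted))
  expect_identical(as.matrix(tdmWeights(fitted)),
                   as.matrix(tdmWeights(frozen)))
})

test_that("term-document matrices serialize to MatrixMarket with sidecars", {
  corp <- toyCorpus()
  tdm <- buildTdm(corp, vocabularySpec(minDfFraction = 0.3))
  d <- withr::local_tempdir()
  paths <- writeTdm(tdm, file.path(d, "tdm"))
  m <- Matrix::readMM(file.path(d, "tdm.mtx"))
  expect_equal(dim(m), dim(tdm))
  labels <- read.delim(file.path(d, "tdm.terms.tsv"))
  expect_identical(labels$term, rownames(tdm))
})
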