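test_that("vote cutoff equals the non-case class fraction", {
  expect_equal(round(computeCutoff(601, 1162), 3), 0.483)
  expect_equal(computeCutoff(50, 100), 0.5)
  expect_equal(computeCutoff(1, 4), 0.75)
  expect_error(computeCutoff(0, 10), "both classes")
  expect_error(computeCutoff(10, 10), "both classes")
})

test_that("forest training separates a strongly planted corpus", {
  corp <- separableCorpus(80)
  tdm <- buildTdm(corp, vocabularySpec(minDfFraction = 0.1))
  fit <- trainForest(tdm, childStatus(corp), nTrees = 150, seed = 3)
  expect_gt(fit$oobAccuracy, 0.95)
  expect_true(all(fit$oobScores >= 0 & fit$oobScores <= 1))
})

test_that("same seed reproduces identical forests and scores", {
  corp <- separableCorpus(40)
  tdm <- buildTdm(corp, vocabularySpec(minDfFraction = 0.1))
  f1 <- trainForest(tdm, childStatus(corp), nTrees = 80, seed = 11)
  f2 <- trainForest(tdm, childStatus(corp), nTrees = 80, seed = 11)
  expect_identical(f1$oobScores, f2$oobScores)
})

test_that("permuted labels give chance-level out-of-bag accuracy", {
  corp <- separableCorpus(80)
  tdm <- buildTdm(corp, vocabularySpec(minDfFraction = 0.1))
  set.seed(5)
  shuffled <- sample(childStatus(corp))
  names(shuffled) <- childIds(corp)
  fit <- trainForest(tdm, shuffled, nTrees = 150, seed = 5)
  maj <- max(table(shuffled)) / length(shuffled)
  # within binomial noise of the majority-class rate
  expect_lt(abs(fit$oobAccuracy - maj), 3 * sqrt(maj * (1 - maj) / 80) + 0.05)
})

test_that("single-class labels and misaligned labels are rejected", {
  corp <- separableCorpus(20)
  tdm <- buildTdm(corp, vocabularySpec(minDfFraction = 0.1))
  expect_error(trainForest(tdm, rep("case", 20)), "single class")
  expect_error(trainForest(tdm, c("case", "noncase")), "align")
})

test_that("permutation importance ranks the separating term first", {
  corp <- separableCorpus(80)
  tdm <- buildTdm(corp, vocabularySpec(minDfFraction = 0.1))
  fit <- trainForest(tdm, childStatus(corp), nTrees = 200, seed = 2,
                     importance = TRUE)
  rk <- permutationImportance(fit)
  expect_identical(rk$term[1], "markerterm")
  expect_identical(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$importance) <= 0))
  # a fit without importance cannot be ranked
  plain <- trainForest(tdm, childStatus(corp), nTrees = 30, seed = 2)
  expect_error(permutationImportance(plain), "importance")
})

test_that("constant columns carry (near) zero importance", {
  corp <- separableCorpus(60)
  tdm <- buildTdm(corp, vocabularySpec(minDfFraction = 0.1))
  # every document contains every filler with similar frequency; the df=N
  # terms have zero tf-idf variance across classes only for markerterm's
  # absence -- use an explicitly constant column instead
  w <- tdmWeights(tdm)
  w["report", ] <- 1
  tdm2 <- asdsurv:::.newTdm(w, tdmVocabulary(tdm), colnames(tdm), "tfidf")
  fit <- trainForest(tdm2, childStatus(corp), nTrees = 200, seed = 8,
                     importance = TRUE)
  rk <- permutationImportance(fit)
  expect_lt(abs(rk$importance[rk$term == "report"]), 1e-12)
})

test_that("nested subset search recovers a small competitive model", {
  corp <- separableCorpus(80)
  tdm <- buildTdm(corp, vocabularySpec(minDfFraction = 0.1))
  labels <- childStatus(corp)
  fit <- trainForest(tdm, labels, nTrees = 150, seed = 4, importance = TRUE)
  rk <- permutationImportance(fit)
  cfg <- forestConfig(nTreesFinal = 100, kCandidates = 20, kStep = 5,
                      seed = 4)
  sel <- selectFeatures(rk, tdm, labels, cfg)
  expect_true("markerterm" %in% sel$terms)
  expect_equal(sel$k, length(sel$terms))
  expect_equal(sel$trace$k, c(5, 10, 15, 20))
  # with tolerance 0 the argmax subset is returned
  cfg0 <- forestConfig(nTreesFinal = 100, kCandidates = 20, kStep = 5,
                       tolerance = 0, seed = 4)
  sel0 <- selectFeatures(rk, tdm, labels, cfg0)
  best <- max(sel0$trace$oob_accuracy)
  expect_equal(sel0$trace$oob_accuracy[sel0$trace$k == sel0$k], best)
  expect_error(selectFeatures(rk[0, ], tdm, labels, cfg), "empty")
})

test_that("the fitted pipeline freezes a reproducible artifact", {
  gen <- generateCorpus(synthConfig(nChildren = 120, nNoise = 200,
                                    seed = 21))
  cfg <- forestConfig(nTreesSelection = 150, nTreesFinal = 100,
                      kCandidates = 40, kStep = 20, seed = 9)
  cl1 <- fitPipeline(gen$corpus, vocabularySpec(), cfg)
  cl2 <- fitPipeline(gen$corpus, vocabularySpec(), cfg)
  expect_identical(selectedTerms(cl1), selectedTerms(cl2))
  expect_equal(voteCutoff(cl1),
               computeCutoff(sum(childStatus(gen$corpus) == "case"),
                             nChildren(gen$corpus)))
  s1 <- predictScores(cl1, gen$corpus)
  s2 <- predictScores(cl1, gen$corpus)
  expect_identical(s1, s2)
  expect_true(all(s1$score >= 0 & s1$score <= 1))
  expect_identical(s1$predicted, ifelse(s1$score >= voteCutoff(cl1),
                                        "case", "noncase"))
})

test_that("children with unknown status cannot enter training", {
  corp <- separableCorpus(20)
  corp@children$status[3] <- "unknown"
  expect_error(fitPipeline(corp, config = forestConfig(
    nTreesSelection = 30, nTreesFinal = 30, kCandidates = 5, kStep = 5)),
    "k003")
})

test_that("out-of-vocabulary children are scored, not dropped", {
  corp <- separableCorpus(60)
  cfg <- forestConfig(nTreesSelection = 100, nTreesFinal = 80,
                      kCandidates = 10, kStep = 5, seed = 2)
  cl <- fitPipeline(corp, vocabularySpec(minDfFraction = 0.1), cfg)
  new_ch <- data.frame(child_id = "oov1", status = "unknown")
  new_ev <- data.frame(child_id = "oov1", source = "school",
                       age_months = 50L,
                       text = "zzyx qwfp vvkk")  # nothing in vocabulary
  newcorp <- SurveillanceCorpus(2010L, new_ch, new_ev)
  expect_message(sc <- predictScores(cl, newcorp), "no in-vocabulary")
  expect_equal(nrow(sc), 1L)
  expect_true(sc$oov)
  expect_true(sc$score >= 0 && sc$score <= 1)
})

test_that("scoring the training corpus agrees with the OOB majority", {
  corp <- separableCorpus(60)
  cfg <- forestConfig(nTreesSelection = 120, nTreesFinal = 100,
                      kCandidates = 10, kStep = 5, seed = 13)
  cl <- fitPipeline(corp, vocabularySpec(minDfFraction = 0.1), cfg)
  sc <- predictScores(cl, corp)
  truth <- childStatus(corp)
  insample <- mean(sc$predicted == truth[sc$child_id])
  oob_agree <- cl@trainingSummary$raw$agreement
  expect_gte(insample, oob_agree)
})
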