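test_that("confusion counts cross-tabulate prediction against truth", {
  pred <- c(rep("case", 10), rep("noncase", 10))
  truth <- c(rep("case", 10), rep("noncase", 10))
  cc <- confusionCounts(pred, truth)
  expect_equal(unclass(cc), c(tp = 10L, fp = 0L, fn = 0L, tn = 10L))
  flipped <- confusionCounts(ifelse(truth == "case", "noncase", "case"),
                             truth)
  expect_equal(flipped[["tp"]] + flipped[["tn"]], 0L)
  # brute-force check on random vectors
  set.seed(23)
  for (r in 1:3) {
    p <- sample(c("case", "noncase"), 50, TRUE)
    t <- sample(c("case", "noncase"), 50, TRUE)
    cc <- confusionCounts(p, t)
    manual <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
    for (i in 1:50) {
      cellname <- if (p[i] == "case" && t[i] == "case") "tp"
      else if (p[i] == "case") "fp"
      else if (t[i] == "case") "fn" else "tn"
      manual[cellname] <- manual[cellname] + 1L
    }
    expect_equal(unclass(cc), manual)
  }
})

test_that("named prediction/truth vectors are matched by child id", {
  pred <- c(a = "case", b = "noncase")
  truth <- c(b = "noncase", a = "case")
  cc <- confusionCounts(pred, truth)
  expect_equal(cc[["tp"]], 1L)
  expect_equal(cc[["tn"]], 1L)
  expect_error(confusionCounts(pred, c(a = "case", z = "noncase")),
               "different child ids")
})

test_that("performance summary reproduces the surveillance-year table", {
  s <- performanceSummary(ConfusionCounts(633, 75, 121, 621))
  expect_identical(s$agreement, 86.5)
  expect_identical(s$sensitivity, 84.0)
  expect_identical(s$specificity, 89.2)
  expect_identical(s$ppv, 89.4)
  expect_identical(s$npv, 83.7)
  expect_identical(s$kappa, 0.73)
  expect_identical(s$n, 1450L)
})

test_that("degenerate confusion tables handled exactly", {
  perfect <- performanceSummary(ConfusionCounts(7, 0, 0, 13))
  expect_equal(perfect$agreement, 100)
  expect_equal(perfect$kappa, 1)
  # p_o == p_e -> kappa 0 (independent marginals)
  chance <- performanceSummary(ConfusionCounts(25, 25, 25, 25))
  expect_equal(chance$kappa, 0)
  # empty denominator -> NA, not fabricated
  nocase <- performanceSummary(ConfusionCounts(0, 0, 0, 10))
  expect_true(is.na(nocase$sensitivity))
  expect_true(is.na(nocase$ppv))
  expect_equal(nocase$agreement, 100)
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(3)
  for (r in 1:5) {
    p <- sample(c("case", "noncase"), 60, TRUE)
    t <- sample(c("case", "noncase"), 60, TRUE, prob = c(0.6, 0.4))
    cc <- confusionCounts(p, t)
    tab <- matrix(cc[c("tp", "fn", "fp", "tn")], 2)
    expect_equal(performanceSummary(cc)$raw$kappa,
                 e1071::classAgreement(tab)$kappa)
  }
})

test_that("rank AUC equals the exhaustive pair oracle and handles ties", {
  truth <- c(rep("case", 5), rep("noncase", 5))
  expect_equal(rocAuc(c(6:10, 1:5), truth), 1)
  expect_equal(rocAuc(rep(0.4, 10), truth), 0.5)
  set.seed(12)
  for (r in 1:4) {
    sc <- round(runif(20), 2)  # rounding induces ties
    tr <- sample(c("case", "noncase"), 20, TRUE)
    if (length(unique(tr)) < 2) next
    expect_equal(rocAuc(sc, tr), oracleAuc(sc, tr), tolerance = 1e-12)
  }
  expect_error(rocAuc(1:5, rep("case", 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  sc <- runif(40)
  tr <- sample(c("case", "noncase"), 40, TRUE)
  expect_equal(rocAuc(sc, tr), rocAuc(qlogis(sc), tr))
  expect_equal(rocAuc(sc, tr), rocAuc(100 * sc + 3, tr))
})

test_that("AUC agrees with pROC on tie-free data", {
  skip_if_not_installed("pROC")
  set.seed(4)
  sc <- runif(50)
  tr <- sample(c("case", "noncase"), 50, TRUE)
  expect_equal(rocAuc(sc, tr),
               as.numeric(pROC::auc(pROC::roc(
                 response = tr, predictor = sc, levels = c("noncase", "case"),
                 direction = "<", quiet = TRUE))))
})

test_that("cutoff sweep hits the degenerate ends and recomputes per cutoff", {
  set.seed(2)
  sc <- runif(40)
  tr <- sample(c("case", "noncase"), 40, TRUE)
  sw <- cutoffSweep(sc, tr, grid = c(0, 0.5, 1))
  expect_equal(sw$sensitivity[1], 100)  # cutoff 0: everyone predicted case
  sw2 <- cutoffSweep(sc, tr, grid = c(0, max(sc) + 1e-6))
  expect_equal(sw2$sensitivity[2], 0)   # above max score: nobody case
  expect_error(cutoffSweep(sc, tr, grid = numeric(0)), "empty")
  expect_error(cutoffSweep(sc, tr, grid = c(-0.1)), "\\[0, 1\\]")
})

test_that("sensitivity is non-increasing and trapezoid equals rank AUC", {
  set.seed(14)
  sc <- runif(200)  # tie-free continuous scores
  tr <- ifelse(runif(200) < plogis(4 * (sc - 0.5)), "case", "noncase")
  grid <- sort(unique(c(0, sc, 1)))
  sw <- cutoffSweep(sc, tr, grid)
  expect_true(all(diff(sw$sensitivity) <= 1e-9))
  # trapezoidal area under (FPR, TPR)
  tpr <- sw$sensitivity / 100
  fpr <- 1 - sw$specificity / 100
  ord <- order(fpr, tpr)
  auc_trap <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2)
  expect_equal(auc_trap, rocAuc(sc, tr), tolerance = 1e-10)
})

test_that("prevalence per 1,000 and its Poisson interval behave", {
  est <- prevalence(100, 10000)
  expect_equal(est$per_1000, 10.0)
  expect_true(est$ci_low < 10 && est$ci_high > 10)
  expect_equal(est$per_1000_raw * est$denominator / 1000,
               est$predicted_cases)
  zero <- prevalence(0, 5000)
  expect_equal(zero$per_1000, 0)
  expect_true(zero$degenerate)
  expect_error(prevalence(10, 0), "positive")
})

test_that("prevalence ratio reproduces printed comparisons", {
  denom <- round(754 / 15.5 * 1000)
  est <- prevalence(708, denom)
  expect_equal(est$per_1000, 14.6)
  expect_equal(prevalenceRatio(est, 15.5), 0.94)
  expect_equal(prevalenceRatio(4.9, 5.5), 0.89)
  expect_equal(prevalenceRatio(10, 10), 1.00)
})

test_that("concordance profile partitions the corpus and matches hand sums", {
  corp <- separableCorpus(40)
  truth <- childStatus(corp)
  set.seed(6)
  sc <- data.frame(child_id = childIds(corp), score = runif(40))
  sc$predicted <- ifelse(sc$score >= 0.5, "case", "noncase")
  prof <- concordanceProfile(corp, sc)
  ns <- unique(prof[, c("cell", "n")])
  expect_equal(sum(ns$n), 40)
  expect_setequal(ns$cell, c("TP", "FP", "FN", "TN"))
  # all children have a single source -> both_sources = 0 everywhere
  both <- prof[prof$statistic == "both_sources_pct", "value"]
  expect_true(all(both[ns$n > 0] == 0))
})

test_that("cell medians and IQRs match order statistics on a toy cell", {
  ch <- data.frame(child_id = paste0("c", 1:5),
                   status = rep("case", 5), sex = "male",
                   race_eth = "white_nh", iq_le_70 = FALSE,
                   prior_asd_dx = TRUE, prior_asd_sped = FALSE,
                   secondary_review = FALSE)
  nev <- c(1L, 2L, 3L, 5L, 9L)
  ev <- do.call(rbind, lapply(1:5, function(i)
    data.frame(child_id = ch$child_id[i], source = "school",
               age_months = seq(30L, by = 6L, length.out = nev[i]),
               text = "autism noted")))
  corp <- SurveillanceCorpus(2008L, ch, ev)
  sc <- data.frame(child_id = ch$child_id, score = 0.9,
                   predicted = "case")
  prof <- concordanceProfile(corp, sc)
  row <- prof[prof$cell == "TP" & prof$statistic == "n_evaluations_median", ]
  expect_equal(row$value, 3)
  expect_equal(c(row$ci_low, row$ci_high),
               unname(quantile(nev, c(0.25, 0.75), type = 2)))
  age <- prof[prof$cell == "TP" & prof$statistic == "age_first_eval_median", ]
  expect_equal(age$value, 30)
})

test_that("score histogram data partitions counts by clinician status", {
  sc <- c(0.1, 0.2, 0.8, 0.9)
  tr <- c("noncase", "noncase", "case", "case")
  h <- scoreHistogramData(sc, tr, breaks = seq(0, 1, 0.5))
  expect_equal(sum(h$count[h$status == "case"]), 2)
  expect_equal(sum(h$count[h$status == "noncase"]), 2)
  expect_equal(h$count[h$status == "case" & h$bin_low == 0.5], 2)
})
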