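#' 2x2 concordance counts between algorithm and clinician
#'
#' Cross-tabulates predicted against clinician-assigned status. Truth is the
#' clinician surveillance classification; prediction is the algorithm. The
#' two vectors must cover the same children: pass named vectors (matched by
#' name) or equal-length aligned vectors.
#'
#' @param predicted character/factor of `"case"`/`"noncase"` predictions, or
#'   the data.frame returned by [predictScores()].
#' @param truth character/factor of clinician statuses (no unknowns).
#' @return object of class `ConfusionCounts`: named integer vector
#'   `(tp, fp, fn, tn)`.
#' @seealso [performanceSummary()]
#' @export
confusionCounts <- function(predicted, truth) {
  if (is.data.frame(predicted)) {
    pr <- stats::setNames(predicted$predicted, predicted$child_id)
  } else pr <- predicted
  if (!is.null(names(pr)) && !is.null(names(truth))) {
    if (!setequal(names(pr), names(truth)))
      stop("predicted and truth cover different child ids")
    truth <- truth[names(pr)]
  } else if (length(pr) != length(truth)) {
    stop("predicted and truth have different lengths and no names to match")
  }
  pr <- as.character(pr); tr <- as.character(truth)
  if (any(!tr %in% c("case", "noncase")))
    stop("truth contains unknown statuses")
  if (any(!pr %in% c("case", "noncase")))
    stop("predictions must be 'case'/'noncase'")
  ConfusionCounts(tp = sum(pr == "case" & tr == "case"),
                  fp = sum(pr == "case" & tr == "noncase"),
                  fn = sum(pr == "noncase" & tr == "case"),
                  tn = sum(pr == "noncase" & tr == "noncase"))
}

#' @rdname confusionCounts
#' @param tp,fp,fn,tn non-negative cell counts (truth in columns, algorithm
#'   in rows), e.g. `ConfusionCounts(633, 75, 121, 621)` for a printed
#'   surveillance-year table.
#' @export
ConfusionCounts <- function(tp, fp, fn, tn) {
  x <- c(tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn), tn = as.integer(tn))
  if (any(is.na(x)) || any(x < 0)) stop("counts must be non-negative")
  if (sum(x) < 1L) stop("confusion table is empty")
  structure(x, class = "ConfusionCounts")
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  m <- matrix(x[c("tp", "fp", "fn", "tn")], 2L, byrow = TRUE,
              dimnames = list(algorithm = c("case", "noncase"),
                              clinician = c("case", "noncase")))
  cat("ConfusionCounts (n =", sum(x), ")\n")
  print(m)
  invisible(x)
}

#' Surveillance performance summary from a confusion table
#'
#' Computes the agreement metrics used to evaluate algorithmic case
#' ascertainment against clinician classification: percent agreement,
#' sensitivity, specificity, positive and negative predictive value, and
#' Cohen's kappa (chance-corrected agreement with expected agreement from
#' the marginal products). Arithmetic is exact before rounding; percentages
#' are reported to 1 decimal and kappa to 2, with unrounded values retained
#' in `$raw`. A metric whose denominator is zero is returned as `NA` rather
#' than fabricated.
#'
#' @param counts a `ConfusionCounts` object (see [confusionCounts()]).
#' @return list with `agreement`, `sensitivity`, `specificity`, `ppv`,
#'   `npv` (percent), `kappa`, `n`, and `raw` (unrounded values).
#' @examples
#' performanceSummary(ConfusionCounts(633, 75, 121, 621))
#' @export
performanceSummary <- function(counts) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  n <- tp + fp + fn + tn
  div <- function(num, den) if (den > 0) num / den else NA_real_
  raw <- list(
    agreement = (tp + tn) / n,
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn))
  p_o <- raw$agreement
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / (n * n)
  raw$kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else if (p_o == 1) 1 else NA_real_
  list(agreement = round(100 * raw$agreement, 1L),
       sensitivity = round(100 * raw$sensitivity, 1L),
       specificity = round(100 * raw$specificity, 1L),
       ppv = round(100 * raw$ppv, 1L),
       npv = round(100 * raw$npv, 1L),
       kappa = round(raw$kappa, 2L),
       n = n,
       raw = raw)
}

#' Rank-based area under the ROC curve
#'
#' AUC as the probability that a randomly chosen case outscores a randomly
#' chosen non-case, with ties credited 1/2 (the Mann-Whitney formulation,
#' computed from ranks). Equals the trapezoidal area under the empirical ROC
#' curve. Forest vote shares lie on a grid of 1/ntree, so ties do occur and
#' the 1/2-credit convention matters.
#'
#' @param scores numeric classification scores.
#' @param truth `"case"`/`"noncase"` per score; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scores, truth) {
  if (!is.null(names(scores)) && !is.null(names(truth)))
    truth <- truth[names(scores)]
  tr <- as.character(truth)
  stopifnot(length(scores) == length(tr))
  is_case <- tr == "case"
  m <- sum(is_case); k <- sum(!is_case)
  if (m == 0L || k == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[is_case]) - m * (m + 1) / 2) / (m * k)
}

#' Performance across a grid of vote-share cutoffs
#'
#' Recomputes predicted statuses (`case` iff score >= cutoff) and the full
#' performance summary at each cutoff in the grid — the sweep behind
#' accuracy/sensitivity/PPV-versus-threshold curves. Values are unrounded
#' percentages.
#'
#' @param scores numeric scores in `[0, 1]` (or a [predictScores()] frame).
#' @param truth `"case"`/`"noncase"` per child.
#' @param grid numeric vector of cutoffs in `[0, 1]`.
#' @return data.frame with one row per cutoff: `cutoff`, `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `kappa`.
#' @export
cutoffSweep <- function(scores, truth, grid = seq(0, 1, by = 0.05)) {
  if (is.data.frame(scores)) {
    truth <- truth[scores$child_id]
    scores <- scores$score
  }
  if (!length(grid)) stop("empty cutoff grid")
  if (any(grid < 0 | grid > 1)) stop("cutoffs must lie in [0, 1]")
  rows <- lapply(grid, function(cut) {
    pred <- ifelse(scores >= cut, "case", "noncase")
    s <- performanceSummary(confusionCounts(pred, as.character(truth)))
    data.frame(cutoff = cut,
               accuracy = 100 * s$raw$agreement,
               sensitivity = 100 * s$raw$sensitivity,
               specificity = 100 * s$raw$specificity,
               ppv = 100 * s$raw$ppv,
               npv = 100 * s$raw$npv,
               kappa = s$raw$kappa)
  })
  do.call(rbind, rows)
}

#' Prevalence per 1,000 from a predicted case count
#'
#' Surveillance-style prevalence: predicted cases over the population
#' denominator, per 1,000 children, with the conventional Poisson
#' log-normal approximate 95% CI for a count
#' (`rate * exp(+/- 1.96 / sqrt(cases))`). A zero case count yields a
#' degenerate (flagged) interval.
#'
#' @param predictedCases non-negative integer count of predicted cases.
#' @param denominator positive population denominator.
#' @return list: `predicted_cases`, `denominator`, `per_1000` (1 decimal),
#'   `per_1000_raw`, `ci_low`, `ci_high`, `ci_method`, `degenerate`.
#' @examples
#' prevalence(708, 48645)
#' @export
prevalence <- function(predictedCases, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  if (predictedCases < 0 || predictedCases > denominator)
    stop("predictedCases must be between 0 and denominator")
  rate <- predictedCases / denominator * 1000
  if (predictedCases > 0) {
    half <- 1.96 / sqrt(predictedCases)
    lo <- rate * exp(-half); hi <- rate * exp(half)
    degen <- FALSE
  } else {
    lo <- 0; hi <- NA_real_; degen <- TRUE
  }
  list(predicted_cases = as.integer(predictedCases),
       denominator = as.integer(denominator),
       per_1000 = round(rate, 1L), per_1000_raw = rate,
       ci_low = round(lo, 1L), ci_high = round(hi, 1L),
       ci_method = "poisson-lognormal", degenerate = degen)
}

#' Ratio of algorithm-derived to published prevalence
#'
#' @param algorithmEst result of [prevalence()] (or a numeric per-1,000
#'   rate).
#' @param publishedPer1000 published prevalence per 1,000 (> 0).
#' @return the ratio, rounded to 2 decimals.
#' @examples
#' prevalenceRatio(prevalence(708, 48645), 15.5)  # 0.94
#' @export
prevalenceRatio <- function(algorithmEst, publishedPer1000) {
  if (publishedPer1000 <= 0) stop("published prevalence must be positive")
  rate <- if (is.list(algorithmEst)) algorithmEst$per_1000_raw else algorithmEst
  round(rate / publishedPer1000, 2L)
}

# Wilson score interval for a binomial proportion
.wilsonCI <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Profile children by algorithm-clinician concordance cell
#'
#' Stratifies the corpus into the four prediction-by-truth cells (true/false
#' positives/negatives) and summarizes each cell: the percentage (with
#' Wilson 95% CI) of each categorical characteristic — sex, race/ethnicity,
#' known IQ <= 70, prior ASD diagnosis / special-education classification,
#' any prior ASD designation, secondary clinician review, and evaluation
#' source mix (school only / health only / both) — plus the median and IQR
#' of the number of evaluations and of age in months at first evaluation.
#'
#' @param corpus a [SurveillanceCorpus-class] with known statuses.
#' @param scores a [predictScores()] data.frame for the same children.
#' @return data.frame in long form: `cell`, `n`, `statistic`, `value`,
#'   `ci_low`, `ci_high` (CIs on percentages only; `value` is the median
#'   for the two count/age rows, with the IQR in `ci_low`/`ci_high`).
#' @export
concordanceProfile <- function(corpus, scores) {
  stopifnot(is(corpus, "SurveillanceCorpus"), is.data.frame(scores))
  truth <- childStatus(corpus)
  if (any(!truth %in% c("case", "noncase")))
    stop("corpus contains children with unknown status")
  pred <- stats::setNames(scores$predicted, scores$child_id)[names(truth)]
  if (anyNA(pred)) stop("scores do not cover every child in the corpus")
  cell <- ifelse(pred == "case",
                 ifelse(truth == "case", "TP", "FP"),
                 ifelse(truth == "case", "FN", "TN"))
  ch <- corpus@children
  ev <- corpus@evaluations
  nev <- table(factor(ev$child_id, levels = ch$child_id))
  agefirst <- vapply(split(ev$age_months, factor(ev$child_id,
                                                 levels = ch$child_id)),
                     min, numeric(1))
  src <- vapply(split(ev$source, factor(ev$child_id, levels = ch$child_id)),
                function(s) {
                  hs <- unique(s)
                  if (length(hs) > 1L) "both"
                  else if (hs == "school") "school_only" else "health_only"
                }, character(1))
  rows <- list()
  for (cl in c("TP", "FP", "FN", "TN")) {
    sel <- cell[ch$child_id] == cl
    n <- sum(sel)
    pct <- function(stat, x, known = rep(TRUE, length(x))) {
      k <- sum(known & sel)
      cnt <- sum(x & known & sel, na.rm = TRUE)
      ci <- .wilsonCI(cnt, k)
      data.frame(cell = cl, n = n, statistic = stat,
                 value = if (k > 0) 100 * cnt / k else NA_real_,
                 ci_low = 100 * ci[1L], ci_high = 100 * ci[2L])
    }
    med <- function(stat, x) {
      v <- x[sel]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 2L)
      data.frame(cell = cl, n = n, statistic = stat, value = q[2L],
                 ci_low = q[1L], ci_high = q[3L])
    }
    rows[[cl]] <- rbind(
      pct("male_pct", ch$sex == "male", !is.na(ch$sex)),
      pct("nonhispanic_white_pct", ch$race_eth == "white_nh",
          !is.na(ch$race_eth)),
      pct("iq_le_70_pct", ch$iq_le_70, !is.na(ch$iq_le_70)),
      pct("prior_asd_dx_pct", ch$prior_asd_dx),
      pct("prior_asd_sped_pct", ch$prior_asd_sped),
      pct("any_prior_asd_pct", ch$prior_asd_dx | ch$prior_asd_sped),
      pct("secondary_review_pct", ch$secondary_review,
          !is.na(ch$secondary_review)),
      pct("school_only_pct", src == "school_only"),
      pct("health_only_pct", src == "health_only"),
      pct("both_sources_pct", src == "both"),
      med("n_evaluations_median", as.numeric(nev)),
      med("age_first_eval_median", agefirst))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Histogram data of classification scores by clinician status
#'
#' Bins the scores separately for clinician-classified cases and non-cases —
#' the data behind score-distribution histograms that show where the two
#' classes concentrate relative to the cutoff.
#'
#' @param scores a [predictScores()] data.frame or numeric scores.
#' @param truth `"case"`/`"noncase"` per child.
#' @param breaks histogram breaks over `[0, 1]`.
#' @return data.frame `bin_low`, `bin_high`, `status`, `count`.
#' @export
scoreHistogramData <- function(scores, truth, breaks = seq(0, 1, by = 0.05)) {
  if (is.data.frame(scores)) {
    truth <- truth[scores$child_id]
    scores <- scores$score
  }
  truth <- as.character(truth)
  out <- lapply(c("case", "noncase"), function(st) {
    h <- hist(scores[truth == st], breaks = breaks, plot = FALSE)
    data.frame(bin_low = utils::head(breaks, -1L),
               bin_high = breaks[-1L], status = st, count = h$counts)
  })
  do.call(rbind, out)
}

#' Evaluate predictions against clinician truth
#'
#' Convenience wrapper producing the full evaluation of a scored corpus:
#' confusion counts, the performance summary, and the rank-based AUC.
#'
#' @param scores a [predictScores()] data.frame.
#' @param truth named `"case"`/`"noncase"` vector (e.g. [childStatus()]).
#' @return list with `confusion`, `summary` (including `$auc`).
#' @export
evaluateScores <- function(scores, truth) {
  cc <- confusionCounts(scores, truth)
  s <- performanceSummary(cc)
  s$auc <- rocAuc(stats::setNames(scores$score, scores$child_id), truth)
  list(confusion = cc, summary = s)
}

#' @importFrom graphics hist
NULL
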