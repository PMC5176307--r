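#' Configuration of the synthetic surveillance corpus generator
#'
#' Full parameterization of a generated corpus: cohort size and case
#' fraction, the planted discriminative vocabulary and its class effect
#' sizes, the per-class distributions of evaluation counts, ages at first
#' evaluation, evaluation sources and child metadata, the token model, and
#' the seed. Defaults emulate the statistical structure of an ADDM-style
#' surveillance year: ~52% cases, evaluation-count medians near 7 (case) and
#' 4 (non-case), age-at-first-evaluation medians near 40 and 53 months, and
#' a school/health source mix that differs by class.
#'
#' @slot nChildren integer(1) number of children.
#' @slot caseFraction numeric(1) case probability (default 601/1162).
#' @slot nDiscriminative integer(1) number of planted discriminative terms.
#' @slot nNoise integer(1) number of class-independent noise word types.
#' @slot effectLogOdds numeric, log-odds shift of per-token planted-term
#'   usage in cases versus non-cases (scalar or one per planted term).
#' @slot plantedPhrases character, the planted surface phrases; multi-word
#'   phrases are emitted as contiguous token runs so the n-gram extractor
#'   can rediscover them. Defaults to autism-like symptom vocabulary.
#' @slot baselineProb numeric(1) per-token probability of each planted term
#'   in non-case text.
#' @slot childEffectSd numeric(1) SD of the per-child random effect on the
#'   planted-term logit (within-child correlation across evaluations).
#' @slot zipfExponent numeric(1) exponent of the Zipf-like noise frequency
#'   profile.
#' @slot evalsMu,evalsSize numeric(2) named `case`/`noncase` negative-
#'   binomial parameters for evaluations per child (shifted by 1 so every
#'   child has at least one evaluation).
#' @slot ageMedianMonths,ageSdlog numeric(2) log-normal parameters for age
#'   at first evaluation, in months.
#' @slot evalGapMeanMonths numeric(1) mean exponential gap between a
#'   child's successive evaluations.
#' @slot sourceMix 2x3 matrix of per-class probabilities over
#'   school-only / health-only / both sources.
#' @slot tokensMu,tokensSize numeric(1) negative-binomial parameters for
#'   tokens per evaluation (minimum 5).
#' @slot sexMaleP,iqLe70P,priorDxP,priorSpedP,secondaryReviewP numeric(2)
#'   per-class probabilities of the child metadata flags.
#' @slot raceProbs named numeric, race/ethnicity distribution.
#' @slot seed integer(1).
#' @export
setClass("SynthConfig",
  slots = c(nChildren = "integer", caseFraction = "numeric",
            nDiscriminative = "integer", nNoise = "integer",
            effectLogOdds = "numeric", plantedPhrases = "character",
            baselineProb = "numeric", childEffectSd = "numeric",
            zipfExponent = "numeric",
            evalsMu = "numeric", evalsSize = "numeric",
            ageMedianMonths = "numeric", ageSdlog = "numeric",
            evalGapMeanMonths = "numeric", sourceMix = "matrix",
            tokensMu = "numeric", tokensSize = "numeric",
            sexMaleP = "numeric", iqLe70P = "numeric", priorDxP = "numeric",
            priorSpedP = "numeric", secondaryReviewP = "numeric",
            raceProbs = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msgs <- character()
  if (object@nChildren < 2L) msgs <- c(msgs, "nChildren must be >= 2")
  if (object@caseFraction < 0 || object@caseFraction > 1)
    msgs <- c(msgs, "caseFraction must be in [0, 1]")
  if (length(object@plantedPhrases) != object@nDiscriminative)
    msgs <- c(msgs, "plantedPhrases length must equal nDiscriminative")
  if (!length(object@effectLogOdds) %in% c(1L, object@nDiscriminative))
    msgs <- c(msgs, "effectLogOdds must be scalar or one per planted term")
  if (any(object@effectLogOdds < 0))
    msgs <- c(msgs, "effectLogOdds must be >= 0")
  if (object@baselineProb <= 0 || object@baselineProb >= 1)
    msgs <- c(msgs, "baselineProb must be in (0, 1)")
  if (object@tokensMu <= 0) msgs <- c(msgs, "tokensMu must be positive")
  if (!all(dim(object@sourceMix) == c(2L, 3L)) ||
      any(abs(rowSums(object@sourceMix) - 1) > 1e-8))
    msgs <- c(msgs, "sourceMix must be a 2x3 matrix with rows summing to 1")
  if (abs(sum(object@raceProbs) - 1) > 1e-8)
    msgs <- c(msgs, "raceProbs must sum to 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

.DEFAULT_PHRASES <- c(
  "autism", "eye contact", "social interaction", "spectrum disorder",
  "repetitive behavior", "hand flapping", "pervasive developmental",
  "joint attention", "stereotyped movements", "sensory seeking",
  "echolalia", "restricted interests", "parallel play", "lining up toys",
  "nonverbal communication")

# deterministic pronounceable letter-only pseudo-words for the noise
# vocabulary (digits would be deleted by the tokenizer)
.synthWords <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r",
            "s", "t", "v", "z", "th", "ch", "st", "br", "cl", "dr")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))  # 100 syllables
  i <- seq_len(n) - 1L
  w <- paste0(syl[(i %% 100L) + 1L],
              syl[((i %/% 100L) %% 100L) + 1L],
              syl[(i %/% 10000L) + 1L])
  make.unique(w, sep = "x")
}

#' @describeIn SynthConfig-class constructor; any parameter can be
#'   overridden, defaults emulate an ADDM-like surveillance year.
#' @param nChildren,caseFraction cohort size and case probability.
#' @param nDiscriminative,nNoise,effectLogOdds,plantedPhrases,baselineProb,childEffectSd,zipfExponent
#'   token-model parameters (see slots).
#' @param evalsMu,evalsSize,ageMedianMonths,ageSdlog,evalGapMeanMonths,sourceMix,tokensMu,tokensSize
#'   evaluation-structure parameters (see slots).
#' @param sexMaleP,iqLe70P,priorDxP,priorSpedP,secondaryReviewP,raceProbs
#'   child-metadata probabilities (see slots).
#' @param seed integer seed.
#' @return a validated `SynthConfig`
#' @examples
#' synthConfig(nChildren = 100, seed = 7)
#' @export
synthConfig <- function(nChildren = 500L, caseFraction = 601 / 1162,
                        nDiscriminative = 10L, nNoise = 600L,
                        effectLogOdds = 2.0,
                        plantedPhrases = .DEFAULT_PHRASES[seq_len(nDiscriminative)],
                        baselineProb = 0.003, childEffectSd = 0.5,
                        zipfExponent = 1.05,
                        evalsMu = c(case = 7.5, noncase = 4.2),
                        evalsSize = c(case = 4, noncase = 4),
                        ageMedianMonths = c(case = 40, noncase = 53),
                        ageSdlog = c(case = 0.5, noncase = 0.45),
                        evalGapMeanMonths = 8,
                        sourceMix = rbind(case = c(0.224, 0.117, 0.659),
                                          noncase = c(0.430, 0.216, 0.354)),
                        tokensMu = 40, tokensSize = 8,
                        sexMaleP = c(case = 0.837, noncase = 0.718),
                        iqLe70P = c(case = 0.35, noncase = 0.22),
                        priorDxP = c(case = 0.75, noncase = 0.04),
                        priorSpedP = c(case = 0.65, noncase = 0.01),
                        secondaryReviewP = c(case = 0.15, noncase = 0.30),
                        raceProbs = c(white_nh = 0.39, black_nh = 0.38,
                                      hispanic = 0.12, other = 0.11),
                        seed = 1L) {
  if (nDiscriminative > length(.DEFAULT_PHRASES) &&
      missing(plantedPhrases))
    plantedPhrases <- c(.DEFAULT_PHRASES,
                        paste("marker", .synthWords(nDiscriminative -
                                                    length(.DEFAULT_PHRASES))))
  colnames(sourceMix) <- c("school_only", "health_only", "both")
  new("SynthConfig", nChildren = as.integer(nChildren),
      caseFraction = caseFraction,
      nDiscriminative = as.integer(nDiscriminative),
      nNoise = as.integer(nNoise),
      effectLogOdds = as.numeric(effectLogOdds),
      plantedPhrases = plantedPhrases, baselineProb = baselineProb,
      childEffectSd = childEffectSd, zipfExponent = zipfExponent,
      evalsMu = evalsMu, evalsSize = evalsSize,
      ageMedianMonths = ageMedianMonths, ageSdlog = ageSdlog,
      evalGapMeanMonths = evalGapMeanMonths, sourceMix = sourceMix,
      tokensMu = tokensMu, tokensSize = tokensSize,
      sexMaleP = sexMaleP, iqLe70P = iqLe70P, priorDxP = priorDxP,
      priorSpedP = priorSpedP, secondaryReviewP = secondaryReviewP,
      raceProbs = raceProbs, seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig: ", object@nChildren, " children (case fraction ",
      sprintf("%.3f", object@caseFraction), "), ",
      object@nDiscriminative, " planted terms (log-odds ",
      paste(unique(object@effectLogOdds), collapse = "/"), ") among ",
      object@nNoise, " noise terms, seed ", object@seed, "\n", sep = "")
})

# statuses: NULL -> Bernoulli(caseFraction) with a guard that both classes
# are realized when the fraction is interior
.drawStatuses <- function(config) {
  st <- ifelse(stats::runif(config@nChildren) < config@caseFraction,
               "case", "noncase")
  if (config@caseFraction > 0 && config@caseFraction < 1 &&
      length(unique(st)) == 1L) {
    st[1L] <- setdiff(c("case", "noncase"), st[1L])
  }
  st
}

.generateGivenStatus <- function(config, statuses, year, idPrefix) {
  n <- length(statuses)
  eff <- rep_len(config@effectLogOdds, config@nDiscriminative)
  noise_words <- .synthWords(config@nNoise)
  noise_p <- (1 / seq_len(config@nNoise)^config@zipfExponent)
  noise_p <- noise_p / sum(noise_p)
  planted_tokens <- strsplit(tolower(config@plantedPhrases), " ", fixed = TRUE)
  ids <- sprintf("%s%05d", idPrefix, seq_len(n))
  is_case <- statuses == "case"
  cls <- ifelse(is_case, "case", "noncase")

  n_evals <- 1L + stats::rnbinom(n, size = config@evalsSize[cls],
                                 mu = pmax(config@evalsMu[cls] - 1, 0.1))
  age_first <- pmax(6, round(stats::rlnorm(
    n, meanlog = log(config@ageMedianMonths[cls]),
    sdlog = config@ageSdlog[cls])))
  sex <- ifelse(stats::runif(n) < config@sexMaleP[cls], "male", "female")
  race <- sample(names(config@raceProbs), n, replace = TRUE,
                 prob = config@raceProbs)
  iq <- stats::runif(n) < config@iqLe70P[cls]
  pdx <- stats::runif(n) < config@priorDxP[cls]
  psped <- stats::runif(n) < config@priorSpedP[cls]
  srev <- stats::runif(n) < config@secondaryReviewP[cls]
  u_child <- stats::rnorm(n, 0, config@childEffectSd)
  base_logit <- stats::qlogis(config@baselineProb)

  ev_child <- rep(ids, n_evals)
  ev_class <- rep(cls, n_evals)
  ev_u <- rep(u_child, n_evals)
  n_ev_tot <- length(ev_child)
  # ages: first age plus cumulative exponential gaps within each child
  gaps <- round(stats::rexp(n_ev_tot, rate = 1 / config@evalGapMeanMonths))
  first <- rep(age_first, n_evals)
  idx_within <- sequence(n_evals)
  gaps[idx_within == 1L] <- 0
  ev_age <- first + ave(gaps, rep(seq_len(n), n_evals), FUN = cumsum)
  # sources: draw each child's mix category, then per-evaluation labels
  mixcat <- vapply(seq_len(n), function(i)
    sample(colnames(config@sourceMix), 1L,
           prob = config@sourceMix[cls[i], ]), character(1))
  ev_mix <- rep(mixcat, n_evals)
  ev_src <- ifelse(ev_mix == "school_only", "school",
            ifelse(ev_mix == "health_only", "health",
                   ifelse(stats::runif(n_ev_tot) < 0.5, "school", "health")))
  # a "both" child must actually show both sources
  both_first2 <- ev_mix == "both" & idx_within <= 2L
  ev_src[both_first2] <- rep(c("school", "health"),
                             length.out = sum(both_first2))

  n_tok <- pmax(5L, stats::rnbinom(n_ev_tot, size = config@tokensSize,
                                   mu = config@tokensMu))
  # planted-term instance counts per evaluation: Binomial(nTok, p) with a
  # class shift and a shared per-child random effect on the logit
  texts <- character(n_ev_tot)
  logit_shift <- ifelse(ev_class == "case", 1, 0)
  for (e in seq_len(n_ev_tot)) {
    nt <- n_tok[e]
    p_t <- stats::plogis(base_logit + eff * logit_shift[e] + ev_u[e])
    k_t <- stats::rbinom(config@nDiscriminative, nt, p_t)
    n_noise <- max(0L, nt - sum(k_t))
    toks <- sample(noise_words, n_noise, replace = TRUE, prob = noise_p)
    if (sum(k_t) > 0) {
      # interleave planted phrases (kept contiguous) among the noise tokens
      units <- rep(seq_len(config@nDiscriminative), k_t)
      allu <- c(as.list(toks), lapply(units, function(t) planted_tokens[[t]]))
      toks <- unlist(allu[sample(length(allu))], use.names = FALSE)
    }
    texts[e] <- paste(toks, collapse = " ")
  }

  children <- data.frame(
    child_id = ids, status = statuses, sex = sex, race_eth = race,
    iq_le_70 = iq, prior_asd_dx = pdx, prior_asd_sped = psped,
    secondary_review = srev, stringsAsFactors = FALSE)
  evaluations <- data.frame(
    child_id = ev_child, source = ev_src, age_months = as.integer(ev_age),
    text = texts, stringsAsFactors = FALSE)
  corpus <- SurveillanceCorpus(year, children, evaluations)

  stem_phrase <- vapply(planted_tokens, function(t)
    paste(porterStem(t), collapse = " "), character(1))
  truth <- list(
    status = stats::setNames(statuses, ids),
    plantedTerms = data.frame(term = stem_phrase,
                              phrase = config@plantedPhrases,
                              effectLogOdds = eff, stringsAsFactors = FALSE))
  list(corpus = corpus, truth = truth)
}

#' Generate a synthetic surveillance corpus with known ground truth
#'
#' Draws a fully reproducible corpus from the generative model of
#' [synthConfig()]: child statuses at the configured case fraction;
#' per-evaluation token streams mixing Zipf-distributed noise words
#' (class-independent) with planted discriminative terms whose per-token
#' usage logit is shifted by `effectLogOdds` in cases and by a shared
#' per-child random effect; evaluation counts, ages, sources and child
#' metadata from the per-class distributions. The returned truth carries
#' the per-child status and the planted terms in their stemmed n-gram form.
#'
#' @param config a [SynthConfig-class].
#' @param surveillanceYear year stamped on the corpus.
#' @param idPrefix prefix for generated child ids.
#' @return list with `corpus` (a [SurveillanceCorpus-class]) and `truth`
#'   (list: `status`, `plantedTerms`).
#' @examples
#' gen <- generateCorpus(synthConfig(nChildren = 50, seed = 1))
#' gen$corpus
#' @export
generateCorpus <- function(config = synthConfig(), surveillanceYear = 2008L,
                           idPrefix = "S") {
  validObject(config)
  set.seed(config@seed)
  statuses <- .drawStatuses(config)
  .generateGivenStatus(config, statuses, surveillanceYear, idPrefix)
}

#' Null (no-signal) generator configuration
#'
#' A configuration in which case and non-case children are exchangeable in
#' everything that reaches the text: zero planted effect and identical
#' per-class evaluation-count distributions. The default configuration's
#' class contrasts in evaluation counts are themselves textual signal
#' (longer composite documents for cases, emulating the real cohort), so a
#' meaningful null requires equalizing them, not just zeroing the planted
#' effects. Child metadata contrasts are retained; they never enter the
#' features.
#'
#' @param nChildren,seed passed to [synthConfig()].
#' @param ... further overrides passed to [synthConfig()].
#' @return a [SynthConfig-class] with no class signal in the text.
#' @export
nullSynthConfig <- function(nChildren = 500L, seed = 1L, ...) {
  synthConfig(nChildren = nChildren, effectLogOdds = 0,
              evalsMu = c(case = 5.5, noncase = 5.5),
              evalsSize = c(case = 4, noncase = 4), seed = seed, ...)
}

#' Generate a matched training/testing corpus pair of ADDM-like size
#'
#' Two corpora from one generative configuration (shared planted vocabulary
#' and effect sizes), sized as the 2008 and 2010 Georgia surveillance
#' cohorts: exactly 1162 children with 601 cases for training, 1450
#' children with 754 cases for testing. Statuses are assigned by exact
#' allocation and then shuffled; texts are sampled afterwards.
#'
#' @param seed integer master seed.
#' @param config a [SynthConfig-class] providing the generative parameters
#'   (its own `nChildren`/`caseFraction`/`seed` are overridden).
#' @param nTrain,nCaseTrain,nTest,nCaseTest cohort sizes.
#' @return list with `train`, `test` (corpora) and `truth` (list with
#'   `train`, `test` statuses and the shared `plantedTerms`).
#' @export
addmLikePair <- function(seed = 1L, config = synthConfig(),
                         nTrain = 1162L, nCaseTrain = 601L,
                         nTest = 1450L, nCaseTest = 754L) {
  validObject(config)
  set.seed(as.integer(seed))
  st_train <- sample(c(rep("case", nCaseTrain),
                       rep("noncase", nTrain - nCaseTrain)))
  cfg <- config
  cfg@nChildren <- as.integer(nTrain)
  train <- .generateGivenStatus(cfg, st_train, 2008L, "TR")
  st_test <- sample(c(rep("case", nCaseTest),
                      rep("noncase", nTest - nCaseTest)))
  cfg@nChildren <- as.integer(nTest)
  test <- .generateGivenStatus(cfg, st_test, 2010L, "TE")
  list(train = train$corpus, test = test$corpus,
       truth = list(train = train$truth$status, test = test$truth$status,
                    plantedTerms = train$truth$plantedTerms))
}
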