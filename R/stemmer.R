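# Porter stemmer (M.F. Porter, 1980), implemented from the algorithm's
# published definition. Operates on lower-case alphabetic tokens; words of
# length <= 2 are returned unchanged, as the algorithm specifies.

.VOWELS <- c("a", "e", "i", "o", "u")

# consonant flags per position; y is a consonant at position 1 or after a
# vowel, a vowel after a consonant
.consFlags <- function(chars) {
  n <- length(chars)
  fl <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    fl[i] <- if (ch %in% .VOWELS) FALSE
             else if (ch == "y") (i == 1L) || !fl[i - 1L]
             else TRUE
  }
  fl
}

# measure m of a stem: [C](VC)^m[V] on collapsed consonant/vowel runs
.measure <- function(stem) {
  if (!nchar(stem)) return(0L)
  runs <- rle(.consFlags(strsplit(stem, "", fixed = TRUE)[[1L]]))$values
  if (length(runs) < 2L) return(0L)
  sum(!runs[-length(runs)] & runs[-1L])
}

.hasVowel <- function(stem) {
  nchar(stem) > 0L && any(!.consFlags(strsplit(stem, "", fixed = TRUE)[[1L]]))
}

.endsDoubleCons <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  a <- substr(w, n - 1L, n - 1L)
  b <- substr(w, n, n)
  a == b && .consFlags(strsplit(w, "", fixed = TRUE)[[1L]])[n]
}

# *o: stem ends consonant-vowel-consonant where the final consonant is not
# w, x or y
.endsCvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  fl <- .consFlags(strsplit(w, "", fixed = TRUE)[[1L]])
  fl[n - 2L] && !fl[n - 1L] && fl[n] &&
    !substr(w, n, n) %in% c("w", "x", "y")
}

.chop <- function(w, k) substr(w, 1L, nchar(w) - k)

# suffix maps for steps 2-4, longest suffix checked first
.STEP2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
            izer = "ize", abli = "able", alli = "al", entli = "ent",
            eli = "e", ousli = "ous", ization = "ize", ation = "ate",
            ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
            ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble")
.STEP3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
            ical = "ic", ful = "", ness = "")
.STEP4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
            "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
            "ous", "ive", "ize")

.ordByLen <- function(x) x[order(-nchar(x))]
.STEP2_SUF <- .ordByLen(names(.STEP2))
.STEP3_SUF <- .ordByLen(names(.STEP3))
.STEP4_SUF <- .ordByLen(.STEP4)

.porterOne <- function(w) {
  if (nchar(w) <= 2L) return(w)

  # step 1a: plurals
  if (endsWith(w, "sses")) w <- paste0(.chop(w, 4L), "ss")
  else if (endsWith(w, "ies")) w <- paste0(.chop(w, 3L), "i")
  else if (!endsWith(w, "ss") && endsWith(w, "s")) w <- .chop(w, 1L)

  # step 1b: -eed / -ed / -ing
  if (endsWith(w, "eed")) {
    if (.measure(.chop(w, 3L)) > 0L) w <- .chop(w, 1L)
  } else {
    stripped <- FALSE
    if (endsWith(w, "ed") && .hasVowel(.chop(w, 2L))) {
      w <- .chop(w, 2L); stripped <- TRUE
    } else if (endsWith(w, "ing") && .hasVowel(.chop(w, 3L))) {
      w <- .chop(w, 3L); stripped <- TRUE
    }
    if (stripped) {
      if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
        w <- paste0(w, "e")
      } else if (.endsDoubleCons(w) &&
                 !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- .chop(w, 1L)
      } else if (.measure(w) == 1L && .endsCvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c: y -> i. Uses the revised condition (y preceded by a consonant,
  # stem containing a vowel), which keeps play/played/playing on one stem
  # instead of splitting plai from play.
  if (endsWith(w, "y")) {
    stem <- .chop(w, 1L)
    if (.hasVowel(stem) &&
        .consFlags(strsplit(w, "", fixed = TRUE)[[1L]])[nchar(stem)])
      w <- paste0(stem, "i")
  }

  # step 2 (m > 0): double-suffix reductions
  for (suf in .STEP2_SUF) {
    if (endsWith(w, suf)) {
      stem <- .chop(w, nchar(suf))
      if (.measure(stem) > 0L) w <- paste0(stem, .STEP2[[suf]])
      break
    }
  }

  # step 3 (m > 0)
  for (suf in .STEP3_SUF) {
    if (endsWith(w, suf)) {
      stem <- .chop(w, nchar(suf))
      if (.measure(stem) > 0L) w <- paste0(stem, .STEP3[[suf]])
      break
    }
  }

  # step 4 (m > 1): strip residual suffixes; -ion only after s or t
  for (suf in .STEP4_SUF) {
    if (endsWith(w, suf)) {
      stem <- .chop(w, nchar(suf))
      if (.measure(stem) > 1L &&
          (suf != "ion" ||
           substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")))
        w <- stem
      break
    }
  }

  # step 5a: drop final e. The m == 1 branch keeps stems of fewer than 3
  # letters intact (eye, use stay whole), matching the Snowball English
  # treatment of short words.
  if (endsWith(w, "e")) {
    stem <- .chop(w, 1L)
    m <- .measure(stem)
    if (m > 1L || (m == 1L && nchar(stem) > 2L && !.endsCvc(stem)))
      w <- stem
  }

  # step 5b: -ll -> -l when m > 1
  if (.measure(w) > 1L && .endsDoubleCons(w) && endsWith(w, "l"))
    w <- .chop(w, 1L)

  w
}

#' Porter stemming
#'
#' Stems English words with the Porter (1980) algorithm: the suffix-stripping
#' procedure standard in bag-of-words text mining (`playing`, `played` ->
#' `play`; `relational` -> `relat`). Words are expected lower-case; words of
#' two letters or fewer are returned unchanged. Stemming is computed once per
#' unique word, so long token streams are cheap.
#'
#' @param words character vector of lower-case words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porterStem(c("playing", "played", "caresses", "ponies"))
#' @export
porterStem <- function(words) {
  words <- as.character(words)
  if (!length(words)) return(character(0))
  u <- unique(words)
  stems <- vapply(u, .porterOne, character(1), USE.NAMES = FALSE)
  stems[match(words, u)]
}
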