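#' Read a surveillance corpus from a JSON-lines file
#'
#' The on-disk format is one JSON object per line, UTF-8, LF line endings.
#' Line 1 is a header `{"surveillance_year": ..., "schema_version": "1.0"}`;
#' every subsequent line is one child record with its nested evaluations.
#' Malformed lines are reported with their line numbers; duplicate child ids
#' fail validation naming the offending id.
#'
#' @param path path to a `.jsonl` corpus file.
#' @return a [SurveillanceCorpus-class]
#' @seealso [writeCorpus()], [readCorpusCsv()]
#' @export
readCorpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty corpus file: ", path)
  hdr <- tryCatch(jsonlite::fromJSON(lines[[1L]]),
                  error = function(e) stop("line 1: malformed header: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(hdr$surveillance_year))
    stop("line 1: header is missing 'surveillance_year'")
  body <- lines[-1L]
  body_no <- which(nzchar(body)) + 1L
  body <- body[nzchar(body)]
  children <- vector("list", length(body))
  evals <- vector("list", length(body))
  for (i in seq_along(body)) {
    rec <- tryCatch(
      jsonlite::fromJSON(body[[i]], simplifyDataFrame = TRUE),
      error = function(e) stop("line ", body_no[i], ": malformed record: ",
                               conditionMessage(e), call. = FALSE))
    req <- c("child_id", "status", "evaluations")
    miss <- req[vapply(req, function(f) is.null(rec[[f]]), logical(1))]
    if (length(miss))
      stop("line ", body_no[i], ": missing required field(s): ",
           paste(miss, collapse = ", "))
    children[[i]] <- data.frame(
      child_id = as.character(rec$child_id),
      status = as.character(rec$status),
      sex = .nullToNA(rec$sex), race_eth = .nullToNA(rec$race_eth),
      iq_le_70 = .nullToNA(rec$iq_le_70, NA),
      prior_asd_dx = isTRUE(rec$prior_asd_dx),
      prior_asd_sped = isTRUE(rec$prior_asd_sped),
      secondary_review = .nullToNA(rec$secondary_review, NA),
      stringsAsFactors = FALSE)
    ev <- as.data.frame(rec$evaluations, stringsAsFactors = FALSE)
    if (!nrow(ev))
      stop("line ", body_no[i], ": child '", rec$child_id,
           "' has no evaluations")
    ev$child_id <- as.character(rec$child_id)
    evals[[i]] <- ev
  }
  if (!length(children)) {
    empty_ch <- data.frame(child_id = character(0), status = character(0),
                           stringsAsFactors = FALSE)
    empty_ev <- data.frame(child_id = character(0), source = character(0),
                           age_months = integer(0), text = character(0),
                           stringsAsFactors = FALSE)
    return(SurveillanceCorpus(hdr$surveillance_year, empty_ch, empty_ev))
  }
  children <- do.call(rbind, children)
  dup <- unique(children$child_id[duplicated(children$child_id)])
  if (length(dup))
    stop("duplicate child_id in corpus: ", paste(dup, collapse = ", "))
  SurveillanceCorpus(hdr$surveillance_year, children, do.call(rbind, evals))
}

.nullToNA <- function(x, na = NA_character_) if (is.null(x)) na else x

#' Write a surveillance corpus as JSON lines
#'
#' Writes the canonical JSON-lines representation read by [readCorpus()].
#' Output is byte-stable: fixed key order, fixed number formatting, UTF-8,
#' LF endings, children in corpus order and evaluations in input order, so
#' two writes of the same corpus are identical files.
#'
#' @param corpus a [SurveillanceCorpus-class]
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(corpus, path) {
  stopifnot(is(corpus, "SurveillanceCorpus"))
  validObject(corpus)
  ch <- corpus@children
  ev <- corpus@evaluations
  hdr <- sprintf('{"surveillance_year":%d,"schema_version":"1.0"}',
                 corpus@surveillanceYear)
  evsplit <- split(ev, factor(ev$child_id, levels = ch$child_id))
  recs <- vapply(seq_len(nrow(ch)), function(i) {
    e <- evsplit[[ch$child_id[i]]]
    evj <- vapply(seq_len(nrow(e)), function(j) {
      sprintf('{"source":%s,"age_months":%d,"text":%s}',
              .jstr(e$source[j]), e$age_months[j], .jstr(e$text[j]))
    }, character(1))
    sprintf(paste0('{"child_id":%s,"status":%s,"sex":%s,"race_eth":%s,',
                   '"iq_le_70":%s,"prior_asd_dx":%s,"prior_asd_sped":%s,',
                   '"secondary_review":%s,"evaluations":[%s]}'),
            .jstr(ch$child_id[i]), .jstr(ch$status[i]), .jstr(ch$sex[i]),
            .jstr(ch$race_eth[i]), .jbool(ch$iq_le_70[i]),
            .jbool(ch$prior_asd_dx[i]), .jbool(ch$prior_asd_sped[i]),
            .jbool(ch$secondary_review[i]), paste(evj, collapse = ","))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(hdr, recs)), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.jstr <- function(x) {
  if (is.na(x)) return("null")
  as.character(jsonlite::toJSON(unbox(x)))
}

.jbool <- function(x) {
  if (is.na(x)) "null" else if (x) "true" else "false"
}

#' @importFrom jsonlite unbox
NULL

#' Read / write the two-file CSV corpus dialect
#'
#' For interoperability a corpus can be stored as `children.csv` (one row
#' per child) plus `evaluations.csv` (one row per evaluation, joined on
#' `child_id`). `readCorpusCsv()`/`writeCorpusCsv()` convert between this
#' dialect and [SurveillanceCorpus-class] objects losslessly.
#'
#' @param childrenPath,evaluationsPath paths to the two CSV files.
#' @param surveillanceYear integer surveillance year (stored in the children
#'   file by `writeCorpusCsv` as a `surveillance_year` column).
#' @return `readCorpusCsv` returns a [SurveillanceCorpus-class];
#'   `writeCorpusCsv` the two paths, invisibly.
#' @export
readCorpusCsv <- function(childrenPath, evaluationsPath,
                          surveillanceYear = NULL) {
  ch <- utils::read.csv(childrenPath, stringsAsFactors = FALSE)
  ev <- utils::read.csv(evaluationsPath, stringsAsFactors = FALSE)
  if (is.null(surveillanceYear)) {
    if (!"surveillance_year" %in% names(ch))
      stop("surveillanceYear not given and children.csv has no ",
           "surveillance_year column")
    surveillanceYear <- ch$surveillance_year[1L]
  }
  ch$surveillance_year <- NULL
  SurveillanceCorpus(surveillanceYear, ch, ev)
}

#' @rdname readCorpusCsv
#' @param corpus a [SurveillanceCorpus-class]
#' @export
writeCorpusCsv <- function(corpus, childrenPath, evaluationsPath) {
  stopifnot(is(corpus, "SurveillanceCorpus"))
  ch <- corpus@children
  ch$surveillance_year <- corpus@surveillanceYear
  utils::write.csv(ch, childrenPath, row.names = FALSE)
  utils::write.csv(corpus@evaluations, evaluationsPath, row.names = FALSE)
  invisible(c(childrenPath, evaluationsPath))
}

#' Aggregate each child's evaluations into one document
#'
#' Concatenates a child's evaluation texts into a single body of text, the
#' unit on which the bag-of-words features are computed. Evaluations are
#' ordered deterministically — ascending age at evaluation, ties broken by
#' source (alphabetical: health before school) and then input order — and
#' joined with a single space, so the same corpus always yields the same
#' documents regardless of evaluation input order.
#'
#' @param corpus a [SurveillanceCorpus-class]
#' @param childId optional character vector restricting to particular
#'   children (default: all, in corpus order).
#' @return named character vector of documents, one per child.
#' @examples
#' ch <- data.frame(child_id = "c1", status = "case")
#' ev <- data.frame(child_id = "c1", source = c("school", "health"),
#'                  age_months = c(53L, 40L), text = c("B", "A"))
#' aggregateChildText(SurveillanceCorpus(2008L, ch, ev))  # "A B"
#' @export
aggregateChildText <- function(corpus, childId = NULL) {
  stopifnot(is(corpus, "SurveillanceCorpus"))
  ids <- if (is.null(childId)) corpus@children$child_id else as.character(childId)
  ev <- corpus@evaluations
  missing <- setdiff(ids, ev$child_id)
  if (length(missing))
    stop("child with no evaluations: ", paste(missing, collapse = ", "))
  ev <- ev[ev$child_id %in% ids, , drop = FALSE]
  ord <- order(match(ev$child_id, ids), ev$age_months, ev$source)
  ev <- ev[ord, , drop = FALSE]
  docs <- vapply(split(ev$text, factor(ev$child_id, levels = ids)),
                 paste, character(1), collapse = " ")
  docs[ids]
}
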