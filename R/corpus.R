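#' The nine HONcode detection criteria
#'
#' The Health On the Net code of conduct comprises eight principles. For
#' automated detection the "attribution" principle is split into two
#' separately detectable parts, "reference" (sources are cited) and "date"
#' (the page carries a dating statement), giving nine detection criteria.
#'
#' @return Character vector of the nine criterion identifiers, in a fixed
#'   canonical order.
#' @examples
#' hon_criteria()
#' @export
hon_criteria <- function() {
  c(
    "authority", "complementarity", "privacy", "reference", "date",
    "justifiability", "contact_details", "financial_disclosure",
    "advertising_policy"
  )
}

# Fail fast on anything outside the closed criterion set.
check_criterion <- function(criterion, what = "criterion") {
  bad <- setdiff(criterion, hon_criteria())
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown %s: %s. Must be one of: %s. Note that 'attribution' is split into 'reference' and 'date'.",
      what, paste(sQuote(bad), collapse = ", "),
      paste(hon_criteria(), collapse = ", ")
    ))
  }
  invisible(criterion)
}

#' Build a training corpus from labelled extracts
#'
#' A training corpus holds the labelled compliance extracts together with the
#' corpus-wide statistics needed for tf-idf weighting: the collection size
#' `N` and, for every term, the document frequency `D` (number of extracts
#' containing the term). These statistics are computed once here and frozen;
#' documents classified later never update them.
#'
#' @param extracts A data frame with columns `text` (non-empty character) and
#'   `criterion` (one of [hon_criteria()]); an optional `source_url` column is
#'   carried along.
#' @param stem Stem tokens with the Porter algorithm before counting?
#' @param stopwords Optional character vector of tokens to drop.
#' @return An object of class `hon_corpus`: a list with `extracts` (a tibble
#'   with a `tokens` list-column), `N`, `df` (named integer vector of document
#'   frequencies), and the tokenization settings.
#' @seealso [read_extracts()] to read a JSON-lines extract file.
#' @export
hon_corpus <- function(extracts, stem = FALSE, stopwords = NULL) {
  extracts <- as_tibble(extracts)
  if (!all(c("text", "criterion") %in% names(extracts))) {
    abort("`extracts` must have columns `text` and `criterion`.")
  }
  if (nrow(extracts) == 0) abort("Corpus must contain at least one extract.")
  if (!"source_url" %in% names(extracts)) extracts$source_url <- NA_character_
  txt <- trimws(extracts$text)
  if (any(is.na(txt) | !nzchar(txt))) {
    abort(sprintf(
      "Extract text must be non-empty after whitespace trimming (record %d).",
      which(is.na(txt) | !nzchar(txt))[1]
    ))
  }
  check_criterion(unique(extracts$criterion))

  extracts$tokens <- lapply(extracts$text, tokenize, stem = stem, stopwords = stopwords)
  df_tab <- table(unlist(lapply(extracts$tokens, unique)))
  df <- setNames(as.integer(df_tab), names(df_tab))

  structure(
    list(
      extracts = extracts[c("text", "criterion", "source_url", "tokens")],
      N = nrow(extracts),
      df = df,
      stem = stem,
      stopwords = stopwords
    ),
    class = "hon_corpus"
  )
}

#' @export
print.hon_corpus <- function(x, ...) {
  cat(sprintf(
    "<hon_corpus> %d extracts, %d terms (stem = %s)\n",
    x$N, length(x$df), x$stem
  ))
  print(table(x$extracts$criterion))
  invisible(x)
}

#' Read labelled training extracts from a JSON-lines file
#'
#' Each line is a JSON object with fields `text`, `criterion` and optionally
#' `source_url`. Criterion labels outside the nine-member set are rejected
#' (in particular the unsplit label `attribution`).
#'
#' @param path Path to a JSONL file.
#' @inheritParams hon_corpus
#' @return An `hon_corpus`; see [hon_corpus()].
#' @export
read_extracts <- function(path, stem = FALSE, stopwords = NULL) {
  if (!file.exists(path)) abort(sprintf("Extract file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("Extract file is empty: %s", path))
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i]),
      error = function(e) {
        abort(sprintf("Malformed extract record at line %d of %s: %s",
                      i, path, conditionMessage(e)))
      }
    )
    if (is.null(rec$text) || is.null(rec$criterion)) {
      abort(sprintf("Extract record at line %d of %s lacks `text` or `criterion`.", i, path))
    }
    tibble(
      text = as.character(rec$text),
      criterion = as.character(rec$criterion),
      source_url = if (is.null(rec$source_url)) NA_character_ else as.character(rec$source_url)
    )
  })
  hon_corpus(dplyr::bind_rows(recs), stem = stem, stopwords = stopwords)
}

#' Write labelled extracts to a JSON-lines file
#'
#' @param extracts A data frame with columns `text`, `criterion` and
#'   optionally `source_url`, or an `hon_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extracts <- function(extracts, path) {
  if (inherits(extracts, "hon_corpus")) extracts <- extracts$extracts
  extracts <- as_tibble(extracts)
  lines <- vapply(seq_len(nrow(extracts)), function(i) {
    rec <- list(text = extracts$text[i], criterion = extracts$criterion[i])
    if ("source_url" %in% names(extracts) && !is.na(extracts$source_url[i])) {
      rec$source_url <- extracts$source_url[i]
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read gold manual assessments
#'
#' Gold assessments record, per site and criterion, the expert verdict and
#' (for compliant verdicts) the page on which the justification was found.
#' The file is a CSV with columns `site_id, criterion, complies,
#' evidence_url`. Criteria missing for a site default to non-compliant with
#' a warning; a compliant verdict without an evidence URL is a validation
#' error.
#'
#' @param path CSV path.
#' @return A tibble with one row per site x criterion (all nine criteria per
#'   site), columns `site_id`, `criterion`, `complies`, `evidence_url`.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) abort(sprintf("Gold assessment file not found: %s", path))
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE, colClasses = "character"))
  need <- c("site_id", "criterion", "complies")
  if (!all(need %in% names(raw))) {
    abort(sprintf("Gold file must have columns %s.", paste(need, collapse = ", ")))
  }
  if (!"evidence_url" %in% names(raw)) raw$evidence_url <- NA_character_
  check_criterion(unique(raw$criterion))
  raw$complies <- tolower(raw$complies) %in% c("true", "t", "1", "yes")
  raw$evidence_url[!nzchar(trimws(ifelse(is.na(raw$evidence_url), "", raw$evidence_url)))] <- NA_character_
  bad <- raw$complies & is.na(raw$evidence_url)
  if (any(bad)) {
    abort(sprintf(
      "Gold verdict complies=true without evidence_url for site %s, criterion %s.",
      raw$site_id[bad][1], raw$criterion[bad][1]
    ))
  }
  full <- tidyr::expand_grid(
    site_id = unique(raw$site_id),
    criterion = hon_criteria()
  )
  out <- dplyr::left_join(full, raw, by = c("site_id", "criterion"))
  missing <- is.na(out$complies)
  if (any(missing)) {
    warn(sprintf(
      "%d site x criterion rows missing from gold file; defaulting to complies = FALSE.",
      sum(missing)
    ))
    out$complies[missing] <- FALSE
  }
  out
}

#' Write gold manual assessments
#'
#' @param gold A tibble as returned by [read_gold()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  gold <- as_tibble(gold)[, c("site_id", "criterion", "complies", "evidence_url")]
  write.csv(gold, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write automated site-assessment reports
#'
#' Reports are CSVs with the fixed header `site_id, criterion, complies,
#' evidence`. The `evidence` field holds every positive detection location,
#' `|`-separated; sentence-level evidence is encoded as `url#s<index>` with a
#' 0-based sentence index. Reports round-trip through
#' [read_assessment_report()] without loss.
#'
#' @param assessments A report tibble (columns `site_id, criterion, complies,
#'   evidence`), an `hon_assessment`, or a list of `hon_assessment`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assessment_report <- function(assessments, path) {
  tbl <- as_report(assessments)
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("Cannot write report to %s: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  write.csv(tbl, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_assessment_report
#' @export
as_report <- function(assessments) {
  if (inherits(assessments, "hon_assessment")) assessments <- list(assessments)
  if (is.list(assessments) && length(assessments) > 0 &&
      all(vapply(assessments, inherits, logical(1), "hon_assessment"))) {
    assessments <- dplyr::bind_rows(lapply(assessments, assessment_rows))
  }
  tbl <- as_tibble(assessments)
  if (nrow(tbl) == 0) {
    tbl <- tibble(site_id = character(), criterion = character(),
                  complies = logical(), evidence = character())
  }
  tbl[, c("site_id", "criterion", "complies", "evidence")]
}

assessment_rows <- function(a) {
  ev <- a$detections
  ev$loc <- ifelse(
    is.na(ev$sentence_index),
    ev$page_url,
    paste0(ev$page_url, "#s", ev$sentence_index)
  )
  ev_by_crit <- vapply(
    split(ev$loc, factor(ev$criterion, levels = hon_criteria())),
    paste, character(1), collapse = "|"
  )
  tibble(
    site_id = a$site_id,
    criterion = hon_criteria(),
    complies = a$verdicts$complies[match(hon_criteria(), a$verdicts$criterion)],
    evidence = ifelse(nzchar(ev_by_crit), ev_by_crit, NA_character_)
  )
}

#' Read an automated assessment report
#'
#' @param path CSV path written by [write_assessment_report()].
#' @return A report tibble with columns `site_id, criterion, complies,
#'   evidence`.
#' @export
read_assessment_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("Assessment report not found: %s", path))
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE, colClasses = "character"))
  need <- c("site_id", "criterion", "complies", "evidence")
  if (!all(need %in% names(raw))) {
    abort(sprintf("Report must have columns %s.", paste(need, collapse = ", ")))
  }
  if (nrow(raw) > 0) check_criterion(unique(raw$criterion))
  raw$complies <- tolower(raw$complies) %in% c("true", "t", "1", "yes")
  raw$evidence[!nzchar(ifelse(is.na(raw$evidence), "", raw$evidence))] <- NA_character_
  raw[, need]
}

# Split a serialized evidence field into page URLs and sentence indices.
parse_evidence <- function(evidence) {
  if (is.na(evidence)) {
    return(tibble(page_url = character(), sentence_index = integer()))
  }
  locs <- strsplit(evidence, "|", fixed = TRUE)[[1]]
  has_s <- grepl("#s[0-9]+$", locs)
  idx <- rep(NA_integer_, length(locs))
  idx[has_s] <- as.integer(sub("^.*#s", "", locs[has_s]))
  tibble(
    page_url = sub("#s[0-9]+$", "", locs),
    sentence_index = idx
  )
}

#' Normalize a URL or page path for joining
#'
#' Sites are identified by normalized root URL: lowercased scheme and host,
#' fragment stripped, no trailing slash. Relative page paths have `./` and
#' `..` segments collapsed, so that the same page reached through different
#' link spellings compares equal.
#'
#' @param url Character vector of URLs or relative paths.
#' @return Normalized character vector.
#' @export
normalize_url <- function(url) {
  vapply(url, function(u) {
    if (is.na(u)) return(NA_character_)
    u <- sub("#.*$", "", u)
    if (grepl("^[a-zA-Z][a-zA-Z0-9+.-]*://", u)) {
      m <- regmatches(u, regexec("^([a-zA-Z][a-zA-Z0-9+.-]*)://([^/]*)(.*)$", u))[[1]]
      u <- paste0(tolower(m[2]), "://", tolower(m[3]), m[4])
    } else {
      # collapse relative path segments
      parts <- strsplit(u, "/", fixed = TRUE)[[1]]
      out <- character(0)
      for (p in parts) {
        if (p == "." || p == "") next
        if (p == "..") out <- out[-length(out)] else out <- c(out, p)
      }
      u <- paste(out, collapse = "/")
    }
    sub("/+$", "", u)
  }, character(1), USE.NAMES = FALSE)
}
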