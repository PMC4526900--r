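#' Extract the meaningful text content of an HTML page
#'
#' Strips `script`, `style`, `noscript` and `head` elements and HTML
#' comments, then concatenates the remaining visible text (including `alt`
#' attributes of images) in document order with whitespace normalized.
#' Boilerplate such as navigation text is deliberately kept: telling signal
#' from boilerplate is the classifier's job, not the parser's.
#'
#' @param raw_html An HTML document as a single string (possibly malformed;
#'   parsed leniently).
#' @param page A label used in error messages (e.g. the page URL).
#' @return A single string of visible text; `""` for an empty document.
#' @export
extract_text <- function(raw_html, page = "<html string>") {
  if (is.na(raw_html) || !nzchar(trimws(raw_html))) return("")
  doc <- tryCatch(
    xml2::read_html(raw_html, options = c("RECOVER", "NOERROR", "NOBLANKS")),
    error = function(e) {
      abort(sprintf("Cannot parse/decode HTML for %s: %s", page, conditionMessage(e)))
    }
  )
  drop <- xml2::xml_find_all(doc, "//script | //style | //noscript | //head | //comment()")
  xml2::xml_remove(drop)
  nodes <- xml2::xml_find_all(doc, "//text()[normalize-space()] | //img/@alt")
  txt <- vapply(nodes, xml2::xml_text, character(1))
  stringr::str_squish(paste(txt, collapse = " "))
}

#' Split plain text into sentences
#'
#' Rule-based splitter: a sentence boundary is a run of `.`, `!` or `?`
#' followed by whitespace and an uppercase letter or digit. A trailing span
#' without terminal punctuation counts as one sentence. Joining the returned
#' sentences with single spaces reproduces the whitespace-normalized input.
#'
#' @param text A single string.
#' @return Character vector of sentences (empty for blank input).
#' @export
split_sentences <- function(text) {
  text <- stringr::str_squish(text)
  if (!nzchar(text)) return(character(0))
  sents <- stringr::str_split(text, "(?<=[.!?])\\s+(?=[A-Z0-9])")[[1]]
  sents <- stringr::str_squish(sents)
  sents[nzchar(sents)]
}

#' Tokenize text into lowercase alphabetic tokens
#'
#' Tokens are maximal runs of Unicode letters; digits and punctuation act as
#' token separators and never enter a token. Purely numeric spans (e.g. a
#' bare date "07/07/2012") therefore produce no tokens at all — a documented
#' blind spot for dating statements written without words. Optionally applies
#' the Porter stemmer and a stop-word filter (both off by default).
#'
#' @param text A single string.
#' @param stem Apply the English Porter stemmer?
#' @param stopwords Optional character vector of (lowercase) tokens to drop,
#'   matched before stemming.
#' @return Character vector of tokens, in text order.
#' @export
tokenize <- function(text, stem = FALSE, stopwords = NULL) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- stringr::str_extract_all(stringr::str_to_lower(text), "\\p{L}+")[[1]]
  if (!is.null(stopwords)) toks <- toks[!toks %in% stopwords]
  if (stem) toks <- porter_stem(toks)
  toks
}

#' Porter stemmer (English, 1980 algorithm)
#'
#' Reduces inflected English words to stems ("policies" -> "polici",
#' "relational" -> "relat"). Implements the original five-step algorithm;
#' words of length two or less are returned unchanged.
#'
#' @param words Character vector of lowercase words.
#' @return Character vector of stems.
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

# --- Porter internals ------------------------------------------------------
# A letter is a consonant unless it is a,e,i,o,u, or a 'y' preceded by a
# consonant. The measure m counts VC sequences in the [C](VC)^m[V] form.

porter_types <- function(w) {
  chars <- strsplit(w, "", fixed = TRUE)[[1]]
  n <- length(chars)
  types <- character(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      types[i] <- "v"
    } else if (ch == "y") {
      types[i] <- if (i > 1 && types[i - 1] == "c") "v" else "c"
    } else {
      types[i] <- "c"
    }
  }
  types
}

porter_m <- function(w) {
  if (!nzchar(w)) return(0L)
  pat <- paste(porter_types(w), collapse = "")
  pat <- gsub("c+", "C", gsub("v+", "V", pat))
  lengths(regmatches(pat, gregexpr("VC", pat, fixed = TRUE)))
}

porter_has_vowel <- function(w) nzchar(w) && "v" %in% porter_types(w)

porter_double_c <- function(w) {
  n <- nchar(w)
  n >= 2 &&
    substr(w, n, n) == substr(w, n - 1, n - 1) &&
    porter_types(w)[n] == "c"
}

# *o: stem ends cvc where the final consonant is not w, x or y.
porter_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3) return(FALSE)
  t <- porter_types(w)
  t[n - 2] == "c" && t[n - 1] == "v" && t[n] == "c" &&
    !substr(w, n, n) %in% c("w", "x", "y")
}

ends_with <- function(w, s) {
  nchar(w) > nchar(s) && substring(w, nchar(w) - nchar(s) + 1) == s
}

chop <- function(w, s) substr(w, 1, nchar(w) - nchar(s))

# Apply the first (longest-suffix) matching rule of a step-2/3/4 style table:
# the longest listed suffix that matches decides; the replacement happens
# only if the measure condition holds on the remaining stem.
porter_rule_table <- function(w, rules, cond) {
  sufs <- names(rules)
  sufs <- sufs[order(-nchar(sufs))]
  for (s in sufs) {
    if (ends_with(w, s)) {
      stem <- chop(w, s)
      if (cond(stem, w)) w <- paste0(stem, rules[[s]])
      return(w)
    }
  }
  w
}

porter_stem1 <- function(w) {
  if (nchar(w) <= 2) return(w)

  # Step 1a
  if (ends_with(w, "sses")) {
    w <- paste0(chop(w, "sses"), "ss")
  } else if (ends_with(w, "ies")) {
    w <- paste0(chop(w, "ies"), "i")
  } else if (!ends_with(w, "ss") && ends_with(w, "s")) {
    w <- chop(w, "s")
  }

  # Step 1b
  step1b2 <- FALSE
  if (ends_with(w, "eed")) {
    if (porter_m(chop(w, "eed")) > 0) w <- chop(w, "d")
  } else if (ends_with(w, "ed") && porter_has_vowel(chop(w, "ed"))) {
    w <- chop(w, "ed"); step1b2 <- TRUE
  } else if (ends_with(w, "ing") && porter_has_vowel(chop(w, "ing"))) {
    w <- chop(w, "ing"); step1b2 <- TRUE
  }
  if (step1b2) {
    if (ends_with(w, "at") || ends_with(w, "bl") || ends_with(w, "iz")) {
      w <- paste0(w, "e")
    } else if (porter_double_c(w) && !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- substr(w, 1, nchar(w) - 1)
    } else if (porter_m(w) == 1 && porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # Step 1c
  if (ends_with(w, "y") && porter_has_vowel(chop(w, "y"))) {
    w <- paste0(chop(w, "y"), "i")
  }

  # Step 2 (condition m(stem) > 0)
  w <- porter_rule_table(w, list(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  ), function(stem, w) porter_m(stem) > 0)

  # Step 3 (condition m(stem) > 0)
  w <- porter_rule_table(w, list(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  ), function(stem, w) porter_m(stem) > 0)

  # Step 4 (condition m(stem) > 1; ion additionally needs stem ending s/t)
  w <- porter_rule_table(w, list(
    al = "", ance = "", ence = "", er = "", ic = "", able = "", ible = "",
    ant = "", ement = "", ment = "", ent = "", ion = "", ou = "", ism = "",
    ate = "", iti = "", ous = "", ive = "", ize = ""
  ), function(stem, w) {
    suf <- substring(w, nchar(stem) + 1)
    if (suf == "ion") {
      return(porter_m(stem) > 1 && nzchar(stem) &&
               substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t"))
    }
    porter_m(stem) > 1
  })

  # Step 5a
  if (ends_with(w, "e")) {
    stem <- chop(w, "e")
    m <- porter_m(stem)
    if (m > 1 || (m == 1 && !porter_cvc(stem))) w <- stem
  }

  # Step 5b
  if (porter_m(w) > 1 && porter_double_c(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    w <- substr(w, 1, nchar(w) - 1)
  }

  w
}
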