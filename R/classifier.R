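#' Train a binary naive Bayes detector for one criterion
#'
#' One-vs-rest training over the labelled extract corpus: the positive class
#' is every extract labelled with `criterion`, the negative class every
#' extract labelled with another criterion (the only labelled text the
#' certification workflow produces). Likelihoods are multinomial with
#' fractional "counts": each document contributes its tf-idf feature weights
#' under the chosen scheme, smoothed additively with `alpha` over the
#' training vocabulary.
#'
#' @param corpus An [hon_corpus()].
#' @param criterion One of [hon_criteria()].
#' @param scheme Term-weighting scheme, `"tfc"` or `"tfx"`.
#' @param alpha Additive smoothing constant, default 0.01. Kept small
#'   relative to the fractional tf-idf "counts": a cosine-normalized document
#'   carries total feature mass of order 1, and a smoothing constant that
#'   dwarfs it washes the per-term class evidence out of the likelihoods.
#' @param threshold Posterior decision threshold in (0, 1); a document is
#'   declared compliant only if its posterior strictly exceeds it, so a tie
#'   at the threshold is negative (specificity over sensitivity).
#' @return An object of class `hon_classifier`.
#' @export
train_classifier <- function(corpus, criterion, scheme = c("tfc", "tfx"),
                             alpha = 0.01, threshold = 0.5) {
  scheme <- match.arg(scheme)
  check_criterion(criterion)
  vecs <- corpus_vectors(corpus, scheme)
  build_classifier(corpus, vecs, criterion, scheme, alpha, threshold)
}

# tf-idf vectors of all training extracts, computed once per scheme.
corpus_vectors <- function(corpus, scheme) {
  lapply(corpus$extracts$tokens, vectorize, corpus = corpus, scheme = scheme)
}

build_classifier <- function(corpus, vecs, criterion, scheme, alpha, threshold) {
  stopifnot(alpha > 0, threshold > 0, threshold < 1)
  labels <- corpus$extracts$criterion
  pos <- labels == criterion
  if (!any(pos)) {
    abort(sprintf("No positive training extracts for criterion '%s'.", criterion))
  }
  if (all(pos)) {
    abort(sprintf(
      "No negative training extracts for criterion '%s' (corpus has no other criteria).",
      criterion
    ))
  }
  vocab <- sort(names(corpus$df))
  sum_class <- function(idx) {
    acc <- setNames(numeric(length(vocab)), vocab)
    for (v in vecs[idx]) {
      if (length(v) > 0) acc[names(v)] <- acc[names(v)] + as.numeric(v)
    }
    acc
  }
  w_pos <- sum_class(which(pos))
  w_neg <- sum_class(which(!pos))
  log_lik <- rbind(
    positive = log(alpha + w_pos) - log(alpha * length(vocab) + sum(w_pos)),
    negative = log(alpha + w_neg) - log(alpha * length(vocab) + sum(w_neg))
  )
  structure(
    list(
      criterion = criterion,
      scheme = scheme,
      alpha = alpha,
      threshold = threshold,
      priors = c(positive = mean(pos), negative = mean(!pos)),
      log_lik = log_lik,
      vocab = vocab
    ),
    class = "hon_classifier"
  )
}

#' @export
print.hon_classifier <- function(x, ...) {
  cat(sprintf(
    "<hon_classifier> %s (%s, alpha = %g, threshold = %g, prior+ = %.3f, %d terms)\n",
    x$criterion, x$scheme, x$alpha, x$threshold, x$priors[["positive"]],
    length(x$vocab)
  ))
  invisible(x)
}

#' Posterior compliance probability for a feature vector
#'
#' Naive Bayes posterior over the weighted feature values:
#' `log P(class | v) ~ log prior + sum_t v_t log theta_{class,t}`, converted
#' to a posterior probability over \{positive, negative\}. An empty (zero)
#' vector yields the class prior. The decision is positive only when the
#' posterior strictly exceeds the classifier's threshold.
#'
#' @param object An `hon_classifier`.
#' @param vector An `hon_vector` built with [vectorize()] under the same
#'   scheme and corpus statistics (a scheme mismatch is an error).
#' @param ... Unused.
#' @return A one-row tibble with columns `criterion`, `posterior`, `decision`.
#' @export
predict.hon_classifier <- function(object, vector, ...) {
  posterior <- nb_posterior(object, vector)
  tibble(
    criterion = object$criterion,
    posterior = posterior,
    decision = posterior > object$threshold
  )
}

# Scalar posterior; the hot path shared by predict() and classify_text().
nb_posterior <- function(clf, vector) {
  vscheme <- attr(vector, "scheme")
  if (!is.null(vscheme) && !identical(vscheme, clf$scheme)) {
    abort(sprintf(
      "Feature vector was built under scheme '%s' but classifier '%s' uses '%s'.",
      vscheme, clf$criterion, clf$scheme
    ))
  }
  terms <- intersect(names(vector), clf$vocab)
  w <- as.numeric(vector[terms])
  log_pos <- log(clf$priors[["positive"]]) +
    sum(w * clf$log_lik["positive", terms])
  log_neg <- log(clf$priors[["negative"]]) +
    sum(w * clf$log_lik["negative", terms])
  1 / (1 + exp(log_neg - log_pos))
}

#' Train the full nine-criterion any-of detector
#'
#' Builds one binary naive Bayes classifier per criterion (see
#' [train_classifier()]); the nine classifiers share the corpus statistics
#' and are applied independently, so one text span may satisfy several
#' criteria at once ("any-of" multi-label classification).
#'
#' @inheritParams train_classifier
#' @param criteria Criteria to train; default all nine.
#' @return An object of class `hon_detector`.
#' @export
train_detector <- function(corpus, scheme = c("tfc", "tfx"), alpha = 0.01,
                           threshold = 0.5, criteria = hon_criteria()) {
  scheme <- match.arg(scheme)
  check_criterion(criteria)
  vecs <- corpus_vectors(corpus, scheme)
  classifiers <- lapply(criteria, function(cr) {
    build_classifier(corpus, vecs, cr, scheme, alpha, threshold)
  })
  names(classifiers) <- criteria
  structure(
    list(
      classifiers = classifiers,
      N = corpus$N,
      df = corpus$df,
      stem = corpus$stem,
      stopwords = corpus$stopwords,
      scheme = scheme,
      alpha = alpha,
      threshold = threshold
    ),
    class = "hon_detector"
  )
}

#' @export
print.hon_detector <- function(x, ...) {
  cat(sprintf(
    "<hon_detector> %d classifiers (%s, alpha = %g, threshold = %g), N = %d, %d terms\n",
    length(x$classifiers), x$scheme, x$alpha, x$threshold, x$N, length(x$df)
  ))
  invisible(x)
}

#' Classify one text span against all trained criteria
#'
#' With `unit = "document"` the whole text is scored once per criterion. With
#' `unit = "sentence"` each sentence is scored separately and a criterion is
#' detected if any sentence passes; the reported evidence is the first
#' passing sentence (0-based index) with its posterior.
#'
#' @param text Plain text of a page (see [extract_text()]).
#' @param detector An [train_detector()] result.
#' @param unit Classification unit, `"document"` or `"sentence"`.
#' @param page_url Optional page URL recorded on each detection.
#' @return A tibble of detections with columns `criterion`, `page_url`,
#'   `sentence_index` (`NA` for document unit), `posterior`. Zero rows if
#'   nothing is detected.
#' @export
classify_text <- function(text, detector, unit = c("document", "sentence"),
                          page_url = NA_character_) {
  unit <- match.arg(unit)
  empty <- tibble(
    criterion = character(), page_url = character(),
    sentence_index = integer(), posterior = double()
  )
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  spans <- if (unit == "document") text else split_sentences(text)
  if (length(spans) == 0) return(empty)
  vecs <- lapply(spans, function(s) {
    vectorize(tokenize(s, stem = detector$stem, stopwords = detector$stopwords),
              detector, scheme = detector$scheme)
  })

  # All classifiers share one vocabulary; score every span against all
  # criteria in one matrix product per span.
  clfs <- detector$classifiers
  vocab <- clfs[[1]]$vocab
  lr <- vapply(clfs, function(clf) {
    clf$log_lik["positive", ] - clf$log_lik["negative", ]
  }, numeric(length(vocab)))
  prior_off <- vapply(clfs, function(clf) {
    log(clf$priors[["positive"]]) - log(clf$priors[["negative"]])
  }, numeric(1))
  logodds <- t(vapply(vecs, function(v) {
    idx <- match(names(v), vocab)
    keep <- !is.na(idx)
    if (!any(keep)) return(prior_off)
    prior_off + as.numeric(crossprod(lr[idx[keep], , drop = FALSE],
                                     as.numeric(v)[keep]))
  }, numeric(length(clfs))))

  rows <- lapply(seq_along(clfs), function(k) {
    cut <- log(clfs[[k]]$threshold) - log(1 - clfs[[k]]$threshold)
    hit <- which(logodds[, k] > cut)
    if (length(hit) == 0) return(NULL)
    i <- hit[1]
    tibble(
      criterion = clfs[[k]]$criterion,
      page_url = page_url,
      sentence_index = if (unit == "sentence") i - 1L else NA_integer_,
      posterior = 1 / (1 + exp(-logodds[i, k]))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

#' Persist a trained detector as a single JSON model file
#'
#' The model bundles all trained classifiers together with the frozen corpus
#' statistics and configuration, so assessment runs need only the model file.
#'
#' @param detector An `hon_detector`.
#' @param path Output path for the JSON model.
#' @return `path`, invisibly.
#' @export
write_model <- function(detector, path) {
  payload <- list(
    format = "honcheck-model",
    version = 1L,
    scheme = detector$scheme,
    alpha = detector$alpha,
    threshold = detector$threshold,
    stem = detector$stem,
    stopwords = detector$stopwords,
    N = detector$N,
    df = as.list(detector$df),
    classifiers = lapply(detector$classifiers, function(clf) {
      list(
        criterion = clf$criterion,
        priors = as.list(clf$priors),
        vocab = clf$vocab,
        log_lik_positive = unname(clf$log_lik["positive", ]),
        log_lik_negative = unname(clf$log_lik["negative", ])
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a JSON model file back into a detector
#'
#' @param path Path written by [write_model()].
#' @return An `hon_detector`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("Model file not found: %s", path))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(m$format, "honcheck-model")) {
    abort(sprintf("%s is not a honcheck model file.", path))
  }
  classifiers <- lapply(m$classifiers, function(c0) {
    structure(
      list(
        criterion = c0$criterion,
        scheme = m$scheme,
        alpha = m$alpha,
        threshold = m$threshold,
        priors = c(positive = c0$priors$positive, negative = c0$priors$negative),
        log_lik = rbind(
          positive = setNames(c0$log_lik_positive, c0$vocab),
          negative = setNames(c0$log_lik_negative, c0$vocab)
        ),
        vocab = c0$vocab
      ),
      class = "hon_classifier"
    )
  })
  names(classifiers) <- vapply(classifiers, `[[`, character(1), "criterion")
  structure(
    list(
      classifiers = classifiers,
      N = as.integer(m$N),
      df = unlist(m$df),
      stem = isTRUE(m$stem),
      stopwords = if (length(m$stopwords) == 0) NULL else m$stopwords,
      scheme = m$scheme,
      alpha = m$alpha,
      threshold = m$threshold
    ),
    class = "hon_detector"
  )
}

#' @rdname train_detector
#' @param x An `hon_detector`.
#' @param n_terms Number of top terms per criterion in the tidy output.
#' @param ... Unused.
#' @details `tidy()` returns, per criterion, the `n_terms` vocabulary terms
#'   with the largest positive-vs-negative log-likelihood ratio (the terms
#'   the detector considers most indicative of compliance). `glance()`
#'   returns a one-row training summary.
#' @method tidy hon_detector
#' @export
tidy.hon_detector <- function(x, n_terms = 10, ...) {
  dplyr::bind_rows(lapply(x$classifiers, function(clf) {
    lr <- clf$log_lik["positive", ] - clf$log_lik["negative", ]
    top <- head(order(lr, decreasing = TRUE), n_terms)
    tibble(
      criterion = clf$criterion,
      term = clf$vocab[top],
      log_odds = unname(lr[top]),
      rank = seq_along(top)
    )
  }))
}

#' @rdname train_detector
#' @method glance hon_detector
#' @export
glance.hon_detector <- function(x, ...) {
  tibble(
    n_criteria = length(x$classifiers),
    n_train = x$N,
    vocab_size = length(x$df),
    scheme = x$scheme,
    alpha = x$alpha,
    threshold = x$threshold,
    stem = x$stem
  )
}
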