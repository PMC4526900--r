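#' Inverse document frequency
#'
#' `idf(N, D) = ln(N / D)`: terms found in few training documents score high,
#' ubiquitous terms score zero. Natural logarithm; the base rescales
#' unnormalized (tfx) weights uniformly and leaves cosine-normalized (tfc)
#' vectors unchanged, so only tfx magnitudes depend on it.
#'
#' @param n Total number of documents in the training collection (N >= 1).
#' @param d Number of training documents containing the term (1 <= D <= N).
#' @return `log(n / d)`, vectorized over `d`.
#' @examples
#' idf(100, 10) # log(10)
#' @export
idf <- function(n, d) {
  if (any(n < 1)) abort("Collection size N must be >= 1.")
  if (any(d < 1) || any(d > n)) {
    abort("Document frequency D must satisfy 1 <= D <= N.")
  }
  log(n / d)
}

#' Convert a token sequence into a weighted sparse feature vector
#'
#' Implements the `tfc` and `tfx` term-weighting schemes: raw term frequency
#' times inverse document frequency (`tfx`), optionally cosine-normalized to
#' unit Euclidean length (`tfc`). Terms unseen in the training collection are
#' dropped before normalization; a document consisting only of unseen terms
#' yields an empty (zero) vector flagged with `attr(v, "all_unseen")`.
#'
#' @param tokens Character vector of tokens (see [tokenize()]).
#' @param corpus An `hon_corpus` (or any list with elements `N` and `df`)
#'   supplying the frozen training statistics.
#' @param scheme `"tfc"` (cosine-normalized) or `"tfx"` (raw tf-idf).
#' @return A named numeric vector of positive weights with attributes
#'   `scheme` and `all_unseen`; class `hon_vector`.
#' @export
vectorize <- function(tokens, corpus, scheme = c("tfc", "tfx")) {
  scheme <- match.arg(scheme)
  known <- tokens[tokens %in% names(corpus$df)]
  all_unseen <- length(known) == 0 && length(tokens) > 0
  if (length(known) == 0) {
    w <- numeric(0)
  } else {
    tf <- table(known)
    terms <- names(tf)
    w <- as.numeric(tf) * idf(corpus$N, as.numeric(corpus$df[terms]))
    names(w) <- terms
    w <- w[w > 0]
    if (scheme == "tfc" && length(w) > 0) {
      w <- w / sqrt(sum(w^2))
    }
  }
  structure(w, scheme = scheme, all_unseen = all_unseen, class = "hon_vector")
}
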