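# Shared fixture builders. Everything is generated in code; no binary data.

# A tiny hand-written corpus with two clearly separated criteria.
tiny_corpus <- function(stem = FALSE) {
  hon_corpus(tibble::tibble(
    text = c(
      "privacy statement protects visitor data",
      "our privacy policy covers cookies",
      "cited sources listed below",
      "references cite medical journals"
    ),
    criterion = c("privacy", "privacy", "reference", "reference")
  ), stem = stem)
}

# Corpus over a 5-word vocabulary for oracle comparisons.
micro_corpus <- function(texts, labels) {
  hon_corpus(tibble::tibble(text = texts, criterion = labels))
}

# Write a small offline site: named list page -> list(body, links).
write_site <- function(dir, pages) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(pages)) {
    p <- pages[[nm]]
    links <- if (is.null(p$links)) character(0) else p$links
    html <- c(
      "<html><head><title>t</title></head><body>",
      sprintf("<p>%s</p>", p$body),
      sprintf('<a href="%s">link</a>', links),
      "</body></html>"
    )
    writeLines(html, file.path(dir, nm))
  }
  dir
}

# A detector trained on the tiny corpus (privacy + reference only).
tiny_detector <- function(scheme = "tfc", ...) {
  train_detector(tiny_corpus(), scheme = scheme,
                 criteria = c("privacy", "reference"), ...)
}

expect_tibble_equal <- function(a, b) {
  testthat::expect_equal(as.data.frame(a), as.data.frame(b))
}

# Brute-force Bayes oracle for tiny vocabularies: direct probability
# products, statistics recomputed from scratch with plain loops. Kept fully
# independent of the package's vectorize()/predict() path.
oracle_posterior <- function(texts, labels, criterion, new_text,
                             scheme, alpha) {
  docs <- strsplit(texts, " ", fixed = TRUE)
  n <- length(docs)
  vocab <- sort(unique(unlist(docs)))
  df <- sapply(vocab, function(t) sum(sapply(docs, function(d) t %in% d)))
  weigh <- function(toks) {
    toks <- toks[toks %in% vocab]
    w <- sapply(vocab, function(t) {
      tf <- sum(toks == t)
      tf * log(n / df[[t]])
    })
    if (scheme == "tfc" && sqrt(sum(w^2)) > 0) w <- w / sqrt(sum(w^2))
    w
  }
  W <- t(sapply(docs, weigh))
  pos <- labels == criterion
  theta <- function(rows) {
    s <- colSums(W[rows, , drop = FALSE])
    (alpha + s) / (alpha * length(vocab) + sum(s))
  }
  th_pos <- theta(which(pos))
  th_neg <- theta(which(!pos))
  prior_pos <- mean(pos)
  w_new <- weigh(strsplit(new_text, " ", fixed = TRUE)[[1]])
  num <- prior_pos * prod(th_pos^w_new)
  den <- num + (1 - prior_pos) * prod(th_neg^w_new)
  num / den
}

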