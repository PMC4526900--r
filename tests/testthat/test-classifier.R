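test_that("training separates criterion vocabulary and estimates priors", {
  corpus <- micro_corpus(
    c("privacy statement", "cited sources"),
    c("privacy", "reference")
  )
  clf <- train_classifier(corpus, "privacy", scheme = "tfx", alpha = 1)
  expect_gt(clf$log_lik["positive", "privacy"], clf$log_lik["positive", "cited"])
  expect_equal(unname(clf$priors), c(0.5, 0.5))
  expect_equal(sum(exp(clf$log_lik["positive", ])), 1, tolerance = 1e-12)
  expect_equal(sum(exp(clf$log_lik["negative", ])), 1, tolerance = 1e-12)
})

test_that("training requires positive and negative extracts", {
  only_privacy <- micro_corpus(c("privacy one", "privacy two"),
                               c("privacy", "privacy"))
  expect_error(train_classifier(only_privacy, "authority"), "authority")
  expect_error(train_classifier(only_privacy, "privacy"), "negative")
})

test_that("posteriors match the brute-force Bayes oracle to 1e-9", {
  vocab <- c("aa", "bb", "cc", "dd", "ee")
  set.seed(13)
  for (trial in 1:30) {
    n_docs <- sample(4:6, 1)
    labels <- sample(c("privacy", "reference"), n_docs, replace = TRUE)
    labels[1:2] <- c("privacy", "reference")
    texts <- sapply(seq_len(n_docs), function(i) {
      paste(sample(vocab, sample(2:6, 1), replace = TRUE), collapse = " ")
    })
    scheme <- sample(c("tfc", "tfx"), 1)
    alpha <- sample(c(0.01, 0.5, 1), 1)
    corpus <- micro_corpus(texts, labels)
    clf <- train_classifier(corpus, "privacy", scheme = scheme, alpha = alpha)
    new_text <- paste(sample(vocab, 4, replace = TRUE), collapse = " ")
    vec <- vectorize(tokenize(new_text), corpus, scheme = scheme)
    got <- predict(clf, vec)$posterior
    want <- oracle_posterior(texts, labels, "privacy", new_text, scheme, alpha)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("terms seen only in positives raise the posterior above the prior", {
  corpus <- micro_corpus(
    c("aa bb", "aa cc", "dd ee", "dd bb"),
    c("privacy", "privacy", "reference", "reference")
  )
  clf <- train_classifier(corpus, "privacy", scheme = "tfx", alpha = 1)
  vec <- vectorize("aa", corpus, scheme = "tfx")
  expect_gt(predict(clf, vec)$posterior, clf$priors[["positive"]])
})

test_that("a zero vector yields the prior, and a threshold tie is negative", {
  corpus <- micro_corpus(c("aa bb", "cc dd"), c("privacy", "reference"))
  clf <- train_classifier(corpus, "privacy", scheme = "tfc", threshold = 0.5)
  vec <- vectorize(character(0), corpus, scheme = "tfc")
  p <- predict(clf, vec)
  expect_equal(p$posterior, 0.5) # balanced priors
  expect_false(p$decision)      # posterior == threshold is NOT a detection
})

test_that("a scheme mismatch between vector and classifier is an error", {
  corpus <- micro_corpus(c("aa bb", "cc dd"), c("privacy", "reference"))
  clf <- train_classifier(corpus, "privacy", scheme = "tfc")
  vec <- vectorize("aa", corpus, scheme = "tfx")
  expect_error(predict(clf, vec), "scheme")
})

test_that("any-of classification detects several criteria independently", {
  cfg <- generator_config(seed = 51, extracts_per_criterion = 20)
  det <- train_detector(generate_corpus(cfg), scheme = "tfc")
  both <- paste(c(cfg$vocab$privacy[1:5], cfg$vocab$contact_details[1:5]),
                collapse = " ")
  hits <- classify_text(both, det)
  expect_setequal(hits$criterion, c("privacy", "contact_details"))
  expect_true(all(is.na(hits$sentence_index)))

  expect_equal(nrow(classify_text("", det)), 0)
  expect_equal(nrow(classify_text("completely unrelated words", det)), 0)
})

test_that("sentence unit reports the first passing 0-based sentence index", {
  det <- tiny_detector()
  txt <- paste(
    "Nothing relevant here.",
    "Our privacy policy protects visitor data and cookies.",
    "Closing remarks follow."
  )
  hits <- classify_text(txt, det, unit = "sentence", page_url = "p.html")
  priv <- hits[hits$criterion == "privacy", ]
  expect_equal(nrow(priv), 1)
  expect_equal(priv$sentence_index, 1L)
  expect_equal(priv$page_url, "p.html")
})

test_that("removing one classifier never changes another's detections", {
  cfg <- generator_config(seed = 52, extracts_per_criterion = 20)
  corpus <- generate_corpus(cfg)
  full <- train_detector(corpus, scheme = "tfc")
  privacy_only <- train_detector(corpus, scheme = "tfc", criteria = "privacy")
  txt <- paste(cfg$vocab$privacy[1:6], collapse = " ")
  full_priv <- classify_text(txt, full)
  solo_priv <- classify_text(txt, privacy_only)
  expect_equal(nrow(solo_priv), 1)
  expect_tibble_equal(
    full_priv[full_priv$criterion == "privacy", ],
    solo_priv
  )
})

test_that("models survive a JSON round-trip", {
  det <- tiny_detector(scheme = "tfx", alpha = 0.5, threshold = 0.4)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(det, f)
  back <- read_model(f)
  expect_equal(back$scheme, "tfx")
  expect_equal(back$alpha, 0.5)
  expect_equal(back$df, det$df)
  txt <- "privacy policy and cited sources"
  expect_equal(classify_text(txt, back), classify_text(txt, det),
               tolerance = 1e-12)
  expect_error(read_model(withr::local_tempfile()), "not found")
})

test_that("tidy and glance summarize a detector", {
  det <- tiny_detector()
  td <- tidy(det, n_terms = 3)
  expect_equal(nrow(td), 6)
  privacy_vocab <- unique(unlist(
    tiny_corpus()$extracts$tokens[tiny_corpus()$extracts$criterion == "privacy"]
  ))
  expect_true(all(td$term[td$criterion == "privacy"] %in% privacy_vocab))
  g <- glance(det)
  expect_equal(g$n_criteria, 2)
  expect_equal(g$n_train, 4)
  expect_equal(g$scheme, "tfc")
})
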