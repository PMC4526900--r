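gold_row <- function(site, criterion, complies, url = NA_character_) {
  g <- tibble::tibble(
    site_id = site, criterion = hon_criteria(),
    complies = FALSE, evidence_url = NA_character_
  )
  g$complies[g$criterion == criterion] <- complies
  g$evidence_url[g$criterion == criterion] <- url
  g
}

auto_row <- function(site, criterion, complies, evidence = NA_character_) {
  a <- tibble::tibble(
    site_id = site, criterion = hon_criteria(),
    complies = FALSE, evidence = NA_character_
  )
  a$complies[a$criterion == criterion] <- complies
  a$evidence[a$criterion == criterion] <- evidence
  a
}

test_that("the five-outcome taxonomy follows the evidence-page rule", {
  g <- gold_row("s", "privacy", TRUE, "https://a/p1")
  expect_equal(compare_site(g, auto_row("s", "privacy", TRUE, "https://a/p1"),
                            "privacy"), "TP")
  expect_equal(compare_site(g, auto_row("s", "privacy", TRUE, "https://a/p2"),
                            "privacy"), "OTHER")
  expect_equal(compare_site(g, auto_row("s", "privacy", FALSE), "privacy"), "FN")
  g0 <- gold_row("s", "privacy", FALSE)
  expect_equal(compare_site(g0, auto_row("s", "privacy", TRUE, "https://a/p2"),
                            "privacy"), "FP")
  expect_equal(compare_site(g0, auto_row("s", "privacy", FALSE), "privacy"), "TN")
})

test_that("TP takes precedence over OTHER and URLs are normalized", {
  g <- gold_row("s", "privacy", TRUE, "https://A.com/p1")
  both <- auto_row("s", "privacy", TRUE, "https://a.com/p2|https://a.com/p1#s3")
  expect_equal(compare_site(g, both, "privacy"), "TP")
  expect_error(compare_site(g, auto_row("t", "privacy", TRUE, "x"), "privacy"),
               "mismatch")
})

test_that("tabulation reproduces the privacy/tfx confusion pattern", {
  outcomes <- tibble::tibble(
    site_id = sprintf("s%02d", 1:27),
    criterion = "privacy",
    outcome = c(rep("TP", 14), rep("TN", 3), rep("FN", 10))
  )
  rec <- tabulate_outcomes(outcomes, label = "tfx")
  expect_equal(rec$tp, 14)
  expect_equal(rec$tn, 3)
  expect_equal(rec$fn, 10)
  expect_equal(rec$fp, 0)
  expect_equal(rec$other, 0)
  expect_equal(rec$manual_pos, 24)
  expect_equal(rec$n_sites, 27)
  expect_equal(rec$arm, "tfx")
  published <- hon_study_counts("weighting")
  expect_tibble_equal(
    rec[, c("criterion", "arm", "tn", "tp", "fn", "fp", "other")],
    published[published$criterion == "privacy" & published$arm == "tfx",
              c("criterion", "arm", "tn", "tp", "fn", "fp", "other")]
  )

  empty <- tabulate_outcomes(tibble::tibble(site_id = character(),
                                            criterion = character(),
                                            outcome = character()))
  expect_equal(nrow(empty), 0)
})

test_that("precision and recall follow the other-tolerant convention", {
  authority_tfc <- tibble::tibble(tp = 1, fp = 2, other = 10, fn = 10, tn = 4,
                                  manual_pos = 21)
  m <- precision_recall(authority_tfc)
  expect_equal(m$precision, 11 / 13)
  expect_equal(m$recall, 11 / 21)
  expect_equal(m$precision_label, "0.85 (11/13)")
  expect_equal(m$recall_label, "0.52 (11/21)")

  privacy_tfx <- tibble::tibble(tp = 14, fp = 0, other = 0, fn = 10, tn = 3,
                                manual_pos = 24)
  m2 <- precision_recall(privacy_tfx)
  expect_equal(m2$precision, 1)
  expect_equal(m2$recall, 14 / 24)
  expect_equal(m2$recall_label, "0.58 (14/24)")

  zeros <- tibble::tibble(tp = 0, fp = 0, other = 0, fn = 0, tn = 0,
                          manual_pos = 0)
  m3 <- precision_recall(zeros)
  expect_equal(m3$precision, 0)
  expect_equal(m3$recall, 0)
  expect_equal(m3$precision_label, "0.00 (0/0)")
})

test_that("published study counts are internally consistent", {
  for (tbl in c("weighting", "unit")) {
    counts <- hon_study_counts(tbl)
    expect_equal(counts$n_sites, rep(27, nrow(counts)))
    expect_equal(counts$manual_pos, counts$tp + counts$fn + counts$other)
  }
  expect_equal(nrow(hon_study_counts("weighting")), 18)
})

# Exhaustive pair-counting oracle for percent agreement.
pair_agreement_oracle <- function(m) {
  agree <- 0; total <- 0
  for (i in seq_len(nrow(m))) {
    for (a in seq_len(ncol(m) - 1)) {
      for (b in (a + 1):ncol(m)) {
        total <- total + 1
        if (m[i, a] == m[i, b]) agree <- agree + 1
      }
    }
  }
  agree / total
}

test_that("percent agreement counts agreeing rater pairs", {
  unanimous <- matrix(1, nrow = 36, ncol = 3)
  expect_equal(percent_agreement(unanimous), 1)

  split21 <- matrix(c(1, 1, 0), nrow = 36, ncol = 3, byrow = TRUE)
  expect_equal(percent_agreement(split21), 1 / 3)

  mixed <- rbind(matrix(1, 28, 3), matrix(c(1, 1, 0), 8, 3, byrow = TRUE))
  expect_equal(percent_agreement(mixed), 92 / 108)
  expect_equal(percent_agreement(mixed), pair_agreement_oracle(mixed))

  expect_error(percent_agreement(matrix(1, 5, 1)), "2 raters")
})

test_that("percent agreement ignores labels and rater order", {
  set.seed(5)
  m <- matrix(sample(c("yes", "no"), 60, replace = TRUE), ncol = 3)
  base <- percent_agreement(m)
  relabelled <- ifelse(m == "yes", "B", "A")
  expect_equal(percent_agreement(relabelled), base)
  expect_equal(percent_agreement(m[, c(3, 1, 2)]), base)
  expect_equal(base, pair_agreement_oracle(m))
})

test_that("Fleiss' kappa matches hand computations", {
  perfect <- matrix(c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                    nrow = 4, byrow = TRUE)
  expect_equal(as.numeric(fleiss_kappa(perfect)), 1)

  # 3 raters, 4 items, yes-counts (3,2,1,0): P_bar = 2/3, P_e = 1/2
  worked <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0), c(0, 0, 0))
  k <- fleiss_kappa(worked)
  expect_equal(as.numeric(k), 1 / 3)
  expect_equal(attr(k, "P_bar"), 2 / 3)
  expect_equal(attr(k, "P_e"), 1 / 2)

  degenerate <- matrix(1, nrow = 6, ncol = 3)
  expect_warning(kd <- fleiss_kappa(degenerate), "prevalence")
  expect_true(is.nan(as.numeric(kd)))
})

test_that("kappa never exceeds 1 and equals 1 only when unanimous", {
  set.seed(9)
  for (i in 1:30) {
    m <- matrix(sample(0:1, 12 * 3, replace = TRUE), ncol = 3)
    if (length(unique(as.vector(m))) < 2) next
    k <- as.numeric(fleiss_kappa(m))
    expect_lte(k, 1)
    unanimous <- all(apply(m, 1, function(r) length(unique(r)) == 1))
    expect_equal(isTRUE(all.equal(k, 1)), unanimous)
  }
})

test_that("kappa interpretation bands follow Landis-Koch", {
  expect_equal(kappa_interpretation(c(-0.113, 0.1, 0.3, 0.463, 0.745, 0.9)),
               c("poor", "slight", "fair", "moderate", "substantial",
                 "almost perfect"))
  expect_true(is.na(kappa_interpretation(NaN)))
})

test_that("agreement_summary reports percent scale and interpretation", {
  m <- rbind(matrix(1, 28, 3), matrix(c(1, 1, 0), 8, 3, byrow = TRUE))
  s <- agreement_summary(list(contact_details = m))
  expect_equal(s$criterion, "contact_details")
  expect_equal(s$percent_agreement, 100 * 92 / 108)
  expect_equal(s$interpretation, kappa_interpretation(s$kappa))
})
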