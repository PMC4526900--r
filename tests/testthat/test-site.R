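test_that("crawling follows internal links only and is cycle-safe", {
  dir <- withr::local_tempdir()
  write_site(dir, list(
    "index.html" = list(body = "Home page.",
                        links = c("a.html", "b.html", "https://external.example/x")),
    "a.html" = list(body = "Page a.", links = "index.html"),
    "b.html" = list(body = "Page b.")
  ))
  site <- crawl_site(dir)
  expect_setequal(site$pages$url, c("index.html", "a.html", "b.html"))
  expect_false(site$truncated)
  expect_equal(nrow(site$failures), 0)
})

test_that("crawl limits truncate the site and are reported", {
  dir <- withr::local_tempdir()
  write_site(dir, list(
    "index.html" = list(body = "Home.", links = c("a.html", "b.html", "c.html")),
    "a.html" = list(body = "A."), "b.html" = list(body = "B."),
    "c.html" = list(body = "C.")
  ))
  site <- crawl_site(dir, max_pages = 2)
  expect_equal(nrow(site$pages), 2)
  expect_true(site$truncated)

  shallow <- crawl_site(dir, max_depth = 0)
  expect_equal(shallow$pages$url, "index.html")
  expect_true(shallow$truncated)
})

test_that("broken links are logged as failures, missing root is fatal", {
  dir <- withr::local_tempdir()
  write_site(dir, list(
    "index.html" = list(body = "Home.", links = c("a.html", "missing.html")),
    "a.html" = list(body = "A.")
  ))
  site <- suppressMessages(crawl_site(dir))
  expect_equal(nrow(site$pages), 2)
  expect_equal(nrow(site$failures), 1)
  expect_match(site$failures$reason, "fetch_error")

  expect_error(crawl_site(file.path(dir, "nope")), "directory")
})

test_that("robots.txt disallow rules parse and match by path prefix", {
  rules <- robots_rules(paste(
    "# comment", "User-agent: special", "Disallow: /everything",
    "User-agent: *", "Disallow: /private/", "Disallow: /tmp",
    sep = "\n"
  ))
  expect_equal(rules, c("/private/", "/tmp"))
  expect_true(robots_disallowed(rules, "/private/a.html"))
  expect_true(robots_disallowed(rules, "/tmpfile"))
  expect_false(robots_disallowed(rules, "/public/a.html"))
  expect_false(robots_disallowed(character(0), "/anything"))
})

planted_site <- function(dir, privacy_on = "b.html") {
  pages <- list(
    "index.html" = list(body = "Welcome visitors.", links = c("a.html", "b.html")),
    "a.html" = list(body = "Unrelated gardening words entirely."),
    "b.html" = list(body = "Filler sentence first. Our privacy policy protects visitor data.")
  )
  if (privacy_on == "a.html") {
    tmp <- pages[["a.html"]]; pages[["a.html"]] <- pages[["b.html"]]; pages[["b.html"]] <- tmp
  }
  write_site(dir, pages)
}

test_that("site assessment finds planted evidence with page-level location", {
  dir <- withr::local_tempdir()
  planted_site(dir)
  det <- tiny_detector()
  a <- assess_site(crawl_site(dir), det, site_id = "fixture")
  expect_s3_class(a, "hon_assessment")
  expect_true(a$verdicts$complies[a$verdicts$criterion == "privacy"])
  priv <- a$detections[a$detections$criterion == "privacy", ]
  expect_equal(priv$page_url, "b.html")
  # complies iff evidence non-empty, for every criterion
  expect_equal(a$verdicts$complies,
               hon_criteria() %in% a$detections$criterion)
})

test_that("a site without planted statements yields nine negatives", {
  dir <- withr::local_tempdir()
  write_site(dir, list(
    "index.html" = list(body = "Gardening words only.", links = "a.html"),
    "a.html" = list(body = "More gardening words follow here.")
  ))
  a <- assess_site(crawl_site(dir), tiny_detector(), site_id = "neg")
  expect_false(any(a$verdicts$complies))
  expect_equal(nrow(a$detections), 0)
})

test_that("sentence unit gives the same verdict with a sentence index", {
  dir <- withr::local_tempdir()
  planted_site(dir)
  det <- tiny_detector()
  doc <- assess_site(crawl_site(dir), det, unit = "document", site_id = "s")
  sen <- assess_site(crawl_site(dir), det, unit = "sentence", site_id = "s")
  expect_equal(sen$verdicts$complies[sen$verdicts$criterion == "privacy"],
               doc$verdicts$complies[doc$verdicts$criterion == "privacy"])
  priv <- sen$detections[sen$detections$criterion == "privacy", ]
  expect_equal(priv$sentence_index, 1L) # evidence is the second sentence
  rep <- as_report(sen)
  expect_match(rep$evidence[rep$criterion == "privacy"], "b.html#s1")
})

test_that("adding a page never retracts a criterion", {
  det <- tiny_detector()
  small <- withr::local_tempdir()
  planted_site(small)
  a1 <- assess_site(crawl_site(small), det, site_id = "x")

  bigger <- withr::local_tempdir()
  planted_site(bigger)
  # extend the site with one more (unrelated) linked page
  html <- readLines(file.path(bigger, "index.html"))
  writeLines(sub("</body>", '<a href="extra.html">more</a></body>', html),
             file.path(bigger, "index.html"))
  writeLines("<html><body><p>Extra unrelated page.</p></body></html>",
             file.path(bigger, "extra.html"))
  a2 <- assess_site(crawl_site(bigger), det, site_id = "x")
  expect_true(all(a2$verdicts$complies >= a1$verdicts$complies))
})

test_that("assessing the same fixture twice is deterministic", {
  dir <- withr::local_tempdir()
  planted_site(dir)
  det <- tiny_detector()
  r1 <- as_report(assess_site(crawl_site(dir), det, site_id = "d"))
  r2 <- as_report(assess_site(crawl_site(dir), det, site_id = "d"))
  expect_tibble_equal(r1, r2)
})
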