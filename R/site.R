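#' Crawl a website or an offline HTML directory
#'
#' Breadth-first crawl from the home page, following internal links only
#' (same host for live sites; inside the root directory for offline
#' fixtures). Each page is fetched once (cycle-safe via normalized URLs);
#' hitting `max_pages` or `max_depth` marks the site as truncated. Individual
#' page failures are logged and skipped and recorded with a reason, so
#' exclusions stay auditable.
#'
#' For an offline directory the root page is `index.html` and page URLs are
#' directory-relative paths. In live mode `robots.txt` disallow rules for
#' `User-agent: *` are respected.
#'
#' @param root A directory containing `index.html`, or an http(s) URL.
#' @param max_pages Crawl at most this many pages (default 500).
#' @param max_depth Follow links at most this many hops from the home page
#'   (default 10).
#' @return An object of class `hon_site`: list with `root`, `pages` (tibble
#'   `url`, `depth`, `text`), `truncated`, and `failures` (tibble `url`,
#'   `reason`).
#' @export
crawl_site <- function(root, max_pages = 500, max_depth = 10) {
  offline <- dir.exists(root)
  if (offline) {
    start <- "index.html"
    if (!file.exists(file.path(root, start))) {
      abort(sprintf("Offline site root %s has no index.html.", root))
    }
    fetch <- function(url) {
      f <- file.path(root, url)
      if (!file.exists(f)) abort("file not found")
      paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
    }
    internal <- function(href, base_url) resolve_offline_link(href, base_url)
    disallowed <- function(url) FALSE
  } else {
    if (!grepl("^https?://", root)) {
      abort(sprintf("Site root must be an existing directory or an http(s) URL: %s", root))
    }
    root <- normalize_url(root)
    host <- url_host(root)
    rules <- tryCatch(
      robots_rules(paste(readLines(paste0(url_origin(root), "/robots.txt"),
                                   warn = FALSE), collapse = "\n")),
      error = function(e) character(0),
      warning = function(e) character(0)
    )
    fetch <- function(url) {
      as.character(xml2::read_html(url))
    }
    internal <- function(href, base_url) {
      u <- resolve_live_link(href, base_url)
      if (is.na(u) || !identical(url_host(u), host)) NA_character_ else u
    }
    disallowed <- function(url) robots_disallowed(rules, url_path(url))
    start <- root
  }

  seen <- character(0)
  queue <- tibble(url = normalize_url(start), depth = 0L)
  pages <- list()
  failures <- list()
  truncated <- FALSE

  while (nrow(queue) > 0) {
    cur <- queue[1, ]
    queue <- queue[-1, , drop = FALSE]
    if (cur$url %in% seen) next
    if (length(pages) >= max_pages) {
      truncated <- TRUE
      break
    }
    seen <- c(seen, cur$url)
    if (disallowed(cur$url)) {
      failures[[length(failures) + 1]] <- tibble(url = cur$url, reason = "robots_disallowed")
      next
    }
    if (!grepl("\\.html?$", cur$url) && offline) {
      failures[[length(failures) + 1]] <- tibble(url = cur$url, reason = "not_html")
      next
    }
    html <- tryCatch(fetch(cur$url), error = function(e) {
      failures[[length(failures) + 1]] <<- tibble(
        url = cur$url, reason = paste0("fetch_error: ", conditionMessage(e))
      )
      if (cur$depth == 0L) {
        abort(sprintf("Site root page could not be fetched: %s", cur$url))
      }
      message(sprintf("honcheck: skipping unreachable page %s", cur$url))
      NA_character_
    })
    if (is.na(html)) next
    pages[[length(pages) + 1]] <- tibble(
      url = cur$url, depth = cur$depth,
      text = extract_text(html, page = cur$url)
    )
    if (cur$depth >= max_depth) {
      # unexpanded links below this page may exist
      if (length(page_links(html)) > 0) truncated <- TRUE
      next
    }
    for (href in page_links(html)) {
      u <- internal(href, cur$url)
      if (is.na(u)) next
      u <- normalize_url(u)
      if (!u %in% seen && !u %in% queue$url) {
        queue <- dplyr::bind_rows(queue, tibble(url = u, depth = cur$depth + 1L))
      }
    }
  }
  if (nrow(queue) > 0) truncated <- TRUE

  structure(
    list(
      root = root,
      pages = if (length(pages) > 0) dplyr::bind_rows(pages) else
        tibble(url = character(), depth = integer(), text = character()),
      truncated = truncated,
      failures = if (length(failures) > 0) dplyr::bind_rows(failures) else
        tibble(url = character(), reason = character())
    ),
    class = "hon_site"
  )
}

#' @export
print.hon_site <- function(x, ...) {
  cat(sprintf(
    "<hon_site> %s: %d pages%s, %d failures\n",
    x$root, nrow(x$pages), if (x$truncated) " (truncated)" else "",
    nrow(x$failures)
  ))
  invisible(x)
}

page_links <- function(html) {
  doc <- tryCatch(xml2::read_html(html), error = function(e) NULL)
  if (is.null(doc)) return(character(0))
  hrefs <- xml2::xml_attr(xml2::xml_find_all(doc, "//a[@href]"), "href")
  hrefs[!is.na(hrefs)]
}

# Offline fixtures: only relative links inside the root directory are
# internal; absolute URLs, mailto: and pure fragments are external/ignored.
resolve_offline_link <- function(href, base_url) {
  if (grepl("^[a-zA-Z][a-zA-Z0-9+.-]*:", href) || grepl("^#", href) ||
      grepl("^//", href)) {
    return(NA_character_)
  }
  base_dir <- dirname(base_url)
  joined <- if (base_dir == ".") href else paste0(base_dir, "/", href)
  u <- normalize_url(joined)
  if (!nzchar(u) || grepl("^\\.\\.", u)) NA_character_ else u
}

resolve_live_link <- function(href, base_url) {
  if (grepl("^#", href) || grepl("^(mailto|javascript):", href)) return(NA_character_)
  if (grepl("^https?://", href)) return(href)
  if (grepl("^//", href)) return(paste0(sub("://.*$", "", base_url), ":", href))
  origin <- url_origin(base_url)
  if (grepl("^/", href)) return(paste0(origin, href))
  base_dir <- sub("/[^/]*$", "", sub("^https?://[^/]*", "", base_url))
  paste0(origin, normalize_url(paste0(sub("^/", "", paste0(base_dir, "/", href)))))
}

url_host <- function(url) tolower(sub("^[a-zA-Z]+://([^/:]*).*$", "\\1", url))

url_origin <- function(url) {
  m <- regexec("^([a-zA-Z]+://[^/]*)", url)
  regmatches(url, m)[[1]][2]
}

url_path <- function(url) {
  p <- sub("^[a-zA-Z]+://[^/]*", "", url)
  if (!nzchar(p)) "/" else p
}

#' Parse robots.txt disallow rules for the generic user agent
#'
#' Extracts the `Disallow` path prefixes that apply to `User-agent: *`.
#'
#' @param robots_txt The robots.txt file contents as a string.
#' @return Character vector of disallowed path prefixes.
#' @export
robots_rules <- function(robots_txt) {
  lines <- trimws(strsplit(robots_txt, "\n", fixed = TRUE)[[1]])
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  rules <- character(0)
  active <- FALSE
  for (ln in lines) {
    if (grepl("^[Uu]ser-agent:", ln)) {
      active <- trimws(sub("^[Uu]ser-agent:", "", ln)) == "*"
    } else if (active && grepl("^[Dd]isallow:", ln)) {
      path <- trimws(sub("^[Dd]isallow:", "", ln))
      if (nzchar(path)) rules <- c(rules, path)
    }
  }
  rules
}

#' @rdname robots_rules
#' @param rules Character vector from `robots_rules()`.
#' @param path URL path to test (e.g. `"/private/a.html"`).
#' @return `TRUE` if any disallow prefix matches the path.
#' @export
robots_disallowed <- function(rules, path) {
  any(vapply(rules, function(r) startsWith(path, r), logical(1)))
}

#' Assess a crawled site against all criteria
#'
#' Every retrieved page is classified for every criterion with no early
#' stopping (unlike manual review, which stops at the first justification
#' found). Per criterion the evidence lists every positive detection in
#' crawl order, and the site complies iff the evidence is non-empty.
#'
#' @param site An `hon_site` from [crawl_site()].
#' @param detector An `hon_detector` from [train_detector()] or [read_model()].
#' @param unit Classification unit, `"document"` or `"sentence"`.
#' @param site_id Site identifier used in reports; defaults to the
#'   normalized root (basename for offline fixtures).
#' @return An object of class `hon_assessment`: list with `site_id`, `unit`,
#'   `verdicts` (tibble `criterion`, `complies`) and `detections` (tibble
#'   `criterion`, `page_url`, `sentence_index`, `posterior`).
#' @export
assess_site <- function(site, detector, unit = c("document", "sentence"),
                        site_id = NULL) {
  unit <- match.arg(unit)
  if (nrow(site$pages) == 0) abort("Cannot assess a site with no retrieved pages.")
  if (is.null(site_id)) {
    site_id <- if (dir.exists(site$root)) basename(normalizePath(site$root)) else
      normalize_url(site$root)
  }
  detections <- dplyr::bind_rows(lapply(seq_len(nrow(site$pages)), function(i) {
    classify_text(site$pages$text[i], detector, unit = unit,
                  page_url = site$pages$url[i])
  }))
  if (nrow(detections) == 0) {
    detections <- tibble(
      criterion = character(), page_url = character(),
      sentence_index = integer(), posterior = double()
    )
  }
  verdicts <- tibble(
    criterion = hon_criteria(),
    complies = hon_criteria() %in% detections$criterion
  )
  structure(
    list(site_id = site_id, unit = unit, verdicts = verdicts,
         detections = detections),
    class = "hon_assessment"
  )
}

#' @export
print.hon_assessment <- function(x, ...) {
  cat(sprintf("<hon_assessment> %s (unit = %s): %d/9 criteria detected\n",
              x$site_id, x$unit, sum(x$verdicts$complies)))
  invisible(x)
}

#' @rdname assess_site
#' @param x An `hon_assessment`.
#' @param ... Unused.
#' @details `tidy()` returns one row per criterion with the verdict, the
#'   number of supporting detections and the first evidence location.
#' @method tidy hon_assessment
#' @export
tidy.hon_assessment <- function(x, ...) {
  det <- x$detections
  first_ev <- vapply(hon_criteria(), function(cr) {
    d <- det[det$criterion == cr, ]
    if (nrow(d) == 0) return(NA_character_)
    if (is.na(d$sentence_index[1])) d$page_url[1] else
      paste0(d$page_url[1], "#s", d$sentence_index[1])
  }, character(1))
  tibble(
    site_id = x$site_id,
    criterion = hon_criteria(),
    complies = x$verdicts$complies,
    n_detections = vapply(hon_criteria(), function(cr) sum(det$criterion == cr), integer(1)),
    first_evidence = unname(first_ev)
  )
}

#' @rdname assess_site
#' @method glance hon_assessment
#' @export
glance.hon_assessment <- function(x, ...) {
  tibble(
    site_id = x$site_id,
    unit = x$unit,
    n_criteria_detected = sum(x$verdicts$complies),
    n_detections = nrow(x$detections)
  )
}
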