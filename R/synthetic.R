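#' Configuration for the synthetic-data generator
#'
#' The generator emulates the three study inputs that cannot be downloaded:
#' per-criterion labelled training extracts, multi-page websites with planted
#' compliance statements (and known gold verdicts), and rater matrices.
#' Vocabularies are synthetic pseudo-words (pure letter strings), pairwise
#' disjoint between the nine criteria and the background, so tests cannot
#' silently depend on English semantics. All vocabularies are drawn here,
#' deterministically from `seed`, so a corpus and sites generated from the
#' same config share the same token universe.
#'
#' @param seed Integer seed; the single source of randomness per run.
#' @param per_criterion_vocab_size Indicative pseudo-words per criterion.
#' @param background_vocab_size Background pseudo-words.
#' @param extracts_per_criterion Training extracts per criterion under
#'   `sizing = "uniform"`.
#' @param signal_strength Probability in (0, 1] that a token of a labelled
#'   extract (or of a planted evidence sentence) is drawn from the criterion
#'   vocabulary rather than the background.
#' @param site_pages Pages per fixture site (index plus content pages); must
#'   exceed the number of criteria so every compliant criterion gets its own
#'   evidence page.
#' @param evidence_mode `"page"` (a dedicated evidence page per compliant
#'   criterion) or `"sentence"` (one evidence sentence hidden inside a long
#'   background page).
#' @param sizing `"uniform"`, or `"paper_like"` for the study's training-set
#'   sizes (minimum 872 extracts for justifiability, maximum 2861 for
#'   contact details; see [paper_like_sizes()]).
#' @param compliance_rate Probability that a fixture site complies with a
#'   given criterion when sampling ground truth.
#' @param extract_length Tokens per training extract.
#' @param sentence_length Tokens per generated sentence.
#' @param page_sentences Sentences per content page in `"page"` mode.
#' @param background_page_sentences Background sentences per content page in
#'   `"sentence"` mode (long pages that dilute whole-document signal).
#' @param stem Build corpora with Porter stemming?
#' @return An object of class `hon_gen_config` (a list), including the drawn
#'   `vocab` (named list of criterion vocabularies) and `background` words.
#' @export
generator_config <- function(seed = 1,
                             per_criterion_vocab_size = 30,
                             background_vocab_size = 200,
                             extracts_per_criterion = 100,
                             signal_strength = 1,
                             site_pages = 12,
                             evidence_mode = c("page", "sentence"),
                             sizing = c("uniform", "paper_like"),
                             compliance_rate = 0.7,
                             extract_length = 40,
                             sentence_length = 8,
                             page_sentences = 5,
                             background_page_sentences = 200,
                             stem = FALSE) {
  evidence_mode <- match.arg(evidence_mode)
  sizing <- match.arg(sizing)
  stopifnot(
    signal_strength > 0, signal_strength <= 1,
    site_pages > length(hon_criteria()) + 1,
    compliance_rate >= 0, compliance_rate <= 1
  )
  words <- with_seed(seed, {
    rand_words(per_criterion_vocab_size * length(hon_criteria()) +
                 background_vocab_size)
  })
  crit_words <- words[seq_len(per_criterion_vocab_size * length(hon_criteria()))]
  vocab <- split(crit_words, rep(hon_criteria(), each = per_criterion_vocab_size))
  structure(
    list(
      seed = as.integer(seed),
      per_criterion_vocab_size = per_criterion_vocab_size,
      background_vocab_size = background_vocab_size,
      extracts_per_criterion = extracts_per_criterion,
      signal_strength = signal_strength,
      site_pages = site_pages,
      evidence_mode = evidence_mode,
      sizing = sizing,
      compliance_rate = compliance_rate,
      extract_length = extract_length,
      sentence_length = sentence_length,
      page_sentences = page_sentences,
      background_page_sentences = background_page_sentences,
      stem = stem,
      vocab = vocab[hon_criteria()],
      background = words[-seq_along(crit_words)]
    ),
    class = "hon_gen_config"
  )
}

# Evaluate `code` under `seed`, then restore the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

# Distinct pronounceable pseudo-words (pure letters: they must survive the
# digit-dropping tokenizer).
rand_words <- function(n, len = 8) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    w <- vapply(seq_len(need), function(i) {
      paste(sample(letters, len, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

# Deterministic per-site seed below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483629)
}

#' Training-set sizes of the published study
#'
#' The study's per-criterion training collections ranged from 872 extracts
#' (justifiability) to 2861 (contact details); the sizes of the remaining
#' seven criteria were not printed and are set to the midpoint.
#'
#' @param scale Multiplier applied to all sizes (rounded, minimum 1).
#' @return Named integer vector over [hon_criteria()].
#' @export
paper_like_sizes <- function(scale = 1) {
  sizes <- setNames(rep(round((872 + 2861) / 2), 9), hon_criteria())
  sizes["justifiability"] <- 872
  sizes["contact_details"] <- 2861
  out <- pmax(1L, as.integer(round(sizes * scale)))
  setNames(out, names(sizes))
}

#' Generate a labelled synthetic training corpus
#'
#' For each criterion, draws the configured number of extracts; each token
#' comes from the criterion's own vocabulary with probability
#' `signal_strength`, otherwise from the background vocabulary.
#' Deterministic given the config (which carries the seed).
#'
#' @param cfg An [generator_config()].
#' @param scale Size multiplier under `sizing = "paper_like"`.
#' @return An [hon_corpus()].
#' @export
generate_corpus <- function(cfg, scale = 1) {
  sizes <- if (cfg$sizing == "paper_like") {
    paper_like_sizes(scale)
  } else {
    setNames(rep(cfg$extracts_per_criterion, 9), hon_criteria())
  }
  extracts <- with_seed(cfg$seed + 1L, {
    dplyr::bind_rows(lapply(hon_criteria(), function(cr) {
      tibble(
        text = vapply(seq_len(sizes[[cr]]), function(i) {
          paste(draw_tokens(cfg, cr, cfg$extract_length), collapse = " ")
        }, character(1)),
        criterion = cr,
        source_url = NA_character_
      )
    }))
  })
  hon_corpus(extracts, stem = cfg$stem)
}

draw_tokens <- function(cfg, criterion, n) {
  from_signal <- runif(n) < cfg$signal_strength
  toks <- character(n)
  toks[from_signal] <- sample(cfg$vocab[[criterion]], sum(from_signal), replace = TRUE)
  toks[!from_signal] <- sample(cfg$background, sum(!from_signal), replace = TRUE)
  toks
}

make_sentence <- function(tokens) {
  s <- paste(tokens, collapse = " ")
  paste0(toupper(substr(s, 1, 1)), substring(s, 2), ".")
}

#' Generate a fixture website with planted compliance evidence
#'
#' Writes a multi-page HTML site (an `index.html` linking every content
#' page) into `dir`. Ground-truth compliance is sampled per criterion at
#' `compliance_rate` (or supplied); each compliant criterion gets one
#' distinct evidence location. In `"page"` mode the evidence page consists of
#' criterion-vocabulary sentences; in `"sentence"` mode every content page is
#' a long background page and the evidence is a single criterion-vocabulary
#' sentence inserted at a random position, emulating a compliance statement
#' buried in boilerplate.
#'
#' @param cfg An [generator_config()].
#' @param dir Output directory (created; becomes the offline crawl root).
#' @param site_id Site identifier recorded in the gold assessment; defaults
#'   to `basename(dir)`.
#' @param seed Seed for this site; defaults to a value derived from the
#'   config seed, so batches should pass `derive_seed(cfg$seed, i)` or
#'   distinct explicit seeds.
#' @param compliant Optional named logical over [hon_criteria()] fixing the
#'   ground truth instead of sampling it.
#' @return A list with `dir`, `site_id`, and `gold` (tibble `site_id`,
#'   `criterion`, `complies`, `evidence_url`).
#' @export
generate_site <- function(cfg, dir, site_id = NULL, seed = NULL,
                          compliant = NULL) {
  if (is.null(site_id)) site_id <- basename(dir)
  if (is.null(seed)) seed <- derive_seed(cfg$seed, 0L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  crits <- hon_criteria()
  with_seed(seed, {
    if (is.null(compliant)) {
      compliant <- setNames(runif(9) < cfg$compliance_rate, crits)
    }
    stopifnot(all(crits %in% names(compliant)))
    n_content <- cfg$site_pages - 1L
    page_files <- sprintf("page%02d.html", seq_len(n_content))
    planted <- crits[compliant[crits]]
    evidence_page <- setNames(sample(page_files, length(planted)), planted)

    background_sentence <- function() {
      make_sentence(sample(cfg$background, cfg$sentence_length, replace = TRUE))
    }
    for (pf in page_files) {
      planted_here <- names(evidence_page)[evidence_page == pf]
      if (cfg$evidence_mode == "page" && length(planted_here) == 1) {
        sents <- vapply(seq_len(cfg$page_sentences), function(i) {
          make_sentence(draw_tokens(cfg, planted_here, cfg$sentence_length))
        }, character(1))
      } else {
        sents <- vapply(seq_len(
          if (cfg$evidence_mode == "sentence") cfg$background_page_sentences
          else cfg$page_sentences
        ), function(i) background_sentence(), character(1))
        if (length(planted_here) == 1) {
          pos <- sample(seq_along(sents), 1)
          sents[pos] <- make_sentence(draw_tokens(cfg, planted_here, cfg$sentence_length))
        }
      }
      write_fixture_page(file.path(dir, pf), title = pf, body = sents)
    }
    write_fixture_page(
      file.path(dir, "index.html"), title = site_id,
      body = background_sentence(),
      links = page_files
    )
    gold <- tibble(
      site_id = site_id,
      criterion = crits,
      complies = unname(compliant[crits]),
      evidence_url = ifelse(compliant[crits],
                            unname(evidence_page[crits]), NA_character_)
    )
    list(dir = dir, site_id = site_id, gold = gold)
  })
}

write_fixture_page <- function(path, title, body, links = character(0)) {
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><title>", title, "</title></head><body>",
    sprintf("<h1>%s</h1>", title),
    sprintf("<p>%s</p>", body),
    sprintf('<p><a href="%s">%s</a></p>', links, links),
    "</body></html>"
  )
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}

#' Generate a batch of fixture sites with a shared gold table
#'
#' @inheritParams generate_site
#' @param n_sites Number of sites.
#' @param dir Parent directory; sites are written to `site01`, `site02`, ...
#' @return A list with `dirs` (character vector) and `gold` (stacked gold
#'   tibble over all sites).
#' @export
generate_site_batch <- function(cfg, dir, n_sites) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sites <- lapply(seq_len(n_sites), function(i) {
    generate_site(
      cfg,
      dir = file.path(dir, sprintf("site%02d", i)),
      seed = derive_seed(cfg$seed, i)
    )
  })
  list(
    dirs = vapply(sites, `[[`, character(1), "dir"),
    gold = dplyr::bind_rows(lapply(sites, `[[`, "gold"))
  )
}

#' Generate a synthetic rating matrix
#'
#' Emulates multiple senior reviewers rating the same items. Per item, a
#' consensus category is drawn as `prevalence` (probability of the dominant
#' category); with probability `unanimity` all raters report it, otherwise
#' one randomly chosen rater dissents with the opposite category. In the
#' prevalence-problem regime (dominant consensus, dissent supplying nearly
#' all rare ratings) percent agreement stays high while Fleiss' kappa drops
#' to zero or below.
#'
#' @param n_items Number of items (e.g. websites).
#' @param n_raters Number of raters.
#' @param profile List with `unanimity` (per-item probability that all raters
#'   agree) and `prevalence` (probability that the item consensus is the
#'   dominant category, coded 1).
#' @param seed Integer seed.
#' @return An `n_items` x `n_raters` integer matrix of 0/1 ratings.
#' @export
generate_ratings <- function(n_items, n_raters,
                             profile = list(unanimity = 0.8, prevalence = 0.7),
                             seed = 1) {
  stopifnot(n_items >= 1, n_raters >= 1)
  with_seed(seed, {
    consensus <- rbinom(n_items, 1, profile$prevalence)
    m <- matrix(rep(consensus, n_raters), nrow = n_items)
    dissent <- runif(n_items) >= profile$unanimity
    if (n_raters >= 2) {
      for (i in which(dissent)) {
        m[i, sample(n_raters, 1)] <- 1L - consensus[i]
      }
    }
    colnames(m) <- paste0("rater", seq_len(n_raters))
    m
  })
}
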