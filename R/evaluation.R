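#' Compare automated and manual verdicts for one site and criterion
#'
#' Five-outcome taxonomy. With gold and automated verdicts both positive, the
#' outcome is `TP` when any automated detection lies on the expert-designated
#' evidence page (normalized URL equality; `TP` takes precedence when
#' detections hit both the gold page and others) and `OTHER` when the
#' criterion was detected only on different pages. Gold-positive without
#' detection is `FN` ("silence"), gold-negative with detection `FP`
#' ("noise"), and agreement on absence `TN`.
#'
#' @param gold One site's gold rows (tibble with `site_id`, `criterion`,
#'   `complies`, `evidence_url`).
#' @param auto The same site's automated report rows (tibble with `site_id`,
#'   `criterion`, `complies`, `evidence`), e.g. from [as_report()].
#' @param criterion The criterion to compare.
#' @return One of `"TP"`, `"TN"`, `"FP"`, `"FN"`, `"OTHER"`.
#' @export
compare_site <- function(gold, auto, criterion) {
  check_criterion(criterion)
  if (inherits(auto, "hon_assessment")) auto <- as_report(auto)
  gsite <- unique(gold$site_id)
  asite <- unique(auto$site_id)
  if (length(gsite) != 1 || length(asite) != 1 || !identical(gsite, asite)) {
    abort(sprintf("Site mismatch between gold (%s) and automated (%s) records.",
                  paste(gsite, collapse = ","), paste(asite, collapse = ",")))
  }
  g <- gold[gold$criterion == criterion, ]
  a <- auto[auto$criterion == criterion, ]
  if (nrow(g) != 1 || nrow(a) != 1) {
    abort(sprintf("Expected exactly one gold and one automated row for criterion '%s'.",
                  criterion))
  }
  g_pos <- isTRUE(g$complies)
  a_pos <- isTRUE(a$complies)
  if (!g_pos && !a_pos) return("TN")
  if (!g_pos && a_pos) return("FP")
  if (g_pos && !a_pos) return("FN")
  pages <- normalize_url(parse_evidence(a$evidence)$page_url)
  if (normalize_url(g$evidence_url) %in% pages) "TP" else "OTHER"
}

#' Compare gold and automated assessments across sites
#'
#' @param gold Gold tibble from [read_gold()] (all sites).
#' @param reports Automated report tibble from [as_report()] /
#'   [read_assessment_report()] (same sites).
#' @return A tibble with one row per site x criterion: `site_id`,
#'   `criterion`, `outcome`.
#' @export
evaluate_sites <- function(gold, reports) {
  sites <- unique(gold$site_id)
  missing <- setdiff(sites, unique(reports$site_id))
  if (length(missing) > 0) {
    abort(sprintf("No automated report for site(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  dplyr::bind_rows(lapply(sites, function(s) {
    g <- gold[gold$site_id == s, ]
    a <- reports[reports$site_id == s, ]
    tibble(
      site_id = s,
      criterion = hon_criteria(),
      outcome = vapply(hon_criteria(), function(cr) compare_site(g, a, cr),
                       character(1))
    )
  }))
}

#' Tabulate outcomes into per-criterion confusion records
#'
#' @param outcomes Tibble from [evaluate_sites()] (columns `criterion`,
#'   `outcome`; one row per site x criterion).
#' @param label Optional label for the experimental arm (e.g. the weighting
#'   scheme or classification unit), stored in an `arm` column.
#' @return A confusion tibble with one row per criterion: counts `tn`, `tp`,
#'   `fn`, `fp`, `other`, plus `manual_pos = tp + fn + other` and `n_sites`.
#' @export
tabulate_outcomes <- function(outcomes, label = NULL) {
  schema <- tibble(
    criterion = character(), tn = integer(), tp = integer(), fn = integer(),
    fp = integer(), other = integer(), manual_pos = integer(),
    n_sites = integer()
  )
  out <- dplyr::bind_rows(schema, lapply(unique(outcomes$criterion), function(cr) {
    o <- outcomes$outcome[outcomes$criterion == cr]
    counts <- table(factor(o, levels = c("TN", "TP", "FN", "FP", "OTHER")))
    tibble(
      criterion = cr,
      tn = as.integer(counts[["TN"]]), tp = as.integer(counts[["TP"]]),
      fn = as.integer(counts[["FN"]]), fp = as.integer(counts[["FP"]]),
      other = as.integer(counts[["OTHER"]]),
      manual_pos = as.integer(counts[["TP"]] + counts[["FN"]] + counts[["OTHER"]]),
      n_sites = length(o)
    )
  }))
  stopifnot(all(out$tn + out$tp + out$fn + out$fp + out$other == out$n_sites))
  if (!is.null(label)) out <- dplyr::mutate(out, arm = label, .after = "criterion")
  out
}

#' Precision and recall under the "other"-tolerant convention
#'
#' Detections on a different page than the expert-designated one (`OTHER`)
#' count as positive detections:
#' `precision = (TP + OTHER) / (TP + FP + OTHER)` and
#' `recall = (TP + OTHER) / manual_pos`, with `0/0` defined as `0.00`.
#' Printed-style fractions accompany each value.
#'
#' @param confusion A confusion tibble from [tabulate_outcomes()] or
#'   [hon_study_counts()] (columns `tp`, `fp`, `fn`, `other`, `manual_pos`;
#'   other columns are carried through).
#' @return The input with columns `precision`, `recall`, `precision_num`,
#'   `precision_den`, `recall_num`, `recall_den`, and formatted
#'   `precision_label` / `recall_label` (e.g. `"0.85 (11/13)"`); class
#'   `hon_metrics`.
#' @export
precision_recall <- function(confusion) {
  confusion <- as_tibble(confusion)
  pos <- confusion$tp + confusion$other
  pden <- confusion$tp + confusion$fp + confusion$other
  rden <- confusion$manual_pos
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  out <- dplyr::mutate(
    confusion,
    precision = safe_div(pos, pden),
    recall = safe_div(pos, rden),
    precision_num = pos, precision_den = pden,
    recall_num = pos, recall_den = rden,
    precision_label = sprintf("%.2f (%d/%d)", .data$precision, pos, pden),
    recall_label = sprintf("%.2f (%d/%d)", .data$recall, pos, rden)
  )
  class(out) <- c("hon_metrics", class(out))
  out
}

#' Confusion counts from the published evaluation study
#'
#' Per-criterion confusion counts from the published manual-versus-automated
#' evaluation of HONcode detection on 27 English health websites:
#' `table = "weighting"` gives the whole-page (document-unit) comparison for
#' both term-weighting schemes (arms `tfc` and `tfx`); `table = "unit"` gives
#' the document-versus-sentence comparison for the privacy and date criteria
#' (arms `document` and `sentence`, tfc weighting). Feeding these counts to
#' [precision_recall()] reproduces the study's printed precision/recall
#' fractions. Note the source tables disagree on the date/document cell
#' (FN 16 / OTHER 5 in the weighting table vs FN 15 / OTHER 6 in the unit
#' table); both are reproduced verbatim.
#'
#' @param table `"weighting"` or `"unit"`.
#' @return A confusion tibble (see [tabulate_outcomes()]) with an `arm`
#'   column.
#' @export
hon_study_counts <- function(table = c("weighting", "unit")) {
  table <- match.arg(table)
  mk <- function(criterion, arm, tn, tp, fn, fp, other) {
    tibble(
      criterion = criterion, arm = arm, tn = tn, tp = tp, fn = fn, fp = fp,
      other = other, manual_pos = tp + fn + other,
      n_sites = tn + tp + fn + fp + other
    )
  }
  if (table == "weighting") {
    dplyr::bind_rows(
      mk("authority", "tfc", 4, 1, 10, 2, 10),
      mk("complementarity", "tfc", 1, 0, 21, 0, 5),
      mk("privacy", "tfc", 1, 14, 9, 2, 1),
      mk("reference", "tfc", 5, 0, 6, 6, 10),
      mk("justifiability", "tfc", 14, 1, 1, 7, 4),
      mk("contact_details", "tfc", 1, 6, 16, 0, 4),
      mk("financial_disclosure", "tfc", 8, 1, 9, 2, 7),
      mk("advertising_policy", "tfc", 9, 0, 13, 2, 3),
      mk("date", "tfc", 6, 0, 16, 0, 5),
      mk("authority", "tfx", 4, 4, 14, 2, 3),
      mk("complementarity", "tfx", 1, 2, 23, 0, 1),
      mk("privacy", "tfx", 3, 14, 10, 0, 0),
      mk("reference", "tfx", 8, 4, 7, 3, 5),
      mk("justifiability", "tfx", 8, 3, 3, 13, 0),
      mk("contact_details", "tfx", 1, 15, 8, 0, 3),
      mk("financial_disclosure", "tfx", 9, 0, 16, 1, 1),
      mk("advertising_policy", "tfx", 10, 1, 13, 1, 2),
      mk("date", "tfx", 6, 0, 21, 0, 0)
    )
  } else {
    dplyr::bind_rows(
      mk("privacy", "document", 1, 14, 9, 2, 1),
      mk("privacy", "sentence", 0, 21, 2, 3, 1),
      mk("date", "document", 6, 0, 15, 0, 6),
      mk("date", "sentence", 0, 11, 1, 6, 9)
    )
  }
}

#' Pairwise percent agreement between raters
#'
#' Fraction of agreeing rater pairs over all item-pair combinations: with
#' `n` items and `r` raters the denominator is `n * r * (r - 1) / 2`.
#'
#' @param ratings An items x raters matrix (or data frame) of categorical
#'   ratings with no missing cells and at least two raters.
#' @return Agreement in `[0, 1]`.
#' @export
percent_agreement <- function(ratings) {
  m <- as.matrix(ratings)
  if (ncol(m) < 2) abort("Percent agreement requires at least 2 raters.")
  if (any(is.na(m))) abort("Rating matrix must have no missing cells.")
  r <- ncol(m)
  agree <- vapply(seq_len(nrow(m)), function(i) {
    counts <- table(m[i, ])
    sum(choose(as.numeric(counts), 2))
  }, numeric(1))
  sum(agree) / (nrow(m) * choose(r, 2))
}

#' Fleiss' kappa for multi-rater agreement
#'
#' Standard Fleiss formulation: per-item agreement
#' `P_i = [sum_j n_ij (n_ij - 1)] / [r (r - 1)]`, chance agreement
#' `P_e = sum_j p_j^2`, and `kappa = (P_bar - P_e) / (1 - P_e)`. When a
#' single category is ever used, `P_e = 1` and kappa is undefined; `NaN` is
#' returned with a prevalence warning. Kappa is also depressed (the
#' "prevalence problem") when one category dominates, and can be negative
#' despite high percent agreement.
#'
#' @inheritParams percent_agreement
#' @param categories Optional vector of all rating categories in the schema;
#'   defaults to the categories observed in `ratings`.
#' @return Kappa (scalar), with attributes `P_bar` and `P_e`.
#' @export
fleiss_kappa <- function(ratings, categories = NULL) {
  m <- as.matrix(ratings)
  if (ncol(m) < 2) abort("Fleiss' kappa requires at least 2 raters.")
  if (any(is.na(m))) abort("Rating matrix must have no missing cells.")
  if (is.null(categories)) categories <- sort(unique(as.vector(m)))
  r <- ncol(m)
  nij <- t(apply(m, 1, function(row) {
    as.numeric(table(factor(row, levels = categories)))
  }))
  if (length(categories) == 1) nij <- matrix(nij, ncol = 1)
  p_i <- (rowSums(nij^2) - r) / (r * (r - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(nij) / (nrow(m) * r)
  p_e <- sum(p_j^2)
  if (p_e >= 1) {
    warn(paste(
      "Only one rating category was ever used: chance agreement is 1 and",
      "Fleiss' kappa is undefined (extreme prevalence problem). Returning NaN."
    ))
    return(structure(NaN, P_bar = p_bar, P_e = p_e))
  }
  structure((p_bar - p_e) / (1 - p_e), P_bar = p_bar, P_e = p_e)
}

#' Landis-Koch interpretation bands for kappa
#'
#' @param kappa Numeric vector of kappa values.
#' @return Character vector: `"poor"` (< 0), `"slight"` (0-0.20), `"fair"`
#'   (0.21-0.40), `"moderate"` (0.41-0.60), `"substantial"` (0.61-0.80),
#'   `"almost perfect"` (> 0.80); `NA` for undefined kappa.
#' @export
kappa_interpretation <- function(kappa) {
  dplyr::case_when(
    is.nan(kappa) | is.na(kappa) ~ NA_character_,
    kappa < 0 ~ "poor",
    kappa <= 0.20 ~ "slight",
    kappa <= 0.40 ~ "fair",
    kappa <= 0.60 ~ "moderate",
    kappa <= 0.80 ~ "substantial",
    TRUE ~ "almost perfect"
  )
}

#' Summarize inter-rater agreement for one or more criteria
#'
#' @param ratings A single items x raters matrix, or a named list of such
#'   matrices (one per criterion).
#' @return A tibble with `criterion` (if a list was given),
#'   `percent_agreement` (in percent, as conventionally reported), `kappa`
#'   and `interpretation`.
#' @export
agreement_summary <- function(ratings) {
  if (is.list(ratings) && !is.data.frame(ratings)) {
    return(dplyr::bind_rows(lapply(names(ratings), function(nm) {
      dplyr::mutate(agreement_summary(ratings[[nm]]), criterion = nm,
                    .before = 1)
    })))
  }
  k <- suppressWarnings(fleiss_kappa(ratings))
  tibble(
    percent_agreement = 100 * percent_agreement(ratings),
    kappa = as.numeric(k),
    interpretation = kappa_interpretation(as.numeric(k))
  )
}
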