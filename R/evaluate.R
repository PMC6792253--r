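#' Rank one case's variants by predicted reported-probability
#'
#' Sorts a case's variants from highest to lowest probability of being
#' clinically reported. Ties break by variant key in lexicographic order so
#' the ranking is deterministic and invariant to input order; an optional
#' pessimistic mode instead assigns every tied variant the worst rank of its
#' tie group, for sensitivity analysis.
#'
#' @param probabilities Named numeric vector: variant key -> probability.
#' @param reported Character vector of reported variant keys (optional).
#' @param acmg Named character vector key -> ACMG class (`"VUS"`, `"LP"`,
#'   `"Path"`) for reported variants (optional).
#' @param case_id Case identifier carried through to summaries.
#' @param ties `"key"` (default, deterministic permutation) or
#'   `"pessimistic"`.
#' @return Object of class `case_ranking`: `case_id`, `keys` (ordered),
#'   `ranks` (named by key), `reported_ranks`, `reported_acmg`.
#' @export
rank_case <- function(probabilities, reported = character(0), acmg = NULL,
                      case_id = NA_character_, ties = c("key", "pessimistic")) {
  ties <- match.arg(ties)
  if (!length(probabilities)) stop("case has no variants")
  keys <- names(probabilities)
  ord <- order(-probabilities, keys)
  keys_sorted <- keys[ord]
  ranks <- if (ties == "key") {
    stats::setNames(seq_along(keys_sorted), keys_sorted)
  } else {
    r <- rank(-probabilities, ties.method = "max")
    stats::setNames(r[ord], keys_sorted)
  }
  reported <- intersect(reported, keys)
  structure(list(case_id = case_id, keys = keys_sorted, ranks = ranks,
                 reported_ranks = ranks[reported],
                 reported_acmg = if (is.null(acmg)) NULL else acmg[reported]),
            class = "case_ranking")
}

#' Rank summaries for reported variants, stratified by ACMG class
#'
#' Pools the ranks of every reported variant across cases and summarizes
#' them overall and within each pathogenicity stratum: count, median rank
#' (even counts: mean of the two central order statistics), mean rank, and
#' the percentage of reported variants ranked in the top 1, 10 and 20 of
#' their case.
#'
#' @param rankings List of `case_ranking`s whose reported variants carry
#'   ACMG classes.
#' @return data.frame with one row per stratum (`All`, `VUS`, `LP`, `Path`):
#'   columns `stratum`, `n`, `median_rank`, `mean_rank`, `top1`, `top10`,
#'   `top20` (percentages in `[0, 100]`). Empty strata get `n = 0` and `NA`
#'   metrics.
#' @export
rank_metrics <- function(rankings) {
  ranks <- unlist(lapply(rankings, `[[`, "reported_ranks"), use.names = FALSE)
  classes <- unlist(lapply(rankings, `[[`, "reported_acmg"), use.names = FALSE)
  if (length(classes) != length(ranks)) {
    stop("every reported variant needs an ACMG class for stratification")
  }
  strata <- list(All = rep(TRUE, length(ranks)),
                 VUS = classes == "VUS", LP = classes == "LP",
                 Path = classes == "Path")
  out <- lapply(names(strata), function(s) {
    r <- ranks[strata[[s]]]
    if (!length(r)) {
      return(data.frame(stratum = s, n = 0L, median_rank = NA_real_,
                        mean_rank = NA_real_, top1 = NA_real_,
                        top10 = NA_real_, top20 = NA_real_))
    }
    data.frame(stratum = s, n = length(r),
               median_rank = stats::median(r), mean_rank = mean(r),
               top1 = 100 * mean(r <= 1), top10 = 100 * mean(r <= 10),
               top20 = 100 * mean(r <= 20))
  })
  do.call(rbind, out)
}

#' ROC and precision-recall curves with areas
#'
#' Sweeps thresholds over the distinct score values. The ROC curve starts at
#' (0, 0) and ends at (1, 1) and its area is computed by the trapezoidal
#' rule; the precision-recall area uses the step-wise average-precision
#' estimator (trapezoidal PR interpolation is optimistic and is deliberately
#' not used).
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (1 = positive); both classes must be present.
#' @return Object of class `curve_summary`: `roc` (data.frame fpr/tpr/
#'   threshold), `pr` (recall/precision/threshold), `auroc`, `auprc`.
#' @export
curves <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to compute curves")
  }
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  # collapse ties: cumulative counts at each distinct threshold
  last_of_tie <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y == 1L)[last_of_tie]
  fp <- cumsum(y == 0L)[last_of_tie]
  thr <- s[last_of_tie]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  roc <- data.frame(fpr = fpr, tpr = tpr, threshold = c(Inf, thr))
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / np
  precision <- tp / (tp + fp)
  pr <- data.frame(recall = recall, precision = precision, threshold = thr)
  auprc <- sum(diff(c(0, recall)) * precision)
  structure(list(roc = roc, pr = pr, auroc = auroc, auprc = auprc),
            class = "curve_summary")
}

#' @export
print.curve_summary <- function(x, ...) {
  cat(sprintf("curve_summary: AUROC %.4f, AUPRC %.4f (%d thresholds)\n",
              x$auroc, x$auprc, nrow(x$pr)))
  invisible(x)
}

#' Per-case rankings from a single feature column
#'
#' Control rankers: order each case's variants by one raw feature (e.g.
#' scaled CADD, or the phenotype cosine score) instead of a model
#' probability — the naive orderings an analyst might use after filtering.
#'
#' @param fm A `feature_matrix` with case IDs and labels.
#' @param feature Name of the feature column to rank by.
#' @return List of `case_ranking`s, one per case.
#' @export
baseline_rankers <- function(fm, feature) {
  if (!feature %in% colnames(fm$x)) {
    stop(sprintf("feature column '%s' absent from the matrix", feature))
  }
  rank_cases_by_score(fm, fm$x[, feature])
}

#' Rank every case in a matrix by an arbitrary per-variant score
#'
#' @param fm A `feature_matrix`.
#' @param scores Numeric vector aligned with the matrix rows.
#' @param ties Tie handling, as in [rank_case()].
#' @return List of `case_ranking`s, one per case (in first-appearance order).
#' @export
rank_cases_by_score <- function(fm, scores, ties = "key") {
  stopifnot(length(scores) == nrow(fm$x))
  idx_by_case <- split(seq_along(scores), factor(fm$case_ids,
                                                 levels = unique(fm$case_ids)))
  lapply(names(idx_by_case), function(cid) {
    i <- idx_by_case[[cid]]
    p <- stats::setNames(scores[i], fm$keys[i])
    rep_keys <- fm$keys[i][fm$labels[i] == 1L]
    acmg <- stats::setNames(fm$acmg_class[i], fm$keys[i])
    rank_case(p, reported = rep_keys, acmg = acmg, case_id = cid, ties = ties)
  })
}

#' Complete a partial ranking conservatively
#'
#' External score files may leave some of a case's variants unscored. Those
#' variants are assumed to sit at the next best possible ranks: they are
#' appended, in key order, immediately after the last scored variant. (This
#' is an optimistic completion for the external method being ingested.)
#'
#' @param scored_keys Variant keys in their scored order (possibly empty).
#' @param case_keys All variant keys of the case.
#' @return Character vector: the completed ordering over `case_keys`.
#' @export
conservative_unranked_fill <- function(scored_keys, case_keys) {
  scored_keys <- intersect(scored_keys, case_keys)
  c(scored_keys, sort(setdiff(case_keys, scored_keys)))
}
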