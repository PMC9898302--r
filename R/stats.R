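#' ROC curve and AUC with Hanley-McNeil confidence interval
#'
#' AUC is computed by the rank (Mann-Whitney) formulation with midranks for
#' ties; the 95% CI uses the Hanley-McNeil variance formula. The curve has
#' one point per distinct threshold.
#'
#' @param scores numeric marker values (higher = more positive-like).
#' @param labels logical or 0/1 class labels (TRUE/1 = positive).
#' @param conf_level confidence level for the CI.
#' @return list with `auc`, `ci` (length-2), `se`, `curve` (data.table of
#'   `threshold`, `sensitivity`, `specificity`).
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stopf("both classes must be present to compute a ROC curve")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.table(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[labels] >= t),
                         numeric(1)),
    specificity = vapply(thr, function(t) mean(scores[!labels] < t),
                         numeric(1)))
  list(auc = auc, ci = ci, se = se, curve = curve)
}

#' Mutual-exclusivity test on two binary alteration events
#'
#' Builds the 2x2 sample table of event co-occurrence and applies a two-sided
#' chi-square test with 1 degree of freedom (no continuity correction by
#' default). The odds ratio uses the Haldane correction (+0.5 per cell) when
#' any cell is zero; OR < 1 indicates mutual exclusivity.
#'
#' @param event_a,event_b logical vectors over the same samples.
#' @param yates apply the continuity correction.
#' @return list with `table` (2x2, a+/a- by b+/b-), `chisq`, `p`,
#'   `odds_ratio`, `direction` in "mutually_exclusive"/"co_occurring"/
#'   "none".
#' @export
mutual_exclusivity <- function(event_a, event_b, yates = FALSE) {
  event_a <- as.logical(event_a); event_b <- as.logical(event_b)
  stopifnot(length(event_a) == length(event_b), length(event_a) >= 1L,
            !anyNA(event_a), !anyNA(event_b))
  tab <- matrix(c(sum(event_a & event_b), sum(event_a & !event_b),
                  sum(!event_a & event_b), sum(!event_a & !event_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("a+", "a-"), c("b+", "b-")))
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warnf("degenerate margin (an event never or always occurs): p undefined")
    chisq <- NA_real_; p <- NA_real_
  } else {
    e <- outer(rs, cs) / n
    d <- abs(tab - e)
    if (yates) d <- pmax(d - 0.5, 0)
    chisq <- sum(d^2 / e)
    p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  t2 <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  direction <- if (or < 1) "mutually_exclusive"
  else if (or > 1) "co_occurring" else "none"
  list(table = tab, chisq = chisq, p = p, odds_ratio = or,
       direction = direction)
}

CN_CATEGORIES <- c("deletion", "none", "gain", "amplification")

#' Summarize copy-number calls
#'
#' @param calls character vector of per-sample calls drawn from
#'   deletion/none/gain/amplification.
#' @return list with `counts` (per category), `n`, `percent_altered` (raw)
#'   and `percent_altered_rounded` (nearest integer); altered = gain +
#'   amplification.
#' @export
copy_number_summary <- function(calls) {
  stopifnot(length(calls) >= 1L)
  bad <- setdiff(unique(calls), CN_CATEGORIES)
  if (length(bad))
    stopf("unknown copy-number category: %s", paste(bad, collapse = ", "))
  counts <- table(factor(calls, levels = CN_CATEGORIES))
  n <- length(calls)
  pct <- 100 * (counts[["gain"]] + counts[["amplification"]]) / n
  list(counts = counts, n = n, percent_altered = pct,
       percent_altered_rounded = round(pct))
}

#' Spearman rank correlation with midranks
#'
#' @param x,y numeric vectors of equal length (>= 3 after NA removal).
#' @return list with `rho` (midrank-based), `p` (t approximation), `n`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  res <- spearman_midrank(x, y)
  if (res$n < 3L) stopf("need at least 3 paired observations")
  res
}
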