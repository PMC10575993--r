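## Small statistical primitives shared across modules. The hypergeometric
## upper tail is one kernel used by both the shared-PPI feature and the
## over-representation analysis; the rank AUC is used by both the per-feature
## classifier evaluation and the drug-response analytics.

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability of observing at least `k` successes when drawing `n_draws`
#' items without replacement from a population of size `n_total` containing
#' `n_success` successes.
#'
#' @param k observed overlap.
#' @param n_draws number of draws.
#' @param n_success successes in the population.
#' @param n_total population size.
#' @return numeric p-value in \[0, 1\].
#' @export
hyper_upper_tail <- function(k, n_draws, n_success, n_total) {
  stopifnot(n_draws <= n_total, n_success <= n_total)
  stats::phyper(k - 1, n_success, n_total - n_success, n_draws,
                lower.tail = FALSE)
}

#' Rank-based AUC (Wilcoxon statistic scaled to \[0,1\])
#'
#' Probability that a randomly chosen positive scores above a randomly chosen
#' negative, ties counted one half. NA scores are dropped pairwise with their
#' labels.
#'
#' @param scores numeric vector.
#' @param labels logical/0-1 vector, `TRUE` = positive class.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("rank_auc needs both classes")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Harrell's concordance index
#'
#' A patient pair is comparable when the shorter observed time ends in an
#' event; concordant when the higher risk fails first; risk ties count one
#' half. Tied event times are not comparable.
#'
#' @param risk numeric predicted risk (higher = worse).
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @return concordance in \[0, 1\].
#' @export
c_index <- function(risk, time, event) {
  keep <- !is.na(risk) & !is.na(time) & !is.na(event)
  risk <- risk[keep]; time <- time[keep]; event <- as.integer(event[keep])
  n <- length(risk)
  dt <- outer(time, time, "<")              # [i,j]: i fails strictly first
  comparable <- dt & matrix(event == 1, n, n)
  if (!any(comparable)) stop("no comparable pairs for the concordance index")
  dr <- outer(risk, risk, "-")              # risk_i - risk_j
  concordant <- sum(dr[comparable] > 0)
  tied <- sum(dr[comparable] == 0)
  (concordant + 0.5 * tied) / sum(comparable)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over the standard step-up procedure so every module corrects
#' within one explicit family.
#'
#' @param p numeric p-values.
#' @return adjusted p-values (same length, NAs preserved).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
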