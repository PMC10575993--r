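## CRISPR dependency-screen filter. For each candidate pair the dependency of
## gene1 across cell lines is regressed on a 0/1 indicator of gene2 carrying
## its rescuing alteration state, with cell-line lineage as categorical
## covariates. Dependency scores are oriented "more negative = more
## essential"; a rescue therefore shifts gene1 dependency toward 0 in lines
## where gene2 is altered. The screen reports the coefficient on the
## essentiality scale (the negated raw-scale coefficient), so a rescue shows
## as a negative coefficient and the published pass rule -- negative
## coefficient, FDR < 0.05, alteration in more than ten cell lines -- applies
## directly.

#' Lineage-adjusted regression of gene1 dependency on gene2 alteration
#'
#' Ordinary least squares of gene1's dependency scores on a 0/1 indicator of
#' gene2 carrying `required_state`, plus one-hot lineage covariates
#' (reference level dropped; lineages with fewer than `min_lineage_size` cell
#' lines merged into `"other"`). AMBIGUOUS calls do not count as the required
#' state.
#'
#' @param g1,g2 gene symbols.
#' @param dep a [dependency_matrix()].
#' @param alt alteration matrix over the same cell lines.
#' @param required_state `"LOF"` or `"GOF"` -- gene2's rescuing state.
#' @param min_lineage_size lineages smaller than this are pooled.
#' @return list with `coefficient` (raw scale: effect of the indicator on the
#'   dependency score as supplied), `p` (two-sided), `n_altered`, `n_total`.
#'   Coefficient/p are NA when the design is rank-deficient.
#' @export
screen_pair <- function(g1, g2, dep, alt, required_state = c("LOF", "GOF"),
                        min_lineage_size = 3) {
  required_state <- match.arg(required_state)
  if (!g1 %in% rownames(dep$scores)) stop("gene1 not in dependency matrix: ", g1)
  lines <- intersect(colnames(dep$scores), colnames(alt))
  if (!g2 %in% rownames(alt)) {
    return(list(coefficient = NA_real_, p = NA_real_, n_altered = 0L,
                n_total = length(lines)))
  }
  y <- dep$scores[g1, lines]
  x <- as.integer(alt[g2, lines] == required_state)
  ok <- !is.na(y)
  y <- y[ok]; x <- x[ok]
  lineage <- dep$lineage[lines][ok]
  small <- names(which(table(lineage) < min_lineage_size))
  lineage[lineage %in% small] <- "other"
  lineage <- factor(lineage)
  n_altered <- sum(x == 1)
  if (n_altered == 0 || n_altered == length(x)) {
    return(list(coefficient = NA_real_, p = NA_real_, n_altered = n_altered,
                n_total = length(x)))
  }
  fit <- if (nlevels(lineage) > 1) {
    stats::lm(y ~ x + lineage)
  } else {
    stats::lm(y ~ x)
  }
  cf <- summary(fit)$coefficients
  if (anyNA(stats::coef(fit)) || !"x" %in% rownames(cf)) {
    message("rank-deficient design for pair ", g1, "-", g2)
    return(list(coefficient = NA_real_, p = NA_real_, n_altered = n_altered,
                n_total = length(x)))
  }
  list(coefficient = unname(cf["x", "Estimate"]),
       p = unname(cf["x", "Pr(>|t|)"]),
       n_altered = n_altered, n_total = length(x))
}

#' Run the dependency screen over candidate pairs
#'
#' Applies [screen_pair()] per candidate (the pair class fixes gene2's
#' rescuing state), restricts to pairs whose partner is altered in more than
#' `min_altered` cell lines (strict), applies Benjamini-Hochberg correction
#' across all tested pairs, and flags passes by the published rule.
#'
#' @param candidates data.frame with `gene1`, `gene2`, `pair_type`.
#' @param dep a [dependency_matrix()].
#' @param alt alteration matrix over cell lines.
#' @param min_altered strict lower bound on altered lines (pairs are tested
#'   only when `n_altered > min_altered`).
#' @param alpha FDR threshold.
#' @param sv_sign which sign of the screen coefficient counts as rescue:
#'   `"negative"` (the published rule, on the essentiality scale) or
#'   `"positive"`.
#' @return data.frame with per-pair `coefficient` (essentiality scale:
#'   negative = rescue), `dep_effect` (raw dependency scale), `p`, `fdr`,
#'   `n_altered`, `n_total`, `tested`, `passed`.
#' @export
run_screen <- function(candidates, dep, alt, min_altered = 10, alpha = 0.05,
                       sv_sign = c("negative", "positive")) {
  sv_sign <- match.arg(sv_sign)
  stopifnot(all(c("gene1", "gene2", "pair_type") %in% names(candidates)))
  n <- nrow(candidates)
  res <- candidates
  res$dep_effect <- res$p <- rep(NA_real_, n)
  res$n_altered <- res$n_total <- rep(NA_integer_, n)
  req <- required_states(candidates$pair_type)[, "gene2"]
  for (i in seq_len(n)) {
    if (is.na(req[i])) next
    if (!candidates$gene1[i] %in% rownames(dep$scores)) next
    s <- suppressMessages(
      screen_pair(candidates$gene1[i], candidates$gene2[i], dep, alt, req[i]))
    res$dep_effect[i] <- s$coefficient
    res$p[i] <- s$p
    res$n_altered[i] <- s$n_altered
    res$n_total[i] <- s$n_total
  }
  ## screen-convention coefficient: essentiality scale, rescue < 0
  res$coefficient <- -res$dep_effect
  res$tested <- !is.na(res$p) & !is.na(res$n_altered) & res$n_altered > min_altered
  res$fdr <- NA_real_
  if (any(res$tested)) {
    res$fdr[res$tested] <- bh_adjust(res$p[res$tested])
  } else {
    warning("no testable candidate pairs (all below the alteration threshold)")
  }
  rescue_sign <- if (sv_sign == "negative") res$coefficient < 0 else res$coefficient > 0
  res$passed <- res$tested & !is.na(res$fdr) & res$fdr < alpha & rescue_sign
  res
}
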