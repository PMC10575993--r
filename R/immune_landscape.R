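## Immune-landscape analytics: single-sample gene-set enrichment (ssGSEA)
## over immune signature sets, high/low-immune clustering, expression and
## score contrasts between risk groups, per-gene event enrichment and
## hypergeometric over-representation.

#' Single-sample gene-set enrichment scores
#'
#' Per sample, genes are ranked by expression (descending; ties take average
#' ranks). Walking down the ranking, the running sum rises by the gene's
#' rank-weight (rank value raised to `weight_exponent`, normalized to sum 1
#' within the set) for in-set genes and falls by 1/(N - set size) otherwise;
#' the score is the sum of the running-sum values over all positions
#' (integrated deviation). Optionally min-max normalized across samples per
#' set.
#'
#' @param expr expression matrix genes x samples.
#' @param sets named list of gene sets.
#' @param weight_exponent rank weighting exponent (default 0.25).
#' @param normalize min-max normalize scores across samples per set.
#' @return samples x sets numeric matrix; a set with no gene in the matrix
#'   yields an NA column (logged).
#' @export
ssgsea <- function(expr, sets, weight_exponent = 0.25, normalize = FALSE) {
  N <- nrow(expr)
  genes <- rownames(expr)
  sets_in <- lapply(sets, intersect, genes)
  empty <- lengths(sets_in) == 0
  if (any(empty)) message("set(s) with no gene in the matrix: ",
                          paste(names(sets)[empty], collapse = ", "))
  if (any(lengths(sets_in) == N)) stop("a gene set covers every gene; the out-of-set decrement is undefined")
  scores <- matrix(NA_real_, nrow = ncol(expr), ncol = length(sets),
                   dimnames = list(colnames(expr), names(sets)))
  for (s in seq_len(ncol(expr))) {
    x <- expr[, s]
    r <- rank(x, ties.method = "average")      # high expression -> high rank value
    ord <- order(x, decreasing = TRUE)
    w_all <- abs(r)^weight_exponent
    for (j in seq_along(sets)) {
      if (empty[j]) next
      m <- length(sets_in[[j]])
      in_set <- genes %in% sets_in[[j]]
      w <- w_all[ord]
      inc <- ifelse(in_set[ord], w, 0)
      inc <- inc / sum(inc)
      dec <- ifelse(in_set[ord], 0, 1 / (N - m))
      running <- cumsum(inc - dec)
      scores[s, j] <- sum(running)
    }
  }
  if (normalize) {
    for (j in seq_len(ncol(scores))) {
      v <- scores[, j]
      rng <- range(v, na.rm = TRUE)
      if (diff(rng) > 0) scores[, j] <- (v - rng[1]) / diff(rng)
    }
  }
  scores
}

#' The bundled synthetic immune signature collection (29 sets)
#'
#' A 29-set GMT shipped for testing and synthetic analyses; gene members are
#' synthetic symbols. For real analyses supply the published immune-process
#' GMTs instead.
#'
#' @return named list of 29 gene sets.
#' @export
immune_signature_sets <- function() {
  read_gmt(system.file("extdata", "immune_signatures_synthetic.gmt",
                       package = "synviab", mustWork = TRUE))
}

#' Cluster samples into high/low immune-infiltration groups
#'
#' k-means (10 restarts, fixed seed) on per-set z-scored ssGSEA scores; the
#' cluster with the larger mean raw score is labeled `high_immune`.
#' Hierarchical Ward clustering is available by flag.
#'
#' @param scores samples x sets score matrix.
#' @param k number of clusters (default 2).
#' @param seed RNG seed for k-means restarts.
#' @param method `"kmeans"` or `"ward"`.
#' @return factor per sample with levels `low_immune`, `high_immune` (k = 2)
#'   or integer cluster ids otherwise.
#' @export
cluster_immune <- function(scores, k = 2, seed = 1, method = c("kmeans", "ward")) {
  method <- match.arg(method)
  if (nrow(scores) < 2 * k) stop("need at least 2k samples to cluster")
  z <- scale(scores)
  z[!is.finite(z)] <- 0
  if (all(stats::dist(z) == 0)) stop("all samples identical; clustering degenerate")
  cl <- if (method == "kmeans") {
    set.seed(seed)
    stats::kmeans(z, centers = k, nstart = 10)$cluster
  } else {
    stats::cutree(stats::hclust(stats::dist(z), method = "ward.D2"), k = k)
  }
  if (k == 2) {
    means <- tapply(rowMeans(scores, na.rm = TRUE), cl, mean)
    high_id <- as.integer(names(which.max(means)))
    factor(ifelse(cl == high_id, "high_immune", "low_immune"),
           levels = c("low_immune", "high_immune"))
  } else {
    cl
  }
}

#' Per-variable contrast between risk groups (fold change, Wilcoxon, FDR)
#'
#' Fold change is mean(low)/mean(high); the one-sided Wilcoxon rank-sum test
#' has alternative "low greater"; Benjamini-Hochberg correction across the
#' variable family.
#'
#' @param values variables x samples numeric matrix (e.g. expression of a
#'   gene family, or ssGSEA scores transposed).
#' @param groups factor per sample with levels containing `low` and `high`.
#' @return data.frame per variable: `fold_change`, `p`, `fdr`.
#' @export
group_contrast <- function(values, groups) {
  groups <- as.character(groups)
  low <- grepl("low", groups); high <- grepl("high", groups)
  if (!any(low) || !any(high)) stop("both groups must be non-empty")
  vars <- rownames(values)
  fc <- p <- rep(NA_real_, nrow(values))
  for (i in seq_len(nrow(values))) {
    x <- values[i, low]; y <- values[i, high]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mh <- mean(y)
    fc[i] <- if (mh == 0) Inf else mean(x) / mh
    p[i] <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                               exact = length(c(x, y)) <= 50)$p.value)
  }
  if (any(!is.finite(fc))) message("zero mean in high group for ",
                                   sum(!is.finite(fc)), " variable(s); FC = Inf")
  data.frame(variable = vars, fold_change = fc, p = p, fdr = bh_adjust(p),
             row.names = NULL)
}

#' Within-group correlation structure of immune signatures
#'
#' Spearman correlations among signature columns within each risk group, and
#' a one-sided Wilcoxon test comparing the two groups' upper-triangle
#' coefficients (low greater).
#'
#' @param scores samples x sets score matrix.
#' @param groups factor per sample (levels containing `low`/`high`).
#' @return list: `cor_low`, `cor_high`, `p`.
#' @export
correlation_structure <- function(scores, groups) {
  groups <- as.character(groups)
  low <- grepl("low", groups); high <- grepl("high", groups)
  if (sum(low) < 3 || sum(high) < 3) stop("need at least 3 samples per group")
  cors <- function(idx) {
    suppressWarnings(stats::cor(scores[idx, , drop = FALSE], method = "spearman",
                                use = "pairwise.complete.obs"))
  }
  cl <- cors(low); ch <- cors(high)
  ut <- upper.tri(cl)
  x <- cl[ut]; y <- ch[ut]
  ok <- !is.na(x) & !is.na(y)
  p <- stats::wilcox.test(x[ok], y[ok], alternative = "greater",
                          exact = FALSE)$p.value
  list(cor_low = cl, cor_high = ch, p = p)
}

#' Per-gene event enrichment between risk groups
#'
#' One 2x2 Fisher test per gene (group x event) with Benjamini-Hochberg
#' correction across genes; genes with zero events shortcut to p = 1.
#'
#' @param events logical matrix genes x samples (e.g. mutated, or deep
#'   deletion).
#' @param groups factor per sample (levels containing `low`/`high`).
#' @param direction which group the events are tested for enrichment in.
#' @return data.frame per gene: counts, `p`, `fdr`.
#' @export
gene_level_enrichment <- function(events, groups, direction = c("low", "high")) {
  direction <- match.arg(direction)
  groups <- as.character(groups)
  low <- grepl("low", groups); high <- grepl("high", groups)
  if (!any(low) || !any(high)) stop("both groups must be non-empty")
  target <- if (direction == "low") low else high
  other <- if (direction == "low") high else low
  n <- nrow(events)
  p <- rep(1, n)
  a <- b <- integer(n)
  for (i in seq_len(n)) {
    e <- events[i, ]
    a[i] <- sum(e & target); b[i] <- sum(e & other)
    if (a[i] + b[i] == 0) next
    tab <- matrix(c(a[i], sum(target) - a[i], b[i], sum(other) - b[i]),
                  nrow = 2, byrow = TRUE)
    p[i] <- stats::fisher.test(tab, alternative = "greater")$p.value
  }
  data.frame(gene = rownames(events), events_target = a, events_other = b,
             p = p, fdr = bh_adjust(p), row.names = NULL)
}

#' Hypergeometric over-representation of a query gene list
#'
#' Upper-tail hypergeometric test per annotation set against a gene universe,
#' with Benjamini-Hochberg correction across sets.
#'
#' @param query character vector of genes (must be a subset of `universe`).
#' @param universe character vector of background genes.
#' @param sets named list of annotation gene sets.
#' @return data.frame per set: overlap `k`, set size in the universe, `p`,
#'   `fdr`.
#' @export
overrepresentation <- function(query, universe, sets) {
  query <- unique(query)
  if (!length(query)) stop("empty query gene list")
  if (!all(query %in% universe)) stop("query genes must be contained in the universe")
  N <- length(unique(universe))
  res <- lapply(names(sets), function(nm) {
    set_u <- intersect(sets[[nm]], universe)
    k <- length(intersect(query, set_u))
    data.frame(set = nm, k = k, set_size = length(set_u),
               p = hyper_upper_tail(k, length(query), length(set_u), N))
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  out
}
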