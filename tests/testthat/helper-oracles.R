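## Independent brute-force oracles used to pin the statistical kernels.
## These deliberately avoid the code paths (and where possible the library
## routines) they check.

## upper-tail hypergeometric P(X >= k) by direct summation of the pmf
oracle_hyper_tail <- function(k, n_draws, n_success, n_total) {
  if (k <= 0) return(1)
  j <- k:min(n_draws, n_success)
  sum(choose(n_success, j) * choose(n_total - n_success, n_draws - j)) /
    choose(n_total, n_draws)
}

## Benjamini-Hochberg step-up by the textbook definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## exact one-sided Fisher p (enrichment of cell [1,1]) by hypergeometric tail
oracle_fisher_greater <- function(tab) {
  a <- tab[1, 1]
  oracle_hyper_tail(a, sum(tab[1, ]), sum(tab[, 1]), sum(tab))
}

## exact one-sided Wilcoxon rank-sum p (x greater) by enumeration of all
## assignments of the pooled ranks; requires no ties
oracle_wilcox_greater <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(pooled), length(x))
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(w_all >= w_obs)
}

## rank AUC by direct pairwise comparison
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## Harrell's C by exhaustive pair enumeration
oracle_c_index <- function(risk, time, event) {
  n <- length(risk)
  conc <- comp <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      comp <- comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

## two-group log-rank chi-square from the per-event-time 2x2 tables
oracle_logrank <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  obs <- exp_ <- var_ <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    obs <- obs + d1
    exp_ <- exp_ + d * n1 / n
    if (n > 1) var_ <- var_ + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (obs - exp_)^2 / var_
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

## unweighted shortest path length by breadth-first search over an edge list
oracle_bfs_distance <- function(edges, from, to) {
  if (from == to) return(0)
  adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  seen <- from
  frontier <- from
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    if (to %in% nxt) return(d)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  Inf
}

## small toy annotation bundle used across feature tests
toy_bundle <- function() {
  list(
    ppi = data.frame(from = c("A", "B", "A", "C", "D"),
                     to = c("B", "C", "X", "X", "X"),
                     stringsAsFactors = FALSE),
    paralog_pairs = data.frame(gene1 = "A", gene2 = "D", stringsAsFactors = FALSE),
    complexes = list(cx1 = c("A", "C", "E"), cx2 = c("B", "D")),
    pathways = list(p1 = c("A", "C"), p2 = c("A", "C", "D"), p3 = c("C", "E")),
    go_bp = list(terms = list(A = "BP:t1", C = "BP:t2"),
                 parents = c("BP:t1" = "BP:t0", "BP:t2" = "BP:t0",
                             "BP:t0" = "BP:root")),
    go_mf = list(terms = list(), parents = character(0)),
    go_cc = list(terms = list(), parents = character(0)),
    compartments = list(A = "nucleus", C = c("nucleus", "cytosol")),
    essentiality = c(A = 0.2, B = 0.4, C = 0.6, D = 0.1, E = 0.5, X = 0.9),
    conservation = c(A = 0.8, C = 0.6),
    tsg_list = c("A", "B", "C"),
    oncogene_list = c("D", "E", "X")
  )
}

## tiny deterministic alteration matrix: genes x samples state matrix
toy_alt <- function(states, genes, samples) {
  m <- matrix(states, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  structure(m, class = c("alteration_matrix", "matrix"))
}
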