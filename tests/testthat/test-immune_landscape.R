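## independent running-sum computation for one sample/set (loop-free of the
## package's vectorized path)
oracle_ssgsea_one <- function(x, set, alpha = 0.25) {
  N <- length(x)
  genes <- names(x)
  r <- rank(x, ties.method = "average")
  ord <- order(x, decreasing = TRUE)
  running <- 0; total <- 0
  w_in <- sum(r[genes %in% set]^alpha)
  for (g in ord) {
    if (genes[g] %in% set) {
      running <- running + r[g]^alpha / w_in
    } else {
      running <- running - 1 / (N - length(intersect(set, genes)))
    }
    total <- total + running
  }
  as.numeric(total)
}

test_that("ssGSEA matches the hand-computed 5-gene running-sum table", {
  x <- c(A = 5, B = 4, C = 3, D = 2, E = 1)
  expr <- matrix(x, ncol = 1, dimnames = list(names(x), "S1"))
  got <- ssgsea(expr, list(set = c("A", "C")))["S1", "set"]
  ## ranks (desc value): A=5,B=4,C=3,D=2,E=1; in-set weights 5^.25, 3^.25
  w <- c(5, 3)^0.25; w <- w / sum(w)
  running <- cumsum(c(w[1], -1/3, w[2], -1/3, -1/3))
  expect_equal(unname(got), sum(running), tolerance = 1e-12)
  expect_equal(unname(got), oracle_ssgsea_one(x, c("A", "C")), tolerance = 1e-12)
})

test_that("a set at the top ranks maximizes the score; at the bottom minimizes", {
  genes <- paste0("g", 1:8)
  x <- setNames(8:1, genes)
  expr <- matrix(x, ncol = 1, dimnames = list(genes, "S1"))
  placements <- utils::combn(8, 3)
  scores <- apply(placements, 2, function(idx) {
    ssgsea(expr, list(s = genes[idx]))["S1", "s"]
  })
  top <- which(apply(placements, 2, function(i) all(i == 1:3)))
  bottom <- which(apply(placements, 2, function(i) all(i == 6:8)))
  expect_equal(which.max(scores), top)
  expect_equal(which.min(scores), bottom)
  expect_lt(scores[bottom], 0)
})

test_that("ssGSEA is rank-based: invariant under monotone transforms", {
  set.seed(61)
  genes <- paste0("g", 1:30)
  expr <- matrix(rnorm(30 * 4, 8, 2), nrow = 30,
                 dimnames = list(genes, paste0("S", 1:4)))
  sets <- list(a = sample(genes, 5), b = sample(genes, 8))
  base <- ssgsea(expr, sets)
  for (i in 1:20) {
    k <- runif(1, 0.5, 3); c0 <- runif(1, -5, 5)
    expect_equal(ssgsea(exp(k * expr) + c0, sets), base, tolerance = 1e-9)
  }
  ## degenerate: a set covering every gene
  expect_error(ssgsea(expr, list(all = genes)), "every gene")
  ## set with no gene present gives an NA column
  expect_message(s2 <- ssgsea(expr, list(a = sets$a, gone = c("zz1", "zz2"))),
                 "no gene")
  expect_true(all(is.na(s2[, "gone"])))
})

test_that("immune clustering separates blobs and is order-invariant", {
  set.seed(62)
  hi <- matrix(rnorm(20 * 5, 3), nrow = 20)
  lo <- matrix(rnorm(30 * 5, -3), nrow = 30)
  scores <- rbind(hi, lo)
  rownames(scores) <- paste0("S", 1:50)
  colnames(scores) <- paste0("set", 1:5)
  cl <- cluster_immune(scores, seed = 3)
  expect_equal(as.character(cl[1:20]), rep("high_immune", 20))
  expect_equal(as.character(cl[21:50]), rep("low_immune", 30))

  perm <- sample(50)
  cl_perm <- cluster_immune(scores[perm, ], seed = 3)
  expect_equal(as.character(cl_perm), as.character(cl)[perm])

  same <- matrix(1, 10, 3, dimnames = list(paste0("S", 1:10), paste0("t", 1:3)))
  expect_error(cluster_immune(same), "degenerate")
})

test_that("group contrasts report FC low/high with BH-corrected one-sided tests", {
  vals <- rbind(eq = rep(2, 10), dbl = rep(c(4, 2), each = 5),
                disj = c(16:20, 1:5))
  colnames(vals) <- paste0("S", 1:10)
  groups <- rep(c("low", "high"), each = 5)
  res <- group_contrast(vals, groups)
  expect_equal(res$fold_change[res$variable == "eq"], 1)
  expect_equal(res$fold_change[res$variable == "dbl"], 2)
  expect_equal(res$p[res$variable == "disj"], 1 / choose(10, 5), tolerance = 1e-12)
  expect_true(all(res$fdr >= res$p))
  ## family of one: FDR equals p
  res1 <- group_contrast(vals["disj", , drop = FALSE], groups)
  expect_equal(res1$fdr, res1$p)
})

test_that("correlation structure contrasts the upper-triangle coefficients", {
  set.seed(63)
  ## low-risk samples share a latent factor, high-risk independent
  latent <- rnorm(40)
  low <- sapply(1:5, function(i) latent + rnorm(40, 0, 0.4))
  high <- matrix(rnorm(40 * 5), ncol = 5)
  scores <- rbind(low, high)
  rownames(scores) <- paste0("S", 1:80)
  colnames(scores) <- paste0("set", 1:5)
  groups <- rep(c("low", "high"), each = 40)
  cs <- correlation_structure(scores, groups)
  expect_lt(cs$p, 0.05)
  expect_true(all(cs$cor_low[upper.tri(cs$cor_low)] > 0.5))
  ## duplicated group on both sides -> no signal
  cs0 <- correlation_structure(rbind(low, low), rep(c("low", "high"), each = 40))
  expect_gte(cs0$p, 0.5)
})

test_that("per-gene event enrichment has exact tails and a permutation null", {
  groups <- rep(c("low", "high"), each = 10)
  events <- rbind(perfect = rep(c(TRUE, FALSE), each = 10),
                  none = rep(FALSE, 20))
  colnames(events) <- paste0("S", 1:20)
  res <- gene_level_enrichment(events, groups, "low")
  expect_equal(res$p[res$gene == "perfect"], 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$p[res$gene == "none"], 1)

  ## permuted labels give a calibrated (super-uniform) p-value distribution:
  ## the exact test's discreteness allows P(p <= t) <= t but never an excess
  set.seed(64)
  e1 <- matrix(runif(20) < 0.4, nrow = 1, dimnames = list("g", paste0("S", 1:20)))
  pvals <- replicate(200, {
    gene_level_enrichment(e1, sample(groups), "low")$p
  })
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    se <- sqrt(t * (1 - t) / 200)
    expect_lte(mean(pvals <= t), t + 3 * se)
  }
})

test_that("over-representation uses the shared hypergeometric kernel", {
  universe <- paste0("u", 1:10)
  sets <- list(hit = universe[1:3], off = universe[8:10], all = universe)
  res <- overrepresentation(universe[1:3], universe, sets)
  expect_equal(res$p[res$set == "hit"], 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(res$p[res$set == "all"], 1)
  res2 <- overrepresentation(universe[4:6], universe, sets["off"])
  expect_equal(res2$p, 1)
  expect_error(overrepresentation(character(0), universe, sets), "empty")
  expect_error(overrepresentation("zz", universe, sets), "contained")
  ## same kernel as the shared-PPI feature
  for (i in 1:20) {
    k <- sample(0:3, 1)
    expect_equal(hyper_upper_tail(k, 3, 4, 10), oracle_hyper_tail(k, 3, 4, 10),
                 tolerance = 1e-12)
  }
})
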