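test_that("shared-PPI hypergeometric p matches closed forms and enumeration", {
  ## population 10, both genes with 3 neighbors, all 3 shared -> 1/C(10,3)
  edges <- data.frame(
    from = c(rep("g1", 3), rep("g2", 3)),
    to = c("n1", "n2", "n3", "n1", "n2", "n3"))
  filler <- data.frame(from = paste0("f", 1:7), to = "n1")
  res <- shared_ppi_pvalue("g1", "g2", rbind(edges, filler))
  ## nodes: g1,g2 + n1..n3 + f1..f7 = 12 -> N = 10
  expect_equal(res$k_shared, 3)
  expect_equal(res$p, 1 / choose(10, 3), tolerance = 1e-12)

  ## N=5, n1=2, n2=2, k=1 -> 1 - C(3,2)/C(5,2) = 0.7
  edges2 <- data.frame(from = c("g1", "g1", "g2", "g2", "a"),
                       to = c("s", "u1", "s", "u2", "b"))
  res2 <- shared_ppi_pvalue("g1", "g2", edges2)
  expect_equal(res2$k_shared, 1)
  expect_equal(res2$p, 0.7, tolerance = 1e-12)

  ## k = 0 -> p = 1
  edges3 <- data.frame(from = c("g1", "g2"), to = c("x", "y"))
  expect_equal(shared_ppi_pvalue("g1", "g2", edges3)$p, 1)

  ## random instances against the brute-force tail sum
  set.seed(1)
  for (i in 1:100) {
    N <- sample(4:12, 1)
    n1 <- sample(0:N, 1); n2 <- sample(0:N, 1)
    k <- sample(0:min(n1, n2), 1)
    expect_equal(hyper_upper_tail(k, n1, n2, N),
                 oracle_hyper_tail(k, n1, n2, N), tolerance = 1e-12)
  }
})

test_that("mean shared-PPI essentiality averages shared neighbors only", {
  b <- toy_bundle()
  ## A and C share neighbors B and X (essentiality 0.4, 0.9)
  expect_equal(mean_shared_ppi_essentiality("A", "C", b$ppi, b$essentiality), 0.65)
  expect_true(is.na(mean_shared_ppi_essentiality("B", "D", b$ppi, b$essentiality)))
  ## single shared neighbor returns its value
  expect_equal(mean_shared_ppi_essentiality("B", "D",
    data.frame(from = c("B", "D"), to = c("Z", "Z")), c(Z = 0.3)), 0.3)
})

test_that("reciprocal PPI distance matches a BFS oracle on random graphs", {
  b <- toy_bundle()
  expect_equal(avg_shortest_distance("A", "B", b$ppi)$score, 1)
  path <- data.frame(from = c("A", "B"), to = c("B", "C"))
  expect_equal(avg_shortest_distance("A", "C", path)$score, 0.5)
  two_comp <- data.frame(from = c("A", "C"), to = c("B", "D"))
  expect_equal(avg_shortest_distance("A", "C", two_comp)$score, 0)

  set.seed(2)
  for (i in 1:50) {
    n <- sample(5:12, 1)
    genes <- paste0("v", 1:n)
    m <- sample(n:(2 * n), 1)
    edges <- unique(data.frame(from = sample(genes, m, TRUE),
                               to = sample(genes, m, TRUE)))
    edges <- edges[edges$from != edges$to, ]
    if (!nrow(edges)) next
    vs <- unique(c(edges$from, edges$to))
    pick <- sample(vs, 2)
    got <- avg_shortest_distance(pick[1], pick[2], edges)$distance
    expect_equal(got, oracle_bfs_distance(edges, pick[1], pick[2]))
  }
})

test_that("GO similarity is the Jaccard of ancestor closures, root excluded", {
  b <- toy_bundle()
  ## closures: {t1,t0} vs {t2,t0} -> 1/3
  expect_equal(go_similarity("A", "C", b$go_bp), 1 / 3)
  same <- list(terms = list(A = "BP:t1", B = "BP:t1"),
               parents = c("BP:t1" = "BP:root"))
  expect_equal(go_similarity("A", "B", same), 1)
  disjoint <- list(terms = list(A = "BP:t1", B = "BP:t2"),
                   parents = c("BP:t1" = "BP:root", "BP:t2" = "BP:root"))
  expect_equal(go_similarity("A", "B", disjoint), 0)
  expect_true(is.na(go_similarity("A", "ZZ", b$go_bp)))
})

test_that("co-expression is the Spearman correlation with rank edge cases", {
  e <- rbind(A = c(1, 2, 3), B = c(1, 3, 2), C = c(3, 2, 1), D = c(2, 4, 6),
             K = c(5, 5, 5))
  colnames(e) <- paste0("S", 1:3)
  expect_equal(coexpression("A", "D", e), 1)
  expect_equal(coexpression("A", "C", e), -1)
  expect_equal(coexpression("A", "B", e), 0.5)
  expect_true(is.na(coexpression("A", "K", e)))   # constant profile
})

test_that("boolean features follow their membership and Fisher rules", {
  b <- toy_bundle()
  alt2 <- toy_alt(c(rep("LOF", 25), rep("WT", 75),
                    rep("LOF", 20), rep("WT", 80)),
                  genes = c("A", "C"), samples = paste0("S", 1:100))
  co <- cooccurring_alteration("A", "C", alt2)
  expect_equal(co$table[1, 1], 20)
  expect_equal(co$p, oracle_fisher_greater(co$table), tolerance = 1e-12)
  expect_lt(co$p, 0.05)

  feat <- compute_pair_features(data.frame(gene1 = "A", gene2 = "D"), b)
  expect_equal(feat$paralog, 1)
  expect_equal(feat$complex_membership, 0)
  feat2 <- compute_pair_features(data.frame(gene1 = "A", gene2 = "C"), b)
  expect_equal(feat2$complex_membership, 1)
  expect_equal(feat2$pathway_number, 2)
  expect_equal(feat2$colocalization, 0.5)
  expect_equal(feat2$conservation, 0.7)
})

test_that("feature AUC matches enumeration and is monotone-invariant", {
  tab <- data.frame(f = c(2, 3, 1, 2), label = c("SV", "SV", "non-SV", "non-SV"))
  expect_equal(feature_auc(tab, "f"), 0.875)
  expect_equal(feature_auc(data.frame(f = c(5, 6, 1, 2),
                                      label = c("SV", "SV", "non-SV", "non-SV")), "f"), 1)
  expect_equal(feature_auc(data.frame(f = rep(1, 6),
                                      label = rep(c("SV", "non-SV"), 3)), "f"), 0.5)

  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(30)
    lab <- sample(c(TRUE, FALSE), 30, TRUE)
    if (length(unique(lab)) < 2) next
    a1 <- rank_auc(x, lab)
    a2 <- rank_auc(exp(2 * x) + 5, lab)   # strictly monotone transform
    expect_equal(a1, a2, tolerance = 1e-12)
    expect_equal(a1, oracle_auc(x, lab), tolerance = 1e-12)
  }
})

test_that("one-sided feature contrast has exact small-sample tails", {
  tab <- data.frame(f = c(10, 11, 12, 1, 2, 3),
                    label = c("SV", "SV", "SV", "non-SV", "non-SV", "non-SV"))
  expect_equal(feature_contrast(tab, "f"), 0.05, tolerance = 1e-12)  # 1/20
  rev_tab <- tab; rev_tab$label <- rev(tab$label)
  expect_gt(feature_contrast(rev_tab, "f"), 0.9)
  same <- data.frame(f = rep(c(1, 2, 7), 2), label = rep(c("SV", "non-SV"), each = 3))
  expect_gte(feature_contrast(same, "f"), 0.5)
})

test_that("enriched synthetic features separate SV from background pairs", {
  hits <- 0
  n_seeds <- 6
  enriched <- c("shared_ppi", "bp_similarity", "coexpression", "paralog",
                "complex_membership", "pathway_number", "colocalization",
                "conservation")
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(seed = 100 + s, n_genes = 120, n_cell_lines = 60,
                             n_true_sv_pairs = 25)
    panel <- simulate_panel(cfg)
    pairs <- rbind(panel$truth$true_sv_pairs[, 1:2],
                   background_pairs(panel, 75, seed = s)[, 1:2])
    feat <- compute_pair_features(pairs, panel$bundle, panel$expr,
                                  features = enriched)
    feat$label <- rep(c("SV", "non-SV"), c(25, 75))
    aucs <- vapply(enriched, function(f) feature_auc(feat, f), numeric(1))
    if (all(aucs > 0.5)) hits <- hits + 1
  }
  expect_gte(hits, n_seeds - 1)
})
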