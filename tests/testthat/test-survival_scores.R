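test_that("sv_score counts pairs whose both genes carry their required states", {
  alt <- toy_alt(c("LOF", "WT",    # A
                   "LOF", "WT",    # B
                   "LOF", "LOF",   # C
                   "WT", "WT"),    # D
                 genes = c("A", "B", "C", "D"), samples = c("S1", "S2"))
  pairs <- data.frame(gene1 = c("A", "C"), gene2 = c("B", "D"),
                      pair_type = c("TSGL_TSGL", "TSGL_OGG"))
  sc <- sv_score(alt, pairs)
  expect_equal(unname(sc), c(1L, 0L))   # S1: A+B LOF; C LOF but D WT. S2: none

  ## all-WT sample scores zero; missing gene pairs are skipped with a message
  expect_message(sc2 <- sv_score(alt, rbind(pairs,
    data.frame(gene1 = "A", gene2 = "ZZ", pair_type = "TSGL_TSGL"))), "skipped")
  expect_equal(sc2, sc)
})

test_that("sv_score equals a brute-force recount on random instances", {
  set.seed(31)
  for (rep in 1:20) {
    genes <- paste0("g", 1:12)
    samples <- paste0("s", 1:15)
    states <- matrix(sample(c("WT", "LOF", "GOF", "AMBIGUOUS"), 180, TRUE,
                            prob = c(0.6, 0.2, 0.15, 0.05)),
                     nrow = 12, dimnames = list(genes, samples))
    pairs <- data.frame(gene1 = sample(genes, 5), gene2 = sample(genes, 5),
                        pair_type = sample(c("TSGL_TSGL", "OGL_OGG", "TSGL_OGG"),
                                           5, TRUE))
    pairs <- pairs[pairs$gene1 != pairs$gene2, ]
    got <- sv_score(states, pairs)
    req <- required_states(pairs$pair_type)
    want <- vapply(samples, function(s) {
      sum(vapply(seq_len(nrow(pairs)), function(i) {
        states[pairs$gene1[i], s] == req[i, 1] &&
          states[pairs$gene2[i], s] == req[i, 2]
      }, logical(1)))
    }, numeric(1))
    expect_equal(unname(got), unname(want))
    ## conservation: total co-occurrence events match
    expect_equal(sum(got), sum(want))
  }
})

test_that("drug_score counts altered partners", {
  alt <- toy_alt(c("LOF", "GOF", "WT", "LOF", "WT", "WT"),
                 genes = c("A", "B", "C"), samples = c("S1", "S2"))
  partners <- data.frame(gene = c("A", "B", "C"),
                         required_state = c("LOF", "LOF", "GOF"))
  expect_equal(unname(drug_score(alt, partners)), c(1L, 1L))
  expect_equal(unname(drug_score(alt, partners[0, ])), c(0L, 0L))
})

test_that("median dichotomization puts ties at the median into the low group", {
  g <- score_groups(c(0, 1, 1, 2, 5))
  expect_equal(as.character(g), c("low", "low", "low", "high", "high"))
})

test_that("log-rank matches a hand-computed toy and degenerates correctly", {
  ## identical groups -> chisq 0, p 1
  km0 <- km_curve(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                  rep(c("a", "b"), each = 3))
  expect_equal(km0$chisq, 0, tolerance = 1e-12)
  expect_equal(km0$p, 1)

  ## 6-patient toy against the per-event-time 2x2 oracle
  time <- c(2, 4, 6, 1, 3, 5); event <- c(1, 1, 0, 1, 1, 1)
  group <- rep(c("hi", "lo"), each = 3)
  km <- km_curve(time, event, group)
  o <- oracle_logrank(time, event, group)
  expect_equal(km$chisq, o$chisq, tolerance = 1e-8)
  expect_equal(km$p, o$p, tolerance = 1e-8)

  ## KM curves start at 1 and are non-increasing
  s <- summary(km$fit)
  expect_true(all(s$surv <= 1))
  expect_true(all(diff(s$surv[s$strata == s$strata[1]]) <= 0))

  expect_error(km_curve(c(1, 2), c(0, 0), c("a", "b")), "no events")
  expect_error(km_curve(c(1, 2), c(1, 1), c("a", "a")), "group")
})

test_that("Cox fits are deterministic and reject degenerate designs", {
  set.seed(41)
  n <- 80
  x <- rnorm(n)
  time <- rexp(n, exp(0.5 * x) / 50)
  event <- rbinom(n, 1, 0.8)
  cov <- data.frame(x = x, age = rnorm(n, 60, 8))
  fit1 <- cox_multivariate(time, event, cov)
  expect_identical(fit1$coef, cox_multivariate(time, event, cov)$coef)
  ## duplicating every patient introduces ties but barely moves the estimate
  fit2 <- cox_multivariate(rep(time, 2), rep(event, 2), rbind(cov, cov))
  expect_equal(fit1$coef, fit2$coef, tolerance = 0.05)
  expect_equal(fit1$hr, exp(fit1$coef), tolerance = 1e-12)
  expect_error(cox_multivariate(time, event, data.frame(k = rep(1, n))),
               "constant")
})

test_that("concordance index matches brute force and its symmetry identity", {
  expect_equal(c_index(c(4, 3, 2, 1), c(1, 2, 3, 4), rep(1, 4)), 1)
  expect_equal(c_index(rep(1, 4), c(1, 2, 3, 4), rep(1, 4)), 0.5)

  risk <- c(2, 1, 3, 2); time <- c(5, 3, 9, 7); event <- c(1, 1, 0, 1)
  expect_equal(c_index(risk, time, event), oracle_c_index(risk, time, event),
               tolerance = 1e-12)

  set.seed(42)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    risk <- rnorm(n); time <- rexp(n); event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) next
    got <- try(c_index(risk, time, event), silent = TRUE)
    if (inherits(got, "try-error")) next
    expect_equal(got, oracle_c_index(risk, time, event), tolerance = 1e-12)
    ## no ties in risk: complementarity
    expect_equal(got + c_index(-risk, time, event), 1, tolerance = 1e-12)
    ## independent implementation in the survival package agrees
    conc <- survival::concordance(survival::Surv(time, event) ~ risk,
                                  reverse = TRUE)
    expect_equal(got, unname(conc$concordance), tolerance = 1e-12)
  }
})

test_that("response AUC treats non-responders as positives", {
  scores <- c(5, 4, 1, 2)
  responder <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(response_auc(scores, responder), 1)
  expect_equal(response_auc(c(2, 3, 1, 2), c(FALSE, FALSE, TRUE, TRUE)), 0.875)
  expect_error(response_auc(scores, rep(TRUE, 4)), "class")
})
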