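## alteration matrix for the 12 signature genes with chosen term indicators
signature_alt <- function(active_terms, n_patients = 1) {
  model <- default_risk_model()
  genes <- unique(c(model$terms$gene1, model$terms$gene2))
  m <- matrix("WT", nrow = length(genes), ncol = n_patients,
              dimnames = list(genes, paste0("P", seq_len(n_patients))))
  for (i in active_terms) {
    m[model$terms$gene1[i], 1] <- model$terms$state1[i]
    m[model$terms$gene2[i], 1] <- model$terms$state2[i]
  }
  structure(m, class = c("alteration_matrix", "matrix"))
}

test_that("RiskScore is exp of the coefficient-weighted indicators with cutoff 1", {
  model <- default_risk_model()
  expect_equal(nrow(model$terms), 6)
  expect_equal(model$cutoff, 1)

  r0 <- risk_score(signature_alt(integer(0)), model)
  expect_equal(r0$risk_score, 1)                       # exp(0)
  expect_equal(as.character(r0$risk_group), "low")     # not strictly > cutoff

  r5 <- risk_score(signature_alt(5), model)            # EIF3E_L:PIK3R1_L only
  expect_equal(r5$risk_score, exp(-1.13), tolerance = 1e-12)
  expect_equal(as.character(r5$risk_group), "low")

  r_all <- risk_score(signature_alt(1:6), model)
  expect_equal(r_all$risk_score, exp(0.96 + 0.92 + 1.06 + 0.98 - 1.13 + 0.98),
               tolerance = 1e-12)
  expect_equal(r_all$risk_score, exp(3.77), tolerance = 1e-12)
  expect_equal(as.character(r_all$risk_group), "high")
})

test_that("RiskScore is log-linear and threshold-consistent", {
  model <- default_risk_model()
  s <- function(terms) risk_score(signature_alt(terms), model)$risk_score
  ## multiplicative over disjoint indicator sets
  expect_equal(s(c(1, 3)) * s(c(2, 5)) / s(integer(0)), s(c(1, 2, 3, 5)),
               tolerance = 1e-12)
  ## positive coefficients increase, the negative term decreases
  for (i in c(1, 2, 3, 4, 6)) expect_gt(s(i), s(integer(0)))
  expect_lt(s(5), s(integer(0)))
  ## raising the cutoff never moves a patient low -> high
  alt <- signature_alt(c(1, 5))
  g1 <- risk_score(alt, risk_model(model$terms, cutoff = 0.5))$risk_group
  g2 <- risk_score(alt, risk_model(model$terms, cutoff = 2))$risk_group
  expect_false(g1 == "low" && g2 == "high")
  ## missing signature genes give indicator 0, with a message
  tiny <- structure(matrix("WT", 1, 1, dimnames = list("JUN", "P1")),
                    class = c("alteration_matrix", "matrix"))
  expect_message(rt <- risk_score(tiny, model), "not in alteration matrix")
  expect_equal(rt$risk_score, 1)
})

test_that("univariate preselection recovers an informative pair and stays calibrated", {
  ## power: one pair with true log-HR 1 retained in nearly all seeds
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 300
    x <- rbinom(n, 1, 0.3)
    time <- rexp(n, exp(1 * x) / 200)
    alt <- structure(
      rbind(A = ifelse(x == 1, "LOF", "WT"), B = ifelse(x == 1, "LOF", "WT"),
            C = sample(c("LOF", "WT"), n, TRUE), D = sample(c("LOF", "WT"), n, TRUE)),
      dimnames = list(c("A", "B", "C", "D"), paste0("P", 1:n)),
      class = c("alteration_matrix", "matrix"))
    clin <- data.frame(patient = paste0("P", 1:n), os_time = time,
                       os_event = rep(1L, n))
    cand <- data.frame(gene1 = c("A", "C"), gene2 = c("B", "D"),
                       pair_type = "TSGL_TSGL")
    sel <- suppressMessages(select_pairs_univariate(cand, alt, clin))
    if ("A" %in% sel$selected$gene1) hits <- hits + 1
  }
  expect_gte(hits, 9)
  ## the refit model carries the retained terms with cutoff 1
  expect_s3_class(sel$model, "risk_model")
  expect_equal(sel$model$cutoff, 1)
  ## empty candidate list
  empty <- select_pairs_univariate(cand[0, ], alt, clin)
  expect_equal(nrow(empty$selected), 0)
  expect_null(empty$model)
})

test_that("responder rules implement the cohort-specific RECIST definitions", {
  clin <- data.frame(patient = paste0("P", 1:5),
                     response = c("CR", "PR", "PD", "SD", "SD"),
                     sd_duration_months = c(NA, NA, NA, 7, 5))
  expect_equal(responder_labels(clin, "liu"), c(TRUE, TRUE, FALSE, NA, NA))
  expect_equal(responder_labels(clin, "gide"), c(TRUE, TRUE, FALSE, TRUE, FALSE))
  clin$sd_duration_months[4] <- NA
  expect_message(lab <- responder_labels(clin, "gide"), "without duration")
  expect_true(is.na(lab[4]))
})

test_that("response association has exact Fisher/Wilcoxon tails", {
  risks <- data.frame(patient = paste0("P", 1:10),
                      risk_score = c(10:6, 5:1) / 10,
                      risk_group = factor(rep(c("high", "low"), each = 5),
                                          levels = c("low", "high")))
  clin <- data.frame(patient = paste0("P", 1:10),
                     response = rep(c("PD", "CR"), each = 5),
                     sd_duration_months = NA_real_)
  ra <- response_association(risks, clin, "liu")
  expect_equal(ra$fisher_p, 1 / choose(10, 5), tolerance = 1e-12)   # 1/252
  expect_equal(ra$wilcoxon_p, 1 / choose(10, 5), tolerance = 1e-12)
  ## balanced table -> no enrichment signal
  clin2 <- clin; clin2$response <- rep(c("PD", "CR"), 5)
  ra2 <- response_association(risks, clin2, "liu")
  expect_gte(ra2$fisher_p, 0.5)
})

test_that("burden comparisons favor the low-risk direction with exact tails", {
  risks <- data.frame(patient = paste0("P", 1:10),
                      risk_score = 1:10,
                      risk_group = factor(rep(c("low", "high"), each = 5),
                                          levels = c("low", "high")))
  clin <- data.frame(patient = paste0("P", 1:10),
                     tmb = c(16:20, 1:5),
                     neoantigen_load = c(26:30, 11:15))
  bc <- suppressWarnings(burden_comparisons(risks, clin))
  expect_equal(unname(bc$wilcoxon["tmb"]), 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(unname(bc$wilcoxon["neoantigen_load"]), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_true(is.na(bc$wilcoxon["cytolytic"]))
  expect_lt(bc$tmb_fisher_p, 0.05)
  ## identical groups are not significant
  clin_same <- data.frame(patient = paste0("P", 1:10), tmb = rep(c(3, 9), 5))
  bc2 <- suppressWarnings(burden_comparisons(risks, clin_same,
                                             variables = "tmb"))
  expect_gte(unname(bc2$wilcoxon["tmb"]), 0.5)
})

test_that("cytolytic score is the geometric mean of GZMA and PRF1", {
  e <- rbind(GZMA = c(4, 0, 7), PRF1 = c(9, 5, 7))
  colnames(e) <- paste0("S", 1:3)
  expect_equal(unname(cytolytic_score(e)), c(6, 0, 7))
  e2 <- rbind(GZMA = c(4, 1, 1)); colnames(e2) <- paste0("S", 1:3)
  expect_true(all(is.na(cytolytic_score(e2))))
})

test_that("signature comparison returns consistent C-indexes and correlations", {
  set.seed(55)
  n <- 60
  risk <- runif(n, 0.2, 5)
  clin <- data.frame(patient = paste0("P", 1:n),
                     os_time = rexp(n, risk / 300), os_event = rbinom(n, 1, 0.8))
  risks <- data.frame(patient = clin$patient, risk_score = risk,
                      risk_group = score_groups(risk))
  competing <- data.frame(patient = clin$patient, same = risk, flipped = -risk,
                          noise = rnorm(n))
  sc <- signature_comparison(risks, competing, clin)
  expect_equal(unname(sc$c_index["same"]), unname(sc$c_index["sv_signature"]),
               tolerance = 1e-12)
  expect_equal(unname(sc$spearman["sv_signature", "same"]), 1, tolerance = 1e-12)
  expect_equal(unname(sc$spearman["sv_signature", "flipped"]), -1, tolerance = 1e-12)
  expect_gt(unname(sc$c_index["sv_signature"]), unname(sc$c_index["noise"]))
})
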