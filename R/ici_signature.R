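## The six-SV-pair ICI-resistance risk model for melanoma. RiskScore =
## exp(sum of coefficient x pair-alteration indicator) over six fixed pair
## terms; patients with RiskScore strictly above the cutoff (1) are high-risk
## (predicted ICI-resistant). The shipped default hard-codes the published
## terms and coefficients; select_pairs_univariate() provides the
## re-derivation mechanism for new cohorts but is not used to regenerate the
## defaults.

#' The default six-pair risk model
#'
#' Six gene-pair terms with fixed Cox coefficients and dichotomization cutoff
#' 1: JUN_L:NR4A3_G (0.96), CASP3_L:BCL2L12_G (0.92), ETV6_L:FGFR2_G (1.06),
#' BCL10_L:CBLC_G (0.98), EIF3E_L:PIK3R1_L (-1.13), RUNX1_L:LCK_L (0.98).
#'
#' @return list of class `risk_model` with `terms` (data.frame gene1, state1,
#'   gene2, state2, coefficient) and `cutoff`.
#' @export
default_risk_model <- function() {
  terms <- data.frame(
    gene1 = c("JUN", "CASP3", "ETV6", "BCL10", "EIF3E", "RUNX1"),
    state1 = "LOF",
    gene2 = c("NR4A3", "BCL2L12", "FGFR2", "CBLC", "PIK3R1", "LCK"),
    state2 = c("GOF", "GOF", "GOF", "GOF", "LOF", "LOF"),
    coefficient = c(0.96, 0.92, 1.06, 0.98, -1.13, 0.98),
    stringsAsFactors = FALSE
  )
  risk_model(terms, cutoff = 1)
}

#' Construct a risk model
#'
#' @param terms data.frame with columns `gene1`, `state1`, `gene2`, `state2`,
#'   `coefficient`.
#' @param cutoff dichotomization cutoff on the RiskScore scale.
#' @return list of class `risk_model`.
#' @export
risk_model <- function(terms, cutoff = 1) {
  need <- c("gene1", "state1", "gene2", "state2", "coefficient")
  stopifnot(all(need %in% names(terms)),
            all(terms$state1 %in% c("LOF", "GOF")),
            all(terms$state2 %in% c("LOF", "GOF")))
  structure(list(terms = terms[, need], cutoff = cutoff), class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> ", nrow(x$terms), " pair terms, cutoff ", x$cutoff, "\n", sep = "")
  print(x$terms)
  invisible(x)
}

#' RiskScore and risk group per patient
#'
#' Each term's indicator is 1 iff both genes carry their required states in
#' the patient; the score is exp of the coefficient-weighted indicator sum;
#' patients strictly above the cutoff are high-risk. Genes missing from the
#' alteration matrix contribute indicator 0 (logged once).
#'
#' @param alt alteration matrix genes x patients.
#' @param model a `risk_model` (default the published six-pair model).
#' @return data.frame: `patient`, one indicator column per term
#'   (`ind_<gene1>_<gene2>`), `risk_score`, `risk_group` (factor low/high).
#' @export
risk_score <- function(alt, model = default_risk_model()) {
  patients <- colnames(alt)
  terms <- model$terms
  ind <- matrix(0L, nrow = length(patients), ncol = nrow(terms))
  missing_genes <- setdiff(unique(c(terms$gene1, terms$gene2)), rownames(alt))
  if (length(missing_genes)) {
    message("signature gene(s) not in alteration matrix, indicators set 0: ",
            paste(missing_genes, collapse = ", "))
  }
  for (i in seq_len(nrow(terms))) {
    g1 <- terms$gene1[i]; g2 <- terms$gene2[i]
    if (g1 %in% rownames(alt) && g2 %in% rownames(alt)) {
      ind[, i] <- as.integer(alt[g1, ] == terms$state1[i] &
                               alt[g2, ] == terms$state2[i])
    }
  }
  score <- exp(as.vector(ind %*% terms$coefficient))
  out <- data.frame(patient = patients, ind, risk_score = score,
                    risk_group = factor(ifelse(score > model$cutoff, "high", "low"),
                                        levels = c("low", "high")),
                    stringsAsFactors = FALSE)
  names(out)[1 + seq_len(nrow(terms))] <- paste0("ind_", terms$gene1, "_", terms$gene2)
  out
}

#' Univariate Cox preselection and multivariate refit of a pair signature
#'
#' Per candidate pair, a univariate Cox model of survival on the pair's
#' co-alteration indicator; pairs with p < `alpha` are retained and jointly
#' refit in a multivariate Cox model whose coefficients define a new
#' [risk_model()] (cutoff 1). Constant indicators are skipped (logged).
#'
#' @param candidates data.frame with `gene1`, `gene2`, `pair_type`.
#' @param alt alteration matrix genes x patients.
#' @param clinical clinical data.frame with `patient`, `os_time`, `os_event`.
#' @param alpha retention threshold on the univariate p-value.
#' @return list with `univariate` (per-pair coef/p), `selected` (retained
#'   pairs), and `model` (refit `risk_model`, NULL when nothing is retained).
#' @export
select_pairs_univariate <- function(candidates, alt, clinical, alpha = 0.05) {
  validate_clinical(clinical)
  patients <- intersect(colnames(alt), clinical$patient)
  clin <- clinical[match(patients, clinical$patient), ]
  req <- required_states(candidates$pair_type)
  n <- nrow(candidates)
  uni <- cbind(candidates,
               data.frame(coef = rep(NA_real_, n), p = rep(NA_real_, n)))
  indicators <- matrix(NA_integer_, nrow = length(patients), ncol = n)
  for (i in seq_len(n)) {
    g1 <- candidates$gene1[i]; g2 <- candidates$gene2[i]
    if (is.na(req[i, 1]) || !(g1 %in% rownames(alt)) || !(g2 %in% rownames(alt))) next
    x <- as.integer(alt[g1, patients] == req[i, "gene1"] &
                      alt[g2, patients] == req[i, "gene2"])
    indicators[, i] <- x
    if (length(unique(x)) < 2) {
      message("constant indicator, pair skipped: ", g1, "-", g2)
      next
    }
    fit <- survival::coxph(survival::Surv(clin$os_time, clin$os_event) ~ x,
                           ties = "efron")
    s <- summary(fit)$coefficients
    uni$coef[i] <- s[1, "coef"]
    uni$p[i] <- s[1, "Pr(>|z|)"]
  }
  sel <- which(!is.na(uni$p) & uni$p < alpha)
  model <- NULL
  if (length(sel)) {
    x <- as.data.frame(indicators[, sel, drop = FALSE])
    names(x) <- paste0("pair", sel)
    fit <- survival::coxph(
      survival::Surv(clin$os_time, clin$os_event) ~ .,
      data = cbind(data.frame(x)), ties = "efron")
    co <- stats::coef(fit)
    terms <- data.frame(
      gene1 = candidates$gene1[sel], state1 = req[sel, "gene1"],
      gene2 = candidates$gene2[sel], state2 = req[sel, "gene2"],
      coefficient = unname(co), stringsAsFactors = FALSE)
    model <- risk_model(terms, cutoff = 1)
  }
  list(univariate = uni, selected = candidates[sel, , drop = FALSE], model = model)
}

#' Resolve RECIST responder labels under a cohort rule
#'
#' `"liu"`: CR/PR responders, PD non-responders, SD excluded (NA).
#' `"gide"`: CR/PR responders; SD with duration > 6 months responders, SD
#' with 6 months or less non-responders, SD without a duration NA (logged);
#' PD non-responders.
#'
#' @param clinical clinical data.frame with `response` and (for gide)
#'   `sd_duration_months`.
#' @param rule `"liu"` or `"gide"`.
#' @return logical vector (TRUE = responder, NA = unresolvable).
#' @export
responder_labels <- function(clinical, rule = c("liu", "gide")) {
  rule <- match.arg(rule)
  r <- clinical$response
  out <- rep(NA, nrow(clinical))
  out[r %in% c("CR", "PR")] <- TRUE
  out[r %in% "PD"] <- FALSE
  if (rule == "gide") {
    sd_idx <- which(r %in% "SD")
    dur <- clinical$sd_duration_months[sd_idx]
    out[sd_idx] <- ifelse(is.na(dur), NA, dur > 6)
    if (anyNA(dur)) message(sum(is.na(dur)), " SD patient(s) without duration excluded")
  }
  out
}

#' Risk-group vs response association
#'
#' One-sided Fisher exact test of non-response enrichment in the high-risk
#' group, plus a one-sided Wilcoxon rank-sum test of risk scores
#' (non-responders greater).
#'
#' @param risks output of [risk_score()].
#' @param clinical clinical table (matched on `patient`).
#' @param rule responder rule, see [responder_labels()].
#' @return list: 2x2 `table` (risk group x response), `fisher_p`,
#'   `wilcoxon_p`.
#' @export
response_association <- function(risks, clinical, rule = c("liu", "gide")) {
  rule <- match.arg(rule)
  m <- match(risks$patient, clinical$patient)
  resp <- responder_labels(clinical[m, , drop = FALSE], rule)
  keep <- !is.na(resp)
  grp <- risks$risk_group[keep]; resp <- resp[keep]
  score <- risks$risk_score[keep]
  tab <- matrix(c(sum(grp == "high" & !resp), sum(grp == "high" & resp),
                  sum(grp == "low" & !resp), sum(grp == "low" & resp)),
                nrow = 2, byrow = TRUE,
                dimnames = list(risk = c("high", "low"),
                                response = c("non_response", "response")))
  fisher_p <- stats::fisher.test(tab, alternative = "greater")$p.value
  x <- score[!resp]; y <- score[resp]
  if (!length(x) || !length(y)) stop("both response classes required")
  if (stats::sd(c(x, y)) == 0) stop("zero-variance risk scores")
  wil <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                            exact = length(c(x, y)) <= 50)$p.value)
  list(table = tab, fisher_p = fisher_p, wilcoxon_p = wil)
}

#' TMB / neoantigen / cytolytic comparisons between risk groups
#'
#' One-sided Wilcoxon tests with alternative "low-risk greater" for each
#' available burden variable, plus a one-sided Fisher test of high-TMB
#' proportion (median split by default) being enriched in low-risk patients.
#'
#' @param risks output of [risk_score()].
#' @param clinical clinical table with any of `tmb`, `neoantigen_load`,
#'   `cytolytic`.
#' @param variables variables to compare.
#' @param tmb_cutoff high-TMB threshold; default the cohort median.
#' @return list: `wilcoxon` (named p-values, NA when a variable is absent),
#'   `tmb_fisher_p`, `tmb_table`.
#' @export
burden_comparisons <- function(risks, clinical,
                               variables = c("tmb", "neoantigen_load", "cytolytic"),
                               tmb_cutoff = NULL) {
  m <- match(risks$patient, clinical$patient)
  clin <- clinical[m, , drop = FALSE]
  low <- risks$risk_group == "low"
  wil <- stats::setNames(rep(NA_real_, length(variables)), variables)
  for (v in variables) {
    if (!v %in% names(clin)) {
      warning("variable absent, skipped: ", v)
      next
    }
    x <- clin[[v]][low]; y <- clin[[v]][!low]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      warning("too few values for ", v)
      next
    }
    wil[v] <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                 exact = length(c(x, y)) <= 50)$p.value)
  }
  tmb_fisher_p <- NA_real_; tmb_table <- NULL
  if ("tmb" %in% names(clin) && any(!is.na(clin$tmb))) {
    if (is.null(tmb_cutoff)) tmb_cutoff <- stats::median(clin$tmb, na.rm = TRUE)
    high_tmb <- clin$tmb > tmb_cutoff
    ok <- !is.na(high_tmb)
    tmb_table <- matrix(c(sum(low & high_tmb & ok), sum(low & !high_tmb & ok),
                          sum(!low & high_tmb & ok), sum(!low & !high_tmb & ok)),
                        nrow = 2, byrow = TRUE,
                        dimnames = list(risk = c("low", "high"),
                                        tmb = c("high_tmb", "low_tmb")))
    tmb_fisher_p <- stats::fisher.test(tmb_table, alternative = "greater")$p.value
  }
  list(wilcoxon = wil, tmb_fisher_p = tmb_fisher_p, tmb_table = tmb_table)
}

#' Cytolytic activity score
#'
#' Geometric mean of GZMA and PRF1 expression (linear scale, non-negative).
#'
#' @param expr expression matrix genes x samples, linear scale.
#' @param sample sample id(s); default all.
#' @return numeric vector; NA when either gene is absent.
#' @export
cytolytic_score <- function(expr, sample = colnames(expr)) {
  if (!all(c("GZMA", "PRF1") %in% rownames(expr))) {
    return(stats::setNames(rep(NA_real_, length(sample)), sample))
  }
  g <- expr["GZMA", sample]; p <- expr["PRF1", sample]
  if (any(g < 0 | p < 0, na.rm = TRUE)) stop("cytolytic score needs non-negative linear-scale expression")
  stats::setNames(sqrt(g * p), sample)
}

#' Compare the risk signature with competing per-patient scores
#'
#' Harrell's C-index per score against the cohort's survival outcome, plus
#' the pairwise Spearman correlation matrix among all scores.
#'
#' @param risks output of [risk_score()].
#' @param competing data.frame of per-patient score columns plus `patient`.
#' @param clinical clinical table with `os_time`, `os_event`.
#' @return list: `c_index` (named vector, risk signature first), `spearman`
#'   (correlation matrix).
#' @export
signature_comparison <- function(risks, competing, clinical) {
  m <- match(risks$patient, clinical$patient)
  time <- clinical$os_time[m]; event <- clinical$os_event[m]
  scores <- data.frame(sv_signature = risks$risk_score)
  if (!is.null(competing)) {
    cm <- match(risks$patient, competing$patient)
    for (v in setdiff(names(competing), "patient")) {
      scores[[v]] <- competing[[v]][cm]
    }
  }
  ci <- vapply(scores, function(s) {
    if (all(is.na(s)) || stats::var(s, na.rm = TRUE) == 0) return(0.5)
    c_index(s, time, event)
  }, numeric(1))
  rho <- suppressWarnings(stats::cor(scores, method = "spearman",
                                     use = "pairwise.complete.obs"))
  list(c_index = ci, spearman = rho)
}
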