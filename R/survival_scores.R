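## Per-sample SV-score / drug-score and the survival analytics built on them:
## Kaplan-Meier curves with log-rank tests, multivariate Cox models, the
## drug-response rank AUC, and Harrell's concordance (in stats_utils.R).

#' SV-score: co-occurring pair alterations per sample
#'
#' Counts, per sample, the SV pairs whose both genes carry their required
#' states (gene1 its primary-lesion state, gene2 its rescuing state). Pairs
#' with a gene missing from the alteration matrix are not counted (logged).
#'
#' @param alt alteration matrix genes x samples.
#' @param pairs data.frame with `gene1`, `gene2`, `pair_type`.
#' @return named integer vector, one count per sample.
#' @export
sv_score <- function(alt, pairs) {
  req <- required_states(pairs$pair_type)
  counts <- stats::setNames(integer(ncol(alt)), colnames(alt))
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
    if (is.na(req[i, 1]) || !(g1 %in% rownames(alt)) || !(g2 %in% rownames(alt))) {
      skipped <- skipped + 1L
      next
    }
    hit <- alt[g1, ] == req[i, "gene1"] & alt[g2, ] == req[i, "gene2"]
    counts <- counts + as.integer(hit)
  }
  if (skipped) message(skipped, " pair(s) skipped (untyped or gene not called)")
  counts
}

#' Drug-score: altered SV partners per sample
#'
#' @param alt alteration matrix genes x samples.
#' @param partners data.frame with `gene`, `required_state` (`"LOF"`/`"GOF"`).
#' @return named integer vector per sample.
#' @export
drug_score <- function(alt, partners) {
  counts <- stats::setNames(integer(ncol(alt)), colnames(alt))
  for (i in seq_len(nrow(partners))) {
    g <- partners$gene[i]
    if (!g %in% rownames(alt)) next
    counts <- counts + as.integer(alt[g, ] == partners$required_state[i])
  }
  counts
}

#' Median-split score groups
#'
#' Samples strictly above the cohort median are `"high"`; ties at the median
#' fall to `"low"`.
#'
#' @param scores numeric vector.
#' @return factor with levels `low`, `high`.
#' @export
score_groups <- function(scores) {
  cutoff <- stats::median(scores, na.rm = TRUE)
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and two-sided log-rank test
#'
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @param group two-or-more-level grouping.
#' @return list with the `survfit` object (`fit`), log-rank `chisq`, `df` and
#'   `p`.
#' @export
km_curve <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (any(table(group) == 0) || nlevels(group) < 2) {
    stop("every group must contain at least one sample")
  }
  if (sum(event) == 0) stop("log-rank undefined: no events observed")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  list(fit = fit, chisq = sd_$chisq, df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards model
#'
#' Efron tie handling. Patients with a missing covariate are dropped from
#' this model only (logged). Stage should be encoded ordinally (I=1..IV=4)
#' upstream.
#'
#' @param time,event survival outcome.
#' @param covariates data.frame of numeric covariates (e.g. score, age,
#'   stage).
#' @return data.frame per covariate: `coef`, `hr`, `lower95`, `upper95`, `p`;
#'   the fitted `coxph` object as attribute `fit`.
#' @export
cox_multivariate <- function(time, event, covariates) {
  stopifnot(is.data.frame(covariates))
  const <- vapply(covariates, function(v) stats::var(v, na.rm = TRUE) == 0, logical(1))
  if (any(const)) stop("constant covariate(s): ",
                       paste(names(covariates)[const], collapse = ", "))
  d <- cbind(data.frame(.time = time, .event = event), covariates)
  drop_n <- sum(!stats::complete.cases(d))
  if (drop_n) message(drop_n, " patient(s) dropped for missing covariates")
  d <- d[stats::complete.cases(d), ]
  if (sum(d$.event) < ncol(covariates)) stop("fewer events than covariates")
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = d,
                         ties = "efron")
  s <- summary(fit)
  out <- data.frame(
    covariate = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    lower95 = s$conf.int[, "lower .95"],
    upper95 = s$conf.int[, "upper .95"],
    p = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL
  )
  attr(out, "fit") <- fit
  out
}

#' Rank AUC of a score for predicting treatment response
#'
#' @param scores per-sample scores.
#' @param response logical (TRUE = responder) or `"R"`/`"NR"`-style labels
#'   coercible to logical.
#' @return AUC in \[0,1\] for scores predicting non-response (higher score =
#'   non-responder), i.e. positives are non-responders.
#' @export
response_auc <- function(scores, response) {
  resp <- as.logical(response)
  rank_auc(scores, !resp)
}
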