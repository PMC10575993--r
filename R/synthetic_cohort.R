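## Synthetic patient cohort keyed to a risk model: per-patient signature-pair
## alteration indicators drive an exponential survival hazard, response
## probabilities, and immune/burden covariates. Omics layers for
## non-signature genes are pure noise, isolating the signature signal.

#' Simulate an immunotherapy patient cohort under a risk model
#'
#' Each patient's pair-alteration indicators are drawn
#' Bernoulli(`alteration_rate`); for an altered pair both genes receive
#' consistent omics evidence of their required states. Survival times are
#' exponential with hazard proportional to RiskScore raised to
#' `signature_hazard_scale`; censoring is an independent exponential
#' calibrated to the target rate; response probability decreases with the
#' latent RiskScore. TMB/neoantigen load and cytolytic/immune expression are
#' higher at low risk.
#'
#' @param cfg a [simulation_config()].
#' @param model a [risk_model()] (default the published six-pair model).
#' @param immune_sets optional named list of gene sets whose member genes are
#'   expressed with a latent immune level anti-correlated with risk.
#' @return list: `expr`, `mut`, `cna`, `clinical`, `truth` (latent risk and
#'   planted indicators).
#' @export
simulate_cohort <- function(cfg = simulation_config(), model = default_risk_model(),
                            immune_sets = NULL) {
  stopifnot(inherits(cfg, "simulation_config"), inherits(model, "risk_model"))
  set.seed(cfg$seed)
  terms <- model$terms
  n <- cfg$n_patients
  patients <- sprintf("P%04d", seq_len(n))
  sig_genes <- unique(c(terms$gene1, terms$gene2))
  filler <- sprintf("F%03d", seq_len(100))
  extra <- c("GZMA", "PRF1")
  imm_genes <- if (!is.null(immune_sets)) {
    setdiff(unique(unlist(immune_sets)), c(sig_genes, filler, extra))
  } else character(0)
  genes <- c(sig_genes, extra, imm_genes, filler)

  ind <- matrix(stats::rbinom(n * nrow(terms), 1, cfg$alteration_rate),
                nrow = n, dimnames = list(patients, NULL))
  latent_risk <- exp(as.vector(ind %*% terms$coefficient))
  log_risk <- log(latent_risk)

  ## omics layers
  mu <- stats::setNames(stats::rnorm(length(genes), 8, 1.5), genes)
  expr <- matrix(stats::rnorm(length(genes) * n, 0, 1),
                 nrow = length(genes), dimnames = list(genes, patients)) + mu
  cna <- matrix(0L, nrow = length(genes), ncol = n,
                dimnames = list(genes, patients))
  layers <- list(expr = expr, cna = cna,
                 mut = data.frame(sample = character(0), gene = character(0),
                                  variant_class = character(0),
                                  protein_change = character(0),
                                  stringsAsFactors = FALSE))
  for (i in seq_len(nrow(terms))) {
    hit <- patients[ind[, i] == 1]
    layers <- plant_state_evidence(terms$gene1[i], hit, terms$state1[i], layers)
    layers <- plant_state_evidence(terms$gene2[i], hit, terms$state2[i], layers)
  }

  ## immune-correlated expression: cytolytic genes and immune-set members
  immune_level <- -0.6 * log_risk + stats::rnorm(n, 0, 1)
  for (g in c(extra, imm_genes)) {
    layers$expr[g, ] <- layers$expr[g, ] + 0.8 * immune_level
  }
  layers$expr <- pmax(layers$expr, 0)

  ## survival: exponential hazard, base median ~1 year
  lambda0 <- log(2) / 365
  hazard <- lambda0 * latent_risk^cfg$signature_hazard_scale
  t_event <- stats::rexp(n, rate = hazard)
  os_time <- t_event
  os_event <- rep(1L, n)
  if (cfg$censoring_rate > 0) {
    lambda_c <- lambda0 * cfg$censoring_rate / (1 - cfg$censoring_rate)
    t_cens <- stats::rexp(n, rate = lambda_c)
    os_event <- as.integer(t_event <= t_cens)
    os_time <- pmin(t_event, t_cens)
  }
  os_time <- pmax(os_time, 1)

  ## response: probability decreasing in latent risk
  p_resp <- stats::plogis(1 - cfg$signature_hazard_scale * log_risk)
  responder <- stats::runif(n) < p_resp
  response <- character(n)
  sd_duration <- rep(NA_real_, n)
  r_draw <- stats::runif(n)
  response[responder] <- ifelse(r_draw[responder] < 0.25, "CR",
                                ifelse(r_draw[responder] < 0.85, "PR", "SD"))
  response[!responder] <- ifelse(r_draw[!responder] < 0.85, "PD", "SD")
  sd_duration[response == "SD" & responder] <-
    stats::runif(sum(response == "SD" & responder), 7, 18)
  sd_duration[response == "SD" & !responder] <-
    stats::runif(sum(response == "SD" & !responder), 1, 6)

  tmb_mean <- 150 * latent_risk^(-0.3)
  tmb_val <- stats::rpois(n, tmb_mean)
  clinical <- data.frame(
    patient = patients,
    os_time = os_time, os_event = os_event,
    response = response, sd_duration_months = sd_duration,
    age = round(stats::rnorm(n, 60, 10)),
    stage = sample(1:4, n, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2)),
    tmb = tmb_val,
    neoantigen_load = stats::rpois(n, 0.1 * tmb_val + 1),
    cytolytic = as.numeric(sqrt(layers$expr["GZMA", ] * layers$expr["PRF1", ])),
    stringsAsFactors = FALSE)
  validate_clinical(clinical)

  list(expr = layers$expr, mut = layers$mut, cna = layers$cna,
       clinical = clinical,
       truth = list(latent_risk = stats::setNames(latent_risk, patients),
                    indicators = ind))
}
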