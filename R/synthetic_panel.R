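## Synthetic study generator: a cell-line panel (expression, mutations, copy
## number, CRISPR dependencies, annotation bundle) with planted synthetic-
## viability pairs whose rescue effects and pair-level features are
## statistically detectable, so every downstream stage has ground truth.
## Deterministic for a fixed seed (base R Mersenne-Twister throughout).

#' Simulation configuration
#'
#' Defaults define the study conditions used throughout the package's tests
#' and analysis scripts: a 200-gene, 200-cell-line, 4-lineage panel with 40
#' planted SV pairs; dependency baselines Normal(-0.4, 0.3), lineage offsets
#' Normal(0, 0.1), measurement noise sd 0.2; alteration rate 0.15; rescue
#' shift +0.5 toward 0; 300-patient cohorts with 30% censoring.
#'
#' @param seed integer RNG seed.
#' @param n_genes,n_cell_lines,n_lineages,n_patients panel/cohort sizes.
#' @param n_true_sv_pairs planted SV pairs (requires `2*n_true_sv_pairs <=
#'   n_genes`; planted pairs are gene-disjoint).
#' @param rescue_effect upward shift (toward 0) of gene1 dependency in cell
#'   lines where gene2 carries its rescuing state.
#' @param alteration_rate per-gene per-sample alteration probability.
#' @param dep_noise_sd dependency measurement noise sd.
#' @param feature_enrichment named list of per-feature planting probabilities
#'   (boolean-generating resources) or mean shifts (quantitative resources)
#'   applied to true SV pairs; see [default_feature_enrichment()].
#' @param signature_hazard_scale exponent linking RiskScore to the hazard in
#'   cohort simulation (0 = no survival signal).
#' @param censoring_rate target fraction of censored patients.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_genes = 200, n_cell_lines = 200,
                              n_lineages = 4, n_patients = 300,
                              n_true_sv_pairs = 40, rescue_effect = 0.5,
                              alteration_rate = 0.15, dep_noise_sd = 0.2,
                              feature_enrichment = default_feature_enrichment(),
                              signature_hazard_scale = 1, censoring_rate = 0.3) {
  stopifnot(alteration_rate >= 0, alteration_rate < 1,
            censoring_rate >= 0, censoring_rate < 1,
            rescue_effect >= 0, dep_noise_sd > 0,
            n_true_sv_pairs <= choose(n_genes, 2),
            2 * n_true_sv_pairs <= n_genes,
            n_lineages >= 1, n_cell_lines >= n_lineages)
  structure(list(seed = seed, n_genes = n_genes, n_cell_lines = n_cell_lines,
                 n_lineages = n_lineages, n_patients = n_patients,
                 n_true_sv_pairs = n_true_sv_pairs, rescue_effect = rescue_effect,
                 alteration_rate = alteration_rate, dep_noise_sd = dep_noise_sd,
                 feature_enrichment = feature_enrichment,
                 signature_hazard_scale = signature_hazard_scale,
                 censoring_rate = censoring_rate),
            class = "simulation_config")
}

#' Default (moderate) feature-enrichment map for planted SV pairs
#'
#' Probabilities of planting shared structure (PPI neighbors, paralogy,
#' complexes, pathways, GO terms, compartments, co-expression, co-occurring
#' alterations) and mean shifts for quantitative resources (conservation,
#' shared-neighbor essentiality).
#'
#' @return named list.
#' @export
default_feature_enrichment <- function() {
  list(shared_ppi = 0.6, coexpression = 0.6, paralog = 0.4,
       complex_membership = 0.5, pathway_number = 0.6, go_terms = 0.6,
       colocalization = 0.6, cooccurring_alteration = 0.35,
       conservation_shift = 0.2, neighbor_essentiality_shift = 0.3)
}

#' Strong feature enrichment preset
#'
#' Used where a strongly separable training set is the stated condition
#' (classifier sanity checks).
#'
#' @return named list.
#' @export
strong_feature_enrichment <- function() {
  list(shared_ppi = 0.9, coexpression = 0.9, paralog = 0.8,
       complex_membership = 0.85, pathway_number = 0.9, go_terms = 0.9,
       colocalization = 0.9, cooccurring_alteration = 0.6,
       conservation_shift = 0.35, neighbor_essentiality_shift = 0.4)
}

## plant omics evidence consistent with a target state (LOF/GOF) for one gene
## across flagged samples; mutation (LOF only) and/or deep CNA, plus an
## expression shift. Returns updated layers.
plant_state_evidence <- function(gene, samples, state, layers) {
  if (!length(samples)) return(layers)
  use_mut <- state == "LOF" & stats::runif(length(samples)) < 0.5
  use_cna <- stats::runif(length(samples)) < 0.6
  use_cna[!use_mut & !use_cna] <- TRUE   # at least one discrete layer
  if (any(use_mut)) {
    cls <- sample(LOF_VARIANT_CLASSES, sum(use_mut), replace = TRUE)
    layers$mut <- rbind(layers$mut, data.frame(
      sample = samples[use_mut], gene = gene, variant_class = cls,
      protein_change = NA_character_, stringsAsFactors = FALSE))
  }
  if (any(use_cna)) {
    layers$cna[gene, samples[use_cna]] <- if (state == "LOF") -2L else 2L
  }
  shift <- if (state == "LOF") -2.5 else 2.5
  layers$expr[gene, samples] <- layers$expr[gene, samples] + shift
  layers
}

#' Simulate a cell-line panel with planted SV pairs
#'
#' Generates expression, mutation, copy-number and CRISPR dependency layers
#' plus an annotation bundle over a synthetic gene universe (half tumor
#' suppressors, half oncogenes; TSGs alter by loss, oncogenes by gain).
#' Planted pairs receive enriched pair features per the configured
#' enrichment, and gene1's dependency is shifted toward 0 by `rescue_effect`
#' in lines where gene2 carries its rescuing state.
#'
#' @param cfg a [simulation_config()].
#' @return list: `expr`, `mut`, `cna`, `dep` ([dependency_matrix()]),
#'   `bundle` (annotation bundle, see [compute_pair_features()]), `truth`
#'   (list with `true_sv_pairs` and per-gene `planted_states` matrix).
#' @export
simulate_panel <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  fe <- cfg$feature_enrichment
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  lines <- sprintf("CL%03d", seq_len(cfg$n_cell_lines))
  tsg_list <- genes[seq_len(cfg$n_genes %/% 2)]
  oncogene_list <- setdiff(genes, tsg_list)
  native_state <- ifelse(genes %in% tsg_list, "LOF", "GOF")
  names(native_state) <- genes
  lineages <- sprintf("lineage%02d", seq_len(cfg$n_lineages))
  lineage <- stats::setNames(sample(lineages, cfg$n_cell_lines, replace = TRUE), lines)

  ## planted pairs: gene-disjoint, typed from gene roles
  pair_genes <- sample(genes, 2 * cfg$n_true_sv_pairs)
  g1 <- pair_genes[seq_len(cfg$n_true_sv_pairs)]
  g2 <- pair_genes[cfg$n_true_sv_pairs + seq_len(cfg$n_true_sv_pairs)]
  pair_type <- type_pair(g1, g2, tsg_list, oncogene_list)
  true_pairs <- data.frame(gene1 = g1, gene2 = g2, pair_type = pair_type,
                           stringsAsFactors = FALSE)

  ## planted alteration states (ground truth), with co-occurrence boost for
  ## true pairs: gene1 alteration upweighted where gene2 is altered
  states <- matrix("WT", nrow = cfg$n_genes, ncol = cfg$n_cell_lines,
                   dimnames = list(genes, lines))
  for (g in genes) {
    hit <- stats::runif(cfg$n_cell_lines) < cfg$alteration_rate
    states[g, hit] <- native_state[g]
  }
  for (i in seq_len(nrow(true_pairs))) {
    a <- true_pairs$gene1[i]; b <- true_pairs$gene2[i]
    co <- states[b, ] != "WT" &
      stats::runif(cfg$n_cell_lines) < fe$cooccurring_alteration
    states[a, co] <- native_state[a]
  }

  ## expression: per-gene baseline + noise, then planted shifts; co-expression
  ## for enriched true pairs
  mu <- stats::setNames(stats::rnorm(cfg$n_genes, 8, 1.5), genes)
  expr <- matrix(stats::rnorm(cfg$n_genes * cfg$n_cell_lines, 0, 1),
                 nrow = cfg$n_genes, dimnames = list(genes, lines)) + mu
  coexpr_pair <- stats::runif(nrow(true_pairs)) < fe$coexpression
  for (i in which(coexpr_pair)) {
    a <- true_pairs$gene1[i]; b <- true_pairs$gene2[i]
    expr[b, ] <- mu[b] + 0.8 * (expr[a, ] - mu[a]) +
      stats::rnorm(cfg$n_cell_lines, 0, 0.6)
  }

  cna <- matrix(0L, nrow = cfg$n_genes, ncol = cfg$n_cell_lines,
                dimnames = list(genes, lines))
  layers <- list(expr = expr, cna = cna,
                 mut = data.frame(sample = character(0), gene = character(0),
                                  variant_class = character(0),
                                  protein_change = character(0),
                                  stringsAsFactors = FALSE))
  for (g in genes) {
    hit <- lines[states[g, ] != "WT"]
    layers <- plant_state_evidence(g, hit, native_state[g], layers)
  }
  ## background passenger mutations (TMB realism)
  n_bg <- stats::rpois(cfg$n_cell_lines, 15)
  bg <- data.frame(
    sample = rep(lines, n_bg),
    gene = sample(genes, sum(n_bg), replace = TRUE),
    variant_class = sample(c("missense", "silent"), sum(n_bg), replace = TRUE,
                           prob = c(0.75, 0.25)),
    protein_change = NA_character_, stringsAsFactors = FALSE)
  layers$mut <- rbind(layers$mut, bg)

  ## dependencies: baseline + lineage offsets + noise, rescue for planted pairs
  baseline <- stats::setNames(stats::rnorm(cfg$n_genes, -0.4, 0.3), genes)
  offsets <- matrix(stats::rnorm(cfg$n_genes * cfg$n_lineages, 0, 0.1),
                    nrow = cfg$n_genes, dimnames = list(genes, lineages))
  dep_scores <- baseline +
    offsets[, lineage[lines], drop = FALSE] +
    matrix(stats::rnorm(cfg$n_genes * cfg$n_cell_lines, 0, cfg$dep_noise_sd),
           nrow = cfg$n_genes)
  dimnames(dep_scores) <- list(genes, lines)
  req <- required_states(true_pairs$pair_type)
  for (i in seq_len(nrow(true_pairs))) {
    a <- true_pairs$gene1[i]; b <- true_pairs$gene2[i]
    rescued <- states[b, ] == req[i, "gene2"]
    dep_scores[a, rescued] <- dep_scores[a, rescued] + cfg$rescue_effect
  }

  bundle <- simulate_bundle(cfg, genes, tsg_list, oncogene_list, true_pairs)

  list(expr = layers$expr, mut = layers$mut, cna = layers$cna,
       dep = dependency_matrix(dep_scores, lineage), bundle = bundle,
       truth = list(true_sv_pairs = true_pairs, planted_states = states))
}

## Annotation bundle: Erdos-Renyi PPI plus clique complexes, random-tree GO
## namespaces, random pathway/compartment memberships; planted pairs get
## shared structure per the enrichment map.
simulate_bundle <- function(cfg, genes, tsg_list, oncogene_list, true_pairs) {
  fe <- cfg$feature_enrichment
  n <- length(genes)

  ## PPI: ER with mean degree ~6
  p_edge <- min(1, 6 / (n - 1))
  adj <- which(upper.tri(matrix(0, n, n)) &
                 matrix(stats::runif(n * n) < p_edge, n, n), arr.ind = TRUE)
  edges <- data.frame(from = genes[adj[, 1]], to = genes[adj[, 2]],
                      stringsAsFactors = FALSE)
  ## planted shared neighbors (also shortens PPI distance)
  extra <- list()
  for (i in seq_len(nrow(true_pairs))) {
    if (stats::runif(1) < fe$shared_ppi) {
      nb <- sample(setdiff(genes, c(true_pairs$gene1[i], true_pairs$gene2[i])), 4)
      extra[[length(extra) + 1]] <- data.frame(
        from = rep(c(true_pairs$gene1[i], true_pairs$gene2[i]), each = 4),
        to = rep(nb, 2), stringsAsFactors = FALSE)
      ## shared neighbors of rescue pairs trend essential
      attr(extra[[length(extra)]], "hub") <- nb
    }
  }
  hub_genes <- unique(unlist(lapply(extra, attr, "hub")))
  if (length(extra)) edges <- rbind(edges, do.call(rbind, extra))
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- unique(edges[edges$from != edges$to, ])

  ## paralogs: background pairs + planted
  bg_par <- data.frame(gene1 = sample(genes, 30, replace = TRUE),
                       gene2 = sample(genes, 30, replace = TRUE),
                       stringsAsFactors = FALSE)
  bg_par <- bg_par[bg_par$gene1 != bg_par$gene2, ]
  keep <- stats::runif(nrow(true_pairs)) < fe$paralog
  paralogs <- rbind(bg_par, true_pairs[keep, c("gene1", "gene2")])

  ## complexes: random cliques; planted pairs co-inserted
  complexes <- lapply(seq_len(max(10, n %/% 10)), function(i) sample(genes, sample(4:8, 1)))
  names(complexes) <- sprintf("complex%03d", seq_along(complexes))
  for (i in seq_len(nrow(true_pairs))) {
    if (stats::runif(1) < fe$complex_membership) {
      cx <- sample(seq_along(complexes), 1)
      complexes[[cx]] <- unique(c(complexes[[cx]], true_pairs$gene1[i], true_pairs$gene2[i]))
    }
  }

  ## pathways: ~25 sets; planted pairs share two extra pathways
  pathways <- lapply(seq_len(25), function(i) sample(genes, 25))
  names(pathways) <- sprintf("pathway%02d", seq_along(pathways))
  for (i in seq_len(nrow(true_pairs))) {
    if (stats::runif(1) < fe$pathway_number) {
      for (px in sample(seq_along(pathways), 2)) {
        pathways[[px]] <- unique(c(pathways[[px]], true_pairs$gene1[i], true_pairs$gene2[i]))
      }
    }
  }

  ## GO namespaces: 3-level tree (root -> 6 branches -> 6 leaves each); genes
  ## annotated with 3 leaves; enriched pairs share two of gene1's leaves
  make_go <- function(ns) {
    root <- paste0(ns, ":root")
    mids <- paste0(ns, ":m", 1:6)
    leaves <- paste0(ns, ":l", 1:36)
    parents <- c(stats::setNames(rep(root, 6), mids),
                 stats::setNames(rep(mids, each = 6), leaves))
    terms <- lapply(stats::setNames(genes, genes), function(g) sample(leaves, 3))
    for (i in seq_len(nrow(true_pairs))) {
      if (stats::runif(1) < fe$go_terms) {
        shared <- terms[[true_pairs$gene1[i]]][1:2]
        terms[[true_pairs$gene2[i]]] <- unique(c(shared, terms[[true_pairs$gene2[i]]][1]))
      }
    }
    list(terms = terms, parents = parents)
  }
  go_bp <- make_go("BP"); go_mf <- make_go("MF"); go_cc <- make_go("CC")

  ## compartments
  comp_labels <- c("nucleus", "cytosol", "membrane", "mitochondrion", "ER", "golgi")
  compartments <- lapply(stats::setNames(genes, genes),
                         function(g) sample(comp_labels, sample(1:2, 1)))
  for (i in seq_len(nrow(true_pairs))) {
    if (stats::runif(1) < fe$colocalization) {
      compartments[[true_pairs$gene2[i]]] <- compartments[[true_pairs$gene1[i]]]
    }
  }

  essentiality <- stats::setNames(stats::runif(n, 0, 0.6), genes)
  if (length(hub_genes)) {
    essentiality[hub_genes] <- pmin(1, essentiality[hub_genes] +
                                      fe$neighbor_essentiality_shift +
                                      stats::runif(length(hub_genes), 0, 0.2))
  }
  conservation <- stats::setNames(stats::runif(n, 0.2, 0.8), genes)
  pg <- unique(c(true_pairs$gene1, true_pairs$gene2))
  conservation[pg] <- pmin(1, conservation[pg] + fe$conservation_shift)

  list(ppi = edges, paralog_pairs = paralogs, complexes = complexes,
       pathways = pathways, go_bp = go_bp, go_mf = go_mf, go_cc = go_cc,
       compartments = compartments, essentiality = essentiality,
       conservation = conservation, tsg_list = tsg_list,
       oncogene_list = oncogene_list)
}

#' Sample background (non-SV) gene pairs for a panel
#'
#' Typed pairs drawn uniformly from the panel's gene universe, excluding the
#' planted SV pairs; used as screen candidates and classifier negatives.
#'
#' @param panel output of [simulate_panel()].
#' @param n number of background pairs.
#' @param seed RNG seed.
#' @return data.frame `gene1`, `gene2`, `pair_type`.
#' @export
background_pairs <- function(panel, n, seed = 1) {
  set.seed(seed)
  genes <- names(panel$bundle$essentiality)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  truth_keys <- key(panel$truth$true_sv_pairs$gene1, panel$truth$true_sv_pairs$gene2)
  g1 <- g2 <- character(0)
  seen <- character(0)
  while (length(g1) < n) {
    a <- sample(genes, 1); b <- sample(genes, 1)
    if (a == b) next
    kk <- key(a, b)
    if (kk %in% truth_keys || kk %in% seen) next
    seen <- c(seen, kk)
    g1 <- c(g1, a); g2 <- c(g2, b)
  }
  data.frame(gene1 = g1, gene2 = g2,
             pair_type = type_pair(g1, g2, panel$bundle$tsg_list,
                                   panel$bundle$oncogene_list),
             stringsAsFactors = FALSE)
}

#' Write a simulated panel to a directory in the package's file formats
#'
#' @param panel output of [simulate_panel()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(panel$expr, file.path(dir, "expression.tsv"))
  write_matrix(panel$cna, file.path(dir, "cna.tsv"))
  write_tsv(panel$mut, file.path(dir, "mutations.tsv"))
  write_matrix(panel$dep$scores, file.path(dir, "dependency.tsv"))
  write_tsv(data.frame(cell_line = names(panel$dep$lineage),
                       lineage = unname(panel$dep$lineage)),
            file.path(dir, "lineage.tsv"))
  write_tsv(panel$truth$true_sv_pairs, file.path(dir, "ground_truth.tsv"))
  write_tsv(panel$bundle$ppi, file.path(dir, "ppi_edges.tsv"))
  invisible(dir)
}
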