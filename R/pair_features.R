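## The 14 pair-level features. Quantitative features: shared-PPI overlap
## significance, mean essentiality of shared PPI neighbors, reciprocal PPI
## distance, GO BP/MF/CC annotation similarity, co-expression, pathway count,
## subcellular co-localization, mean conservation, essentiality of shared
## complex partners. Boolean features: paralogy, complex co-membership,
## significant shared PPI, significant co-occurring alteration. Each feature
## is computed independently; NA means the underlying resource does not cover
## the pair.

#' Default feature registry
#'
#' Names of the 14 pair-level features, in the order they appear in the
#' feature table. The registry is pluggable: [compute_pair_features()] accepts
#' any subset.
#'
#' @return character vector of length 14.
#' @export
default_feature_registry <- function() {
  c("shared_ppi", "shared_ppi_essentiality", "avg_shortest_distance",
    "bp_similarity", "mf_similarity", "cc_similarity", "coexpression",
    "paralog", "complex_membership", "cooccurring_alteration",
    "pathway_number", "colocalization", "conservation", "complex_essentiality")
}

ppi_graph <- function(edges) {
  igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE)
}

ppi_neighbors <- function(graph, gene) {
  if (!gene %in% igraph::V(graph)$name) return(NULL)
  igraph::neighbors(graph, gene)$name
}

#' Shared protein-protein interactors, hypergeometric test
#'
#' Tests whether two genes share more PPI neighbors than expected by chance:
#' upper-tail hypergeometric probability with population all PPI nodes except
#' the two genes, draws the first gene's neighbors (excluding the partner) and
#' successes the second's.
#'
#' @param g1,g2 gene symbols.
#' @param ppi edge-list data.frame (`from`, `to`) or an igraph graph.
#' @return list with `k_shared` and `p`; both NA when a gene is absent from
#'   the graph.
#' @export
shared_ppi_pvalue <- function(g1, g2, ppi) {
  graph <- if (inherits(ppi, "igraph")) ppi else ppi_graph(ppi)
  n1 <- ppi_neighbors(graph, g1)
  n2 <- ppi_neighbors(graph, g2)
  if (is.null(n1) || is.null(n2)) {
    message("gene absent from PPI graph: ", if (is.null(n1)) g1 else g2)
    return(list(k_shared = NA_integer_, p = NA_real_))
  }
  n1 <- setdiff(n1, g2); n2 <- setdiff(n2, g1)
  N <- igraph::vcount(graph) - 2L
  k <- length(intersect(n1, n2))
  list(k_shared = k,
       p = hyper_upper_tail(k, length(n1), length(n2), N))
}

#' Mean essentiality of the shared PPI neighbors of a pair
#'
#' @param g1,g2 gene symbols.
#' @param ppi edge list or igraph graph.
#' @param essentiality named numeric vector, per-gene essentiality.
#' @return mean essentiality over shared neighbors; NA when there are none.
#' @export
mean_shared_ppi_essentiality <- function(g1, g2, ppi, essentiality) {
  graph <- if (inherits(ppi, "igraph")) ppi else ppi_graph(ppi)
  n1 <- ppi_neighbors(graph, g1); n2 <- ppi_neighbors(graph, g2)
  shared <- intersect(setdiff(n1, g2), setdiff(n2, g1))
  if (!length(shared)) return(NA_real_)
  vals <- essentiality[shared]
  if (anyNA(vals)) {
    message(sum(is.na(vals)), " shared neighbor(s) without essentiality excluded")
    vals <- vals[!is.na(vals)]
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Reciprocal shortest PPI distance between two genes
#'
#' The feature score is 1/d so that closer pairs score higher; disconnected
#' pairs score 0. The raw distance is returned alongside.
#'
#' @inheritParams mean_shared_ppi_essentiality
#' @return list with `distance` (Inf when disconnected, NA when a gene is
#'   absent) and `score` (1/d, 0 when disconnected).
#' @export
avg_shortest_distance <- function(g1, g2, ppi) {
  graph <- if (inherits(ppi, "igraph")) ppi else ppi_graph(ppi)
  vs <- igraph::V(graph)$name
  if (!(g1 %in% vs) || !(g2 %in% vs)) {
    return(list(distance = NA_real_, score = NA_real_))
  }
  d <- igraph::distances(graph, v = g1, to = g2)[1, 1]
  list(distance = d, score = if (is.finite(d)) 1 / d else 0)
}

go_closure <- function(terms, parents, cache = NULL) {
  roots <- setdiff(unname(parents), names(parents))
  out <- character(0)
  frontier <- terms
  while (length(frontier)) {
    out <- union(out, frontier)
    nxt <- unname(parents[frontier])
    nxt <- nxt[!is.na(nxt)]
    frontier <- setdiff(nxt, out)
  }
  setdiff(out, roots)
}

#' Annotation-set similarity for a GO namespace
#'
#' Jaccard index of the ancestor-closed term sets of the two genes (each
#' gene's direct terms unioned with all ancestors along the parent links; the
#' namespace root is excluded).
#'
#' @param g1,g2 gene symbols.
#' @param go list with `terms` (named list gene -> term ids) and `parents`
#'   (named character vector term -> parent term; roots are terms that appear
#'   only as parents).
#' @return Jaccard similarity in \[0,1\]; NA when either gene is unannotated.
#' @export
go_similarity <- function(g1, g2, go) {
  t1 <- go$terms[[g1]]; t2 <- go$terms[[g2]]
  if (is.null(t1) || is.null(t2) || !length(t1) || !length(t2)) return(NA_real_)
  c1 <- go_closure(t1, go$parents)
  c2 <- go_closure(t2, go$parents)
  u <- union(c1, c2)
  if (!length(u)) return(0)
  length(intersect(c1, c2)) / length(u)
}

#' Spearman co-expression of a gene pair across samples
#'
#' @param g1,g2 gene symbols.
#' @param expr numeric matrix genes x samples.
#' @param min_samples minimum pairwise-complete samples.
#' @return Spearman correlation; NA when either profile is constant, a gene
#'   is absent, or fewer than `min_samples` complete pairs exist.
#' @export
coexpression <- function(g1, g2, expr, min_samples = 3) {
  if (!(g1 %in% rownames(expr)) || !(g2 %in% rownames(expr))) return(NA_real_)
  x <- expr[g1, ]; y <- expr[g2, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_samples) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' One-sided Fisher test for co-occurring alterations of a pair
#'
#' 2x2 table of non-WT calls (AMBIGUOUS counts as altered for co-occurrence
#' screening is avoided: AMBIGUOUS is excluded) across samples; one-sided test
#' for enrichment of co-alteration.
#'
#' @param g1,g2 gene symbols.
#' @param alt alteration matrix from [call_alterations()].
#' @return list with `p` and the 2x2 `table`; NA when a gene is uncalled.
#' @export
cooccurring_alteration <- function(g1, g2, alt) {
  if (!(g1 %in% rownames(alt)) || !(g2 %in% rownames(alt))) {
    return(list(p = NA_real_, table = NULL))
  }
  a1 <- alt[g1, ]; a2 <- alt[g2, ]
  ok <- a1 != "AMBIGUOUS" & a2 != "AMBIGUOUS"
  x1 <- a1[ok] != "WT"; x2 <- a2[ok] != "WT"
  tab <- matrix(c(sum(x1 & x2), sum(x1 & !x2), sum(!x1 & x2), sum(!x1 & !x2)),
                nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(p = p, table = tab)
}

#' Compute the 14-feature table for a set of gene pairs
#'
#' @param pairs data.frame with columns `gene1`, `gene2` (and optionally
#'   `pair_type`).
#' @param bundle annotation bundle: a list with elements `ppi` (edge list),
#'   `paralog_pairs` (data.frame gene1/gene2), `complexes` (named list of gene
#'   vectors), `pathways` (named list), `go_bp`/`go_mf`/`go_cc` (see
#'   [go_similarity()]), `compartments` (named list gene -> labels),
#'   `essentiality`, `conservation` (named numeric vectors).
#' @param expr optional expression matrix for the co-expression feature.
#' @param alt optional alteration matrix for the co-occurrence feature.
#' @param features feature names to compute (default all 14).
#' @param alpha significance level turning the shared-PPI and co-occurrence
#'   p-values into boolean features.
#' @return data.frame: pairs columns, one column per feature, plus raw
#'   intermediates `shared_ppi_p`, `shared_ppi_k`, `ppi_distance_raw`,
#'   `cooccurrence_p`.
#' @export
compute_pair_features <- function(pairs, bundle, expr = NULL, alt = NULL,
                                  features = default_feature_registry(),
                                  alpha = 0.05) {
  stopifnot(all(c("gene1", "gene2") %in% names(pairs)))
  graph <- ppi_graph(bundle$ppi)
  n <- nrow(pairs)
  out <- pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  paralog_keys <- if (!is.null(bundle$paralog_pairs)) {
    key(bundle$paralog_pairs$gene1, bundle$paralog_pairs$gene2)
  } else character(0)

  ## per-gene memberships for complex/pathway lookups
  membership <- function(sets) {
    if (is.null(sets)) return(NULL)
    genes <- unique(unlist(sets, use.names = FALSE))
    idx <- lapply(stats::setNames(genes, genes), function(g) {
      names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
    })
    idx
  }
  complex_of <- membership(bundle$complexes)
  pathway_of <- membership(bundle$pathways)

  get0chr <- function(lst, g) if (!is.null(lst) && g %in% names(lst)) lst[[g]] else NULL

  cols <- c(features, "shared_ppi_p", "shared_ppi_k", "ppi_distance_raw",
            "cooccurrence_p")
  for (cn in cols) out[[cn]] <- NA_real_

  for (i in seq_len(n)) {
    g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
    if (any(c("shared_ppi", "shared_ppi_essentiality", "avg_shortest_distance")
            %in% features)) {
      sp <- suppressMessages(shared_ppi_pvalue(g1, g2, graph))
      out$shared_ppi_p[i] <- sp$p
      out$shared_ppi_k[i] <- sp$k_shared
      if ("shared_ppi" %in% features) {
        out$shared_ppi[i] <- if (is.na(sp$p)) NA_real_ else as.numeric(sp$p < alpha)
      }
      if ("shared_ppi_essentiality" %in% features) {
        out$shared_ppi_essentiality[i] <- suppressMessages(
          mean_shared_ppi_essentiality(g1, g2, graph, bundle$essentiality))
      }
      if ("avg_shortest_distance" %in% features) {
        d <- avg_shortest_distance(g1, g2, graph)
        out$avg_shortest_distance[i] <- d$score
        out$ppi_distance_raw[i] <- d$distance
      }
    }
    if ("bp_similarity" %in% features) out$bp_similarity[i] <- go_similarity(g1, g2, bundle$go_bp)
    if ("mf_similarity" %in% features) out$mf_similarity[i] <- go_similarity(g1, g2, bundle$go_mf)
    if ("cc_similarity" %in% features) out$cc_similarity[i] <- go_similarity(g1, g2, bundle$go_cc)
    if ("coexpression" %in% features && !is.null(expr)) {
      out$coexpression[i] <- coexpression(g1, g2, expr)
    }
    if ("paralog" %in% features) {
      out$paralog[i] <- as.numeric(key(g1, g2) %in% paralog_keys)
    }
    if ("complex_membership" %in% features && !is.null(complex_of)) {
      c1 <- get0chr(complex_of, g1); c2 <- get0chr(complex_of, g2)
      out$complex_membership[i] <- as.numeric(length(intersect(c1, c2)) > 0)
    }
    if ("cooccurring_alteration" %in% features && !is.null(alt)) {
      co <- cooccurring_alteration(g1, g2, alt)
      out$cooccurrence_p[i] <- co$p
      out$cooccurring_alteration[i] <-
        if (is.na(co$p)) NA_real_ else as.numeric(co$p < alpha)
    }
    if ("pathway_number" %in% features && !is.null(pathway_of)) {
      p1 <- get0chr(pathway_of, g1); p2 <- get0chr(pathway_of, g2)
      out$pathway_number[i] <- length(intersect(p1, p2))
    }
    if ("colocalization" %in% features && !is.null(bundle$compartments)) {
      l1 <- get0chr(bundle$compartments, g1); l2 <- get0chr(bundle$compartments, g2)
      out$colocalization[i] <- if (is.null(l1) || is.null(l2)) NA_real_ else {
        u <- union(l1, l2)
        if (!length(u)) NA_real_ else length(intersect(l1, l2)) / length(u)
      }
    }
    if ("conservation" %in% features && !is.null(bundle$conservation)) {
      v <- bundle$conservation[c(g1, g2)]
      out$conservation[i] <- if (anyNA(v)) NA_real_ else mean(v)
    }
    if ("complex_essentiality" %in% features && !is.null(complex_of)) {
      c1 <- get0chr(complex_of, g1); c2 <- get0chr(complex_of, g2)
      shared_cx <- intersect(c1, c2)
      if (length(shared_cx)) {
        partners <- setdiff(unique(unlist(bundle$complexes[shared_cx])), c(g1, g2))
        vals <- bundle$essentiality[partners]
        vals <- vals[!is.na(vals)]
        out$complex_essentiality[i] <- if (length(vals)) mean(vals) else NA_real_
      }
    }
  }
  out
}

#' AUC of one feature as an individual classifier of SV vs non-SV pairs
#'
#' @param table feature data.frame with a `label` column (`"SV"`/`"non-SV"` or
#'   logical).
#' @param feature feature column name.
#' @return rank AUC in \[0,1\].
#' @export
feature_auc <- function(table, feature) {
  lab <- if (is.logical(table$label)) table$label else table$label == "SV"
  rank_auc(table[[feature]], lab)
}

#' One-sided Wilcoxon rank-sum contrast of a feature, SV greater
#'
#' @inheritParams feature_auc
#' @return p-value.
#' @export
feature_contrast <- function(table, feature) {
  lab <- if (is.logical(table$label)) table$label else table$label == "SV"
  x <- table[[feature]][lab]; y <- table[[feature]][!lab]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both classes needed for feature_contrast")
  suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                      exact = length(c(x, y)) <= 50)$p.value)
}
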