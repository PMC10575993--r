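## Per-sample functional-state calling from three omics layers. A gene is
## called LOF in a sample on any of: a truncating-class mutation, a deep
## copy-number loss, or strongly reduced expression (per-gene z-score across
## the cohort); GOF on a high-level amplification or strongly elevated
## expression. Conflicting evidence yields AMBIGUOUS, which downstream
## co-occurrence counting ignores (direction undefined).

#' Thresholds for loss/gain-of-function calling
#'
#' Expression evidence uses per-gene z-scores across the cohort. Missense
#' mutations alone are neither LOF nor GOF by default; a configurable
#' allow-list (`gof_variant_classes`) can mark known activating classes.
#'
#' @param expr_low_z,expr_high_z z-score cutoffs for expression-based LOF/GOF.
#' @param cna_loss_level,cna_gain_level GISTIC levels treated as deep
#'   loss/high amplification.
#' @param lof_variant_classes mutation classes treated as loss of function.
#' @param gof_variant_classes mutation classes treated as gain of function.
#' @return list of class `calling_thresholds`.
#' @export
calling_thresholds <- function(expr_low_z = -1.5, expr_high_z = 1.5,
                               cna_loss_level = -2L, cna_gain_level = 2L,
                               lof_variant_classes = LOF_VARIANT_CLASSES,
                               gof_variant_classes = character(0)) {
  stopifnot(expr_low_z < expr_high_z, cna_loss_level < 0, cna_gain_level > 0)
  structure(list(expr_low_z = expr_low_z, expr_high_z = expr_high_z,
                 cna_loss_level = cna_loss_level, cna_gain_level = cna_gain_level,
                 lof_variant_classes = lof_variant_classes,
                 gof_variant_classes = gof_variant_classes),
            class = "calling_thresholds")
}

#' Call per-sample LOF/GOF states from expression, mutation and copy number
#'
#' Layers may be `NULL`; genes/samples missing a layer are called from the
#' available layers. Samples are the intersection of the supplied layers'
#' sample sets, genes their union.
#'
#' @param expr numeric matrix genes x samples (log scale) or `NULL`.
#' @param mut mutation data.frame (see [read_maf()]) or `NULL`.
#' @param cna integer GISTIC matrix genes x samples or `NULL`.
#' @param thresholds a [calling_thresholds()] object.
#' @return character matrix genes x samples over
#'   `{"WT","LOF","GOF","AMBIGUOUS"}`, of class `alteration_matrix`, with an
#'   `evidence` attribute holding one logical matrix per evidence channel
#'   (`mut_lof`, `mut_gof`, `cna_loss`, `cna_gain`, `expr_low`, `expr_high`).
#' @export
call_alterations <- function(expr = NULL, mut = NULL, cna = NULL,
                             thresholds = calling_thresholds()) {
  ## matrix layers define the sample universe; a mutation table lists events,
  ## so a sample absent from it is simply unmutated
  layers <- list(expr = expr, cna = cna)
  sample_sets <- lapply(Filter(Negate(is.null), layers), colnames)
  if (!length(sample_sets)) {
    if (is.null(mut)) stop("no omics layers supplied")
    sample_sets <- list(unique(mut$sample))
  }
  samples <- Reduce(intersect, sample_sets)
  if (!length(samples)) stop("zero overlapping samples across omics layers")
  genes <- unique(c(rownames(expr), rownames(cna), if (!is.null(mut)) mut$gene))
  genes <- sort(genes)

  blank <- matrix(FALSE, nrow = length(genes), ncol = length(samples),
                  dimnames = list(genes, samples))
  ev <- list(mut_lof = blank, mut_gof = blank, cna_loss = blank,
             cna_gain = blank, expr_low = blank, expr_high = blank)

  if (!is.null(mut)) {
    keep <- mut$sample %in% samples & mut$gene %in% genes
    ml <- mut[keep & mut$variant_class %in% thresholds$lof_variant_classes, ]
    mg <- mut[keep & mut$variant_class %in% thresholds$gof_variant_classes, ]
    ev$mut_lof[cbind(ml$gene, ml$sample)] <- TRUE
    if (nrow(mg)) ev$mut_gof[cbind(mg$gene, mg$sample)] <- TRUE
  }
  if (!is.null(cna)) {
    g <- intersect(genes, rownames(cna))
    cc <- cna[g, samples, drop = FALSE]
    cc[is.na(cc)] <- 0L
    ev$cna_loss[g, ] <- cc <= thresholds$cna_loss_level
    ev$cna_gain[g, ] <- cc >= thresholds$cna_gain_level
  }
  if (!is.null(expr)) {
    g <- intersect(genes, rownames(expr))
    e <- expr[g, samples, drop = FALSE]
    mu <- rowMeans(e, na.rm = TRUE)
    sd_ <- apply(e, 1, stats::sd, na.rm = TRUE)
    z <- (e - mu) / ifelse(sd_ > 0, sd_, Inf)
    z[is.na(z)] <- 0
    ev$expr_low[g, ] <- z <= thresholds$expr_low_z
    ev$expr_high[g, ] <- z >= thresholds$expr_high_z
  }

  lof <- ev$mut_lof | ev$cna_loss | ev$expr_low
  gof <- ev$mut_gof | ev$cna_gain | ev$expr_high
  states <- matrix("WT", nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  states[lof & !gof] <- "LOF"
  states[gof & !lof] <- "GOF"
  states[lof & gof] <- "AMBIGUOUS"
  structure(states, evidence = ev, class = c("alteration_matrix", "matrix"))
}

#' Classify a gene pair into one of the four synthetic-viability classes
#'
#' gene1 carries the primary loss; the rescuer's required state follows its
#' role: a tumor-suppressor rescues by loss, an oncogene by gain. A gene on
#' both lists is resolved by `precedence` (logged).
#'
#' @param gene1,gene2 character vectors of gene symbols (recycled).
#' @param tsg_list,oncogene_list character vectors of gene symbols.
#' @param precedence which role wins when a gene is on both lists.
#' @return character vector of pair classes (`UNTYPED` when a gene is on
#'   neither list).
#' @export
type_pair <- function(gene1, gene2, tsg_list, oncogene_list,
                      precedence = c("tsg", "oncogene")) {
  precedence <- match.arg(precedence)
  role <- function(g) {
    in_tsg <- g %in% tsg_list
    in_og <- g %in% oncogene_list
    both <- in_tsg & in_og
    if (any(both)) {
      message(sum(both), " gene(s) on both TSG and oncogene lists resolved as ",
              precedence)
    }
    out <- rep(NA_character_, length(g))
    out[in_tsg] <- "TSG"
    out[in_og & !in_tsg] <- "OG"
    if (precedence == "oncogene") out[both] <- "OG"
    out
  }
  r1 <- role(gene1); r2 <- role(gene2)
  out <- rep("UNTYPED", length(r1))
  out[r1 == "TSG" & r2 == "TSG"] <- "TSGL_TSGL"
  out[r1 == "OG" & r2 == "OG"] <- "OGL_OGG"
  out[r1 == "OG" & r2 == "TSG"] <- "OGL_TSGL"
  out[r1 == "TSG" & r2 == "OG"] <- "TSGL_OGG"
  out[is.na(r1) | is.na(r2)] <- "UNTYPED"
  out
}

#' Tumor mutational burden: count of non-silent mutation rows per sample
#'
#' Rows are events: duplicated identical rows are counted twice. A sample
#' absent from the table scores 0.
#'
#' @param mut mutation data.frame.
#' @param sample sample id(s).
#' @return integer vector of non-silent mutation counts.
#' @export
tmb <- function(mut, sample) {
  nonsilent <- mut[mut$variant_class != "silent", , drop = FALSE]
  counts <- table(nonsilent$sample)
  out <- as.integer(counts[sample])
  out[is.na(out)] <- 0L
  stats::setNames(out, sample)
}
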