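#' @keywords internal
"_PACKAGE"

## Shared domain types. Matrices are plain numeric/integer matrices with gene
## rownames and sample colnames; tables are data.frames. Light S3 wrappers are
## used only where extra state must travel with the object (dependency scores
## carry lineage labels; alteration calls carry per-layer evidence).

PAIR_TYPES <- c("TSGL_TSGL", "OGL_OGG", "OGL_TSGL", "TSGL_OGG", "UNTYPED")
VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "splice", "silent", "other")
LOF_VARIANT_CLASSES <- c("nonsense", "frameshift", "splice")
RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD")

assert_gene_id <- function(x) {
  bad <- !nzchar(x) | grepl("\\s", x) | is.na(x)
  if (any(bad)) {
    stop("invalid gene id(s): ", paste(utils::head(x[bad]), collapse = ", "))
  }
  invisible(x)
}

#' Canonical representation of a gene pair
#'
#' Symmetric pair classes (both genes carry the same required state, e.g.
#' TSGL_TSGL, or untyped pairs) are stored with genes in lexicographic order so
#' each pair has one representation; asymmetric classes keep gene1 as the
#' primary lesion and gene2 as the rescuer.
#'
#' @param gene1,gene2 character gene symbols.
#' @param pair_type one of `TSGL_TSGL`, `OGL_OGG`, `OGL_TSGL`, `TSGL_OGG`,
#'   `UNTYPED`.
#' @return data.frame with columns `gene1`, `gene2`, `pair_type`.
#' @export
gene_pair <- function(gene1, gene2, pair_type = "UNTYPED") {
  assert_gene_id(gene1); assert_gene_id(gene2)
  pair_type <- match.arg(pair_type, PAIR_TYPES, several.ok = TRUE)
  pair_type <- rep_len(pair_type, length(gene1))
  if (any(gene1 == gene2)) stop("a gene pair must contain two distinct genes")
  symmetric <- pair_type %in% c("TSGL_TSGL", "UNTYPED")
  swap <- symmetric & gene1 > gene2
  g1 <- ifelse(swap, gene2, gene1)
  g2 <- ifelse(swap, gene1, gene2)
  data.frame(gene1 = g1, gene2 = g2, pair_type = pair_type,
             stringsAsFactors = FALSE)
}

#' Required alteration states for a pair class
#'
#' gene1 always carries the primary loss (by alteration or drug inhibition);
#' gene2 carries the rescuing loss or gain depending on the class.
#'
#' @param pair_type character vector of pair classes.
#' @return two-column character matrix (`gene1`, `gene2`) of `"LOF"`/`"GOF"`;
#'   `NA` for untyped pairs.
#' @export
required_states <- function(pair_type) {
  g2 <- c(TSGL_TSGL = "LOF", OGL_OGG = "GOF", OGL_TSGL = "LOF",
          TSGL_OGG = "GOF", UNTYPED = NA_character_)[pair_type]
  g1 <- ifelse(pair_type == "UNTYPED", NA_character_, "LOF")
  cbind(gene1 = unname(g1), gene2 = unname(g2))
}

#' Dependency matrix with cell-line lineage labels
#'
#' @param scores numeric matrix, genes x cell lines; more negative means the
#'   gene is more essential in that line (post-knockout fitness effect).
#' @param lineage named character vector, one lineage label per cell line.
#' @return object of class `dependency_matrix`.
#' @export
dependency_matrix <- function(scores, lineage) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)), !is.null(colnames(scores)))
  missing <- setdiff(colnames(scores), names(lineage))
  if (length(missing)) {
    stop("cell lines without a lineage label: ", paste(utils::head(missing), collapse = ", "))
  }
  structure(list(scores = scores, lineage = lineage[colnames(scores)]),
            class = "dependency_matrix")
}

#' @export
print.dependency_matrix <- function(x, ...) {
  cat("<dependency_matrix> ", nrow(x$scores), " genes x ", ncol(x$scores),
      " cell lines, ", length(unique(x$lineage)), " lineages\n", sep = "")
  invisible(x)
}

validate_clinical <- function(clin) {
  stopifnot(is.data.frame(clin), "patient" %in% names(clin))
  if ("os_event" %in% names(clin)) {
    ev <- clin$os_event[!is.na(clin$os_event)]
    if (!all(ev %in% c(0L, 1L))) stop("os_event must be 0/1")
  }
  if ("os_time" %in% names(clin)) {
    tt <- clin$os_time[!is.na(clin$os_time)]
    if (any(tt <= 0)) stop("os_time must be positive")
  }
  if ("response" %in% names(clin)) {
    r <- clin$response[!is.na(clin$response)]
    if (!all(r %in% RESPONSE_LEVELS)) stop("response must be one of CR/PR/SD/PD or NA")
  }
  invisible(clin)
}
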