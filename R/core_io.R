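## Readers/writers for the plain-text formats the pipeline touches. The
## on-disk dialect for all matrices is TSV with a header row of sample ids and
## gene symbols in the first column (Xena/DepMap style). Gene symbols are
## matched case-sensitively after trimming.

read_tsv_matrix <- function(path, what = "matrix") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed ", what, " header in ", path,
                         ": need a gene column plus at least one sample")
  genes <- trimws(as.character(df[[1]]))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "NA")
      if (length(bad)) {
        stop("non-numeric cell in ", path, " at row ", bad[1] + 1,
             " (gene ", genes[bad[1]], "), column '", names(vals)[j], "'")
      }
      v <- vn
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  m
}

#' Read a gene x sample expression matrix (TSV)
#'
#' Duplicated gene rows are collapsed by their per-sample mean (with a
#' message); NA values are allowed and propagated.
#'
#' @param path path to a TSV with gene symbols in the first column and one
#'   column per sample.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  m <- read_tsv_matrix(path, "expression")
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    message("collapsing ", length(dup), " duplicated gene row(s) by mean: ",
            paste(utils::head(dup), collapse = ", "))
    m <- rowsum(m, group = rownames(m), na.rm = TRUE) /
      as.vector(table(rownames(m))[sort(unique(rownames(m)))])
    ## rowsum sorts groups; restore nothing (order is by symbol) -- acceptable
  }
  assert_gene_id(rownames(m))
  if (anyDuplicated(colnames(m))) stop("duplicated sample ids in ", path)
  m
}

#' Read a GISTIC-style gene-level copy-number matrix (TSV)
#'
#' Values must be integer calls in \{-2,-1,0,1,2\}; duplicate gene rows are an
#' error (calls are categorical); NA is treated as 0 (neutral) with a message.
#'
#' @inheritParams read_expression
#' @return integer matrix, genes x samples.
#' @export
read_cna <- function(path) {
  m <- read_tsv_matrix(path, "copy-number")
  if (anyDuplicated(rownames(m))) {
    stop("duplicated gene rows in CNA matrix: ",
         paste(utils::head(unique(rownames(m)[duplicated(rownames(m))])), collapse = ", "))
  }
  if (anyNA(m)) {
    message("CNA: ", sum(is.na(m)), " NA call(s) treated as 0 (neutral)")
    m[is.na(m)] <- 0
  }
  if (!all(m %in% -2:2)) stop("CNA calls must be GISTIC levels -2..2 in ", path)
  storage.mode(m) <- "integer"
  m
}

#' Read a MAF-like somatic mutation table (TSV)
#'
#' Expected columns: `sample`, `gene`, `variant_class`, optionally
#' `protein_change`. Unknown variant classes are mapped to `"other"` with a
#' warning.
#'
#' @inheritParams read_expression
#' @return data.frame with columns sample, gene, variant_class, protein_change.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "gene", "variant_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mutation table missing column(s): ", paste(miss, collapse = ", "))
  if (!"protein_change" %in% names(df)) df$protein_change <- NA_character_
  unknown <- !(df$variant_class %in% VARIANT_CLASSES)
  if (any(unknown)) {
    warning(sum(unknown), " mutation row(s) with unknown variant class mapped to 'other'")
    df$variant_class[unknown] <- "other"
  }
  df[, c("sample", "gene", "variant_class", "protein_change")]
}

#' Read CRISPR dependency scores plus lineage labels
#'
#' @param path TSV of dependency scores (genes x cell lines).
#' @param lineage_path two-column TSV `cell_line`, `lineage`.
#' @return a [dependency_matrix()].
#' @export
read_dependency <- function(path, lineage_path) {
  m <- read_tsv_matrix(path, "dependency")
  if (anyDuplicated(rownames(m))) stop("duplicated gene rows in dependency matrix")
  lin <- utils::read.delim(lineage_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("cell_line", "lineage") %in% names(lin))) {
    stop("lineage table needs columns cell_line, lineage")
  }
  dependency_matrix(m, stats::setNames(lin$lineage, lin$cell_line))
}

#' Read a per-patient clinical table (TSV)
#'
#' Validates `os_event` in \{0,1\}, `os_time` > 0 and RECIST response codes.
#'
#' @inheritParams read_expression
#' @return data.frame, one row per patient.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_clinical(df)
}

#' Read an undirected edge list (two-column TSV)
#'
#' Self-loops are dropped and undirected duplicates (A-B vs B-A) collapsed.
#'
#' @inheritParams read_expression
#' @return data.frame with columns `from`, `to` (canonical order, from < to).
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list needs two columns")
  edges <- data.frame(from = trimws(df[[1]]), to = trimws(df[[2]]),
                      stringsAsFactors = FALSE)
  loops <- edges$from == edges$to
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- unique(edges)
  rownames(edges) <- NULL
  edges
}

#' Read gene sets in GMT format
#'
#' @inheritParams read_expression
#' @return named list of character vectors, in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) stop("GMT line ", i, " has fewer than 3 fields")
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT line ", i, " defines an empty set")
    nm[i] <- fields[1]
    sets[[i]] <- genes
  }
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  stats::setNames(sets, nm)
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene x sample matrix as TSV
#' @param m matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param gene_col name for the first (gene) column.
#' @export
write_matrix <- function(m, path, gene_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
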