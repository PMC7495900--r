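read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"")
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a gene expression matrix from TSV/CSV
#'
#' Reads a delimited file with a header line and identifiers in the first
#' column, returning genes on rows regardless of the on-disk orientation.
#' Rows (genes) containing missing or non-numeric cells are dropped with a
#' warning stating how many were removed.
#'
#' @param path path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param genes_in `"rows"` (default) if genes are on rows on disk,
#'   `"columns"` if the file stores samples on rows.
#' @param label_row optional name of a row (in the genes-on-rows orientation)
#'   holding the sample class labels; it is extracted into `sample_labels`
#'   and removed from the matrix.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, genes_in = c("rows", "columns"),
                            label_row = NULL) {
  genes_in <- match.arg(genes_in)
  raw <- read_delim_auto(path)
  if (ncol(raw) < 2L) stop("expression file needs an id column plus data: ", path)
  ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(mat) <- ids
  if (genes_in == "columns") mat <- t(mat)
  if (!is.null(label_row)) {
    hit <- match(label_row, rownames(mat))
    if (is.na(hit)) stop("label row '", label_row, "' not found in ", path)
    sample_labels <- as.character(mat[hit, ])
    mat <- mat[-hit, , drop = FALSE]
  } else sample_labels <- NULL
  dup <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = dimnames(mat)))
  bad <- apply(num, 1L, anyNA)
  if (any(bad)) {
    warning("dropped ", sum(bad), " gene row(s) with missing/non-numeric ",
            "values from ", path)
    num <- num[!bad, , drop = FALSE]
  }
  expression_matrix(num, sample_labels = sample_labels)
}

#' Read a precomputed similarity matrix
#'
#' Entry point for a user-supplied view: a square numeric matrix with a
#' matching header row and id column. Small asymmetries (up to 1e-8) are
#' symmetrized as (M + t(M))/2 and the diagonal is forced to 1; entries
#' outside \[0, 1\] or larger asymmetries are rejected.
#'
#' @param path path to a TSV/CSV file.
#' @return a [similarity_view()].
#' @export
read_similarity <- function(path) {
  raw <- read_delim_auto(path)
  ids <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (nrow(m) != ncol(m))
    stop("similarity matrix in ", path, " is not square: ",
         nrow(m), " x ", ncol(m))
  if (!identical(ids, colnames(m)))
    stop("row and column gene ids differ in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  similarity_view(m, gene_ids = ids)
}

#' Write / read a partition as two-column TSV
#'
#' The on-disk format is `id<TAB>cluster` with a header, clusters written as
#' 0-based integers. `read_partition` restores the 1-based internal labels.
#'
#' @param p a `Partition`.
#' @param ids character vector of element identifiers, same length as
#'   `p$labels`.
#' @param path output path.
#' @return `write_partition` returns `path` invisibly; `read_partition`
#'   returns a list with `ids` and `partition`.
#' @export
write_partition <- function(p, ids, path) {
  p <- as_partition(p)
  if (length(ids) != length(p$labels))
    stop("ids length must match the partition size")
  utils::write.table(data.frame(id = ids, cluster = p$labels - 1L),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  list(ids = as.character(tab[[1L]]), partition = partition(tab[[2L]] + 1L))
}

#' Write a gene list, one id per line
#'
#' @param genes character vector of gene ids.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Write the reduced expression matrix for a gene subset
#'
#' Keeps only the selected gene rows, in the order given, preserving the
#' original sample order. Unknown gene ids are rejected.
#'
#' @param em an `ExpressionMatrix`.
#' @param genes character vector, subset of `em$gene_ids`.
#' @param path output path (TSV).
#' @export
write_reduced <- function(em, genes, path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  idx <- match(genes, em$gene_ids)
  if (anyNA(idx))
    stop("gene id(s) not in expression matrix: ",
         paste(genes[is.na(idx)], collapse = ", "))
  out <- data.frame(gene = genes,
                    em$values[idx, , drop = FALSE],
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a similarity view as TSV
#'
#' @param sv a `SimilarityView`.
#' @param path output path.
#' @export
write_similarity <- function(sv, path) {
  stopifnot(inherits(sv, "SimilarityView"))
  out <- data.frame(gene = sv$gene_ids, sv$matrix, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV (genes on rows)
#'
#' @param em an `ExpressionMatrix`.
#' @param path output path.
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  out <- data.frame(gene = em$gene_ids, em$values, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
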