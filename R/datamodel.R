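#' Construct an expression matrix container
#'
#' The central data container of the package: a genes-by-samples real matrix
#' with gene and sample identifiers and, optionally, one class label per
#' sample (used only for external validation of downstream sample clustering).
#'
#' @param values numeric matrix, genes on rows, samples on columns.
#' @param gene_ids character vector of unique gene identifiers (length
#'   `nrow(values)`). Defaults to the rownames of `values`.
#' @param sample_ids character vector of unique sample identifiers (length
#'   `ncol(values)`). Defaults to the colnames of `values`.
#' @param sample_labels optional character vector of class labels, one per
#'   sample.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `sample_labels`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              sample_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length (", length(sample_ids), ") != number of columns (",
         ncol(values), ")")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values after construction")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 genes and 2 samples, got ", nrow(values), " x ",
         ncol(values))
  if (!is.null(sample_labels)) {
    sample_labels <- as.character(sample_labels)
    if (length(sample_labels) != ncol(values))
      stop("sample_labels length must equal the number of samples")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, sample_labels = sample_labels),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples",
      if (is.null(x$sample_labels)) "" else
        paste0("(", length(unique(x$sample_labels)), " sample classes)"),
      "\n")
  invisible(x)
}

#' Construct a similarity view
#'
#' A view is a symmetric gene-gene similarity matrix over a fixed gene index,
#' with entries in \[0, 1\] and unit diagonal. The clustering core consumes
#' only objects of this class, so any data modality (expression distances,
#' GO/PPIN functional similarity, a user-precomputed matrix) enters the
#' algorithm through the same contract.
#'
#' @param matrix numeric n x n matrix of pairwise similarities.
#' @param gene_ids character vector of unique gene identifiers (length n).
#' @param tol tolerance on the \[0,1\] bounds and the symmetry check.
#' @return an object of class `SimilarityView`: list with `gene_ids`, `matrix`.
#' @export
similarity_view <- function(matrix, gene_ids = rownames(matrix), tol = 1e-12) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("similarity matrix must be square")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(m)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(m))
    stop("gene_ids length must match the matrix dimension")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyNA(m)) stop("similarity matrix contains missing values")
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8)
    stop("similarity matrix is asymmetric (max |M - t(M)| = ",
         format(asym), ")")
  m <- (m + t(m)) / 2
  bad <- which(m < -tol | m > 1 + tol, arr.ind = TRUE)
  bad <- bad[order(bad[, 1L], bad[, 2L]), , drop = FALSE]
  if (nrow(bad))
    stop("similarity entry out of [0,1] at [", bad[1, 1], ",", bad[1, 2],
         "]: ", m[bad[1, 1], bad[1, 2]])
  m[m < 0] <- 0
  m[m > 1] <- 1
  diag(m) <- 1
  dimnames(m) <- list(gene_ids, gene_ids)
  structure(list(gene_ids = gene_ids, matrix = m), class = "SimilarityView")
}

#' @export
print.SimilarityView <- function(x, ...) {
  cat("SimilarityView over", length(x$gene_ids), "genes\n")
  invisible(x)
}

#' Construct a partition
#'
#' A total assignment of n elements to K labeled clusters. Internally labels
#' are consecutive integers 1..K with every label used; on disk they are
#' written 0-based (see [write_partition()]).
#'
#' @param labels integer vector of cluster labels, one per element. Arbitrary
#'   label values are accepted and recoded to 1..K preserving first-appearance
#'   order.
#' @return an object of class `Partition`: list with `labels` (1..K) and `K`.
#' @export
partition <- function(labels) {
  if (anyNA(labels)) stop("partition labels contain NA")
  f <- factor(labels, levels = unique(labels))
  lab <- as.integer(f)
  K <- nlevels(f)
  structure(list(labels = lab, K = K), class = "Partition")
}

#' @export
print.Partition <- function(x, ...) {
  cat("Partition of", length(x$labels), "elements into", x$K, "clusters\n")
  invisible(x)
}

#' Co-membership (agreement) matrix of a partition
#'
#' Binary n x n matrix with entry (i, j) = 1 iff elements i and j share a
#' cluster; unit diagonal by construction.
#'
#' @param p a `Partition`.
#' @return integer n x n matrix.
#' @export
comembership <- function(p) {
  stopifnot(inherits(p, "Partition"))
  outer(p$labels, p$labels, "==") * 1L
}

as_partition <- function(p) {
  if (inherits(p, "Partition")) p else partition(p)
}
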