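# View construction. View 1 is expression-based: pairwise similarity
# 1 - Euclidean distance between gene expression profiles. As printed, that
# quantity is unbounded below, so by default distances are first divided by
# the maximum observed pairwise distance, which lands every similarity in
# [0, 1]; normalize = "none" keeps the literal subtraction for audit.
# View 2 is functional: the average of a GO term-set similarity and a PPIN
# similarity, both pluggable callables returning values in [0, 1].

#' Build the expression-distance view
#'
#' @param em an `ExpressionMatrix`.
#' @param normalize `"minmax"` (default): divide all pairwise Euclidean
#'   distances by the maximum observed distance before subtracting from 1;
#'   `"none"`: literal `1 - d` with negative values clipped to 0.
#' @return a `SimilarityView` over `em$gene_ids`.
#' @export
build_view1 <- function(em, normalize = c("minmax", "none")) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  normalize <- match.arg(normalize)
  d <- as.matrix(stats::dist(em$values))
  if (normalize == "minmax") {
    dmax <- max(d)
    if (dmax == 0) {
      warning("all expression profiles identical; all similarities set to 1")
      s <- matrix(1, nrow(d), ncol(d))
    } else s <- 1 - d / dmax
  } else {
    s <- 1 - d
    s[s < 0] <- 0
  }
  dimnames(s) <- dimnames(d)
  similarity_view(s, gene_ids = em$gene_ids)
}

#' Default GO term-set similarity: best-match-average of ancestor Jaccard
#'
#' For two annotation term sets the similarity of a term pair is the Jaccard
#' index of their self-inclusive ancestor sets; each term is matched to its
#' best partner in the other set and the two directional averages are
#' averaged. Returns values in \[0, 1\]; identical term sets give 1.
#'
#' @param ann a `GeneAnnotation`.
#' @return function(gene_i, gene_j) -> similarity in \[0, 1\].
#' @export
go_jaccard_bma <- function(ann) {
  stopifnot(inherits(ann, "GeneAnnotation"))
  anc <- lapply(
    stats::setNames(nm = unique(unlist(ann$terms, use.names = FALSE))),
    function(t) term_ancestors(ann$ontology, t))
  function(gi, gj) {
    ti <- ann$terms[[gi]]; tj <- ann$terms[[gj]]
    if (is.null(ti) || is.null(tj)) stop("gene without annotations: ",
                                         if (is.null(ti)) gi else gj)
    jac <- function(a, b) {
      u <- length(union(a, b))
      if (u == 0) 0 else length(intersect(a, b)) / u
    }
    best <- function(from, to) mean(vapply(from, function(t1)
      max(vapply(to, function(t2) jac(anc[[t1]], anc[[t2]]), numeric(1))),
      numeric(1)))
    (best(ti, tj) + best(tj, ti)) / 2
  }
}

#' Default PPIN similarity: confidence for interacting pairs, else
#' neighborhood Jaccard
#'
#' Interacting protein pairs score their edge confidence; non-interacting
#' pairs score the Jaccard index of their neighbor sets (0 when neither is in
#' the network or they share no neighbors).
#'
#' @param ppin a `PPINetwork`.
#' @return function(gene_i, gene_j) -> similarity in \[0, 1\].
#' @export
ppi_confidence_jaccard <- function(ppin) {
  stopifnot(inherits(ppin, "PPINetwork"))
  nb <- ppin_neighbors(ppin)
  key <- paste(pmin(ppin$edges$a, ppin$edges$b),
               pmax(ppin$edges$a, ppin$edges$b), sep = "\r")
  conf <- stats::setNames(ppin$edges$confidence, key)
  function(gi, gj) {
    a <- ppin_node(ppin, gi); b <- ppin_node(ppin, gj)
    k <- paste(min(a, b), max(a, b), sep = "\r")
    if (!is.na(conf[k])) return(unname(conf[k]))
    na <- nb[[a]]; nbb <- nb[[b]]
    u <- length(union(na, nbb))
    if (u == 0) 0 else length(intersect(na, nbb)) / u
  }
}

#' Build the functional (GO + PPIN) view
#'
#' Each entry is the average of a GO term-set similarity and a PPIN
#' similarity. Both measures are pluggable: any callable mapping a gene pair
#' to \[0, 1\] is accepted, with [go_jaccard_bma()] and
#' [ppi_confidence_jaccard()] as documented defaults. Every gene in
#' `gene_ids` must carry at least one annotation; exclude unannotated genes
#' before calling.
#'
#' @param ann a `GeneAnnotation`.
#' @param ppin a `PPINetwork`.
#' @param gene_ids genes to include (ordered).
#' @param go_sim,ppi_sim pairwise similarity callables; defaults built from
#'   `ann` and `ppin`.
#' @return a `SimilarityView` over `gene_ids`.
#' @export
build_view2 <- function(ann, ppin, gene_ids,
                        go_sim = go_jaccard_bma(ann),
                        ppi_sim = ppi_confidence_jaccard(ppin)) {
  missing_ann <- setdiff(gene_ids, names(ann$terms))
  if (length(missing_ann))
    stop("gene(s) without annotations must be excluded first: ",
         paste(missing_ann, collapse = ", "))
  n <- length(gene_ids)
  s <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    gs <- go_sim(gene_ids[i], gene_ids[j])
    ps <- ppi_sim(gene_ids[i], gene_ids[j])
    if (gs < -1e-12 || gs > 1 + 1e-12 || ps < -1e-12 || ps > 1 + 1e-12)
      stop("similarity callable returned a value outside [0,1] for pair (",
           gene_ids[i], ", ", gene_ids[j], ")")
    s[i, j] <- s[j, i] <- (gs + ps) / 2
  }
  dimnames(s) <- list(gene_ids, gene_ids)
  similarity_view(s, gene_ids = gene_ids)
}

#' Restrict views to their common gene set
#'
#' Re-indexes every view to the sorted intersection of their gene sets; all
#' downstream clustering runs on this aligned index only.
#'
#' @param views list of two or more `SimilarityView`s.
#' @param min_genes smallest usable intersection; below it the views are
#'   rejected (default 4, the minimum the clustering core can work with).
#' @return list with `gene_ids` (the common index) and `views` (restricted
#'   views, same order as input).
#' @export
align_views <- function(views, min_genes = 4L) {
  stopifnot(length(views) >= 2L,
            all(vapply(views, inherits, logical(1), "SimilarityView")))
  common <- Reduce(intersect, lapply(views, `[[`, "gene_ids"))
  if (length(common) == 0L) stop("views share no genes")
  if (length(common) < min_genes)
    stop("views share only ", length(common), " gene(s); need at least ",
         min_genes)
  common <- sort(common)
  restricted <- lapply(views, function(v) {
    idx <- match(common, v$gene_ids)
    similarity_view(v$matrix[idx, idx, drop = FALSE], gene_ids = common)
  })
  list(gene_ids = common, views = restricted)
}
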