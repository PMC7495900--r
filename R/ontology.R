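# Parsers for the functional-similarity view's inputs: Gene Ontology term
# graph (OBO 1.2/1.4), gene-to-term annotations (GAF 2.x) and a protein
# interaction network (two-column TSV or PSI-MITAB). Only the fields the
# similarity defaults consume are retained.

#' Read a Gene Ontology graph from an OBO file
#'
#' Parses `[Term]` stanzas keeping id, name, namespace, obsolescence and the
#' hierarchical edges (`is_a` and `relationship: part_of`). The result is a
#' directed acyclic graph from child terms to their parents, with per-namespace
#' roots (terms without parents).
#'
#' @param path path to an OBO 1.2/1.4 file.
#' @return an object of class `OntologyGraph`: list with `graph` (igraph,
#'   edges child -> parent), `namespace` (named character), `obsolete`
#'   (character vector of obsolete ids), `roots` (named list per namespace).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanza found in ", path)
  stanza_starts <- grep("^\\[", lines)
  ids <- character(0); ns <- character(0); obs <- character(0)
  edges_from <- character(0); edges_to <- character(0); edge_type <- character(0)
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):end]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), block,
                                                 value = TRUE))
      if (length(v)) v[1L] else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) next
    ids <- c(ids, id)
    ns[id] <- get1("namespace")
    if (identical(get1("is_obsolete"), "true")) obs <- c(obs, id)
    isa <- grep("^is_a:", block, value = TRUE)
    if (length(isa)) {
      parents <- sub("^is_a: *([^ !]+).*$", "\\1", isa)
      edges_from <- c(edges_from, rep(id, length(parents)))
      edges_to <- c(edges_to, parents)
      edge_type <- c(edge_type, rep("is_a", length(parents)))
    }
    rel <- grep("^relationship: *part_of ", block, value = TRUE)
    if (length(rel)) {
      parents <- sub("^relationship: *part_of *([^ !]+).*$", "\\1", rel)
      edges_from <- c(edges_from, rep(id, length(parents)))
      edges_to <- c(edges_to, parents)
      edge_type <- c(edge_type, rep("part_of", length(parents)))
    }
  }
  keep <- edges_to %in% ids & edges_from %in% ids
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_from[keep], to = edges_to[keep],
               type = edge_type[keep], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  if (!igraph::is_dag(g)) stop("ontology graph in ", path, " contains a cycle")
  live <- setdiff(ids, obs)
  out_deg <- igraph::degree(g, v = live, mode = "out")
  roots <- split(live[out_deg == 0], ns[live[out_deg == 0]])
  structure(list(graph = g, namespace = ns, obsolete = obs, roots = roots),
            class = "OntologyGraph")
}

#' Ancestor term set (self-inclusive)
#'
#' @param onto an `OntologyGraph`.
#' @param term a term id.
#' @return character vector of the term and all terms reachable by is_a /
#'   part_of edges.
#' @export
term_ancestors <- function(onto, term) {
  if (!term %in% igraph::V(onto$graph)$name) return(character(0))
  names(igraph::subcomponent(onto$graph, term, mode = "out"))
}

#' Read gene annotations (GAF 2.x) against an ontology
#'
#' Restricts annotations to the requested GO namespaces, drops terms that are
#' obsolete or absent from the ontology (with a warning, never an error), and
#' reports genes left with zero surviving annotations as unmapped.
#'
#' @param gaf_path path to a GAF 2.x file (`!` comment lines ignored).
#' @param obo_path path to the OBO file, or an already-parsed `OntologyGraph`.
#' @param namespaces subset of `c("BP","MF","CC")`; default all three.
#' @param id_col GAF column used as the gene identifier (2 = DB Object ID,
#'   the default; 3 = DB Object Symbol).
#' @return list of class `GeneAnnotation`: `terms` (named list gene ->
#'   character vector of term ids), `unmapped` (character vector), and
#'   `ontology` (the `OntologyGraph`).
#' @export
read_annotations <- function(gaf_path, obo_path,
                             namespaces = c("BP", "MF", "CC"),
                             id_col = 2L) {
  namespaces <- match.arg(namespaces, several.ok = TRUE)
  ns_full <- c(BP = "biological_process", MF = "molecular_function",
               CC = "cellular_component")[namespaces]
  onto <- if (inherits(obo_path, "OntologyGraph")) obo_path else
    read_obo(obo_path)
  lines <- readLines(gaf_path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) stop("no annotation rows in ", gaf_path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(fields, function(f) f[[id_col]], character(1))
  terms <- vapply(fields, function(f) f[[5L]], character(1))
  known <- terms %in% igraph::V(onto$graph)$name
  if (any(!known))
    warning("dropped ", sum(!known), " annotation(s) to term(s) absent from ",
            "the ontology: ", paste(unique(terms[!known]), collapse = ", "))
  alive <- known & !(terms %in% onto$obsolete) &
    onto$namespace[terms] %in% ns_full
  ann <- lapply(split(terms[alive], genes[alive]), unique)
  unmapped <- setdiff(unique(genes), names(ann))
  if (length(unmapped))
    message(length(unmapped), " gene(s) unmapped after namespace/obsolete ",
            "filtering: ", paste(unmapped, collapse = ", "))
  structure(list(terms = ann, unmapped = unmapped, ontology = onto),
            class = "GeneAnnotation")
}

#' Read a protein-protein interaction network
#'
#' Accepts either a plain edge list (two id columns plus an optional
#' confidence column) or PSI-MITAB (ids in columns 1-2, confidence parsed
#' from the `score:value` pairs of column 15). The network is undirected and
#' deduplicated keeping the maximum confidence per pair; self-loops are
#' removed; an unreadable score becomes confidence 1 with a warning.
#'
#' @param path path to the network file.
#' @param dialect `"tsv-edges"` (default) or `"psi-mitab"`.
#' @param mapping optional data.frame (gene_id, protein_id) mapping gene ids
#'   to network node ids; identity mapping when omitted.
#' @return object of class `PPINetwork`: list with `edges` (data.frame a, b,
#'   confidence), `mapping`.
#' @export
read_ppin <- function(path, dialect = c("tsv-edges", "psi-mitab"),
                      mapping = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "tsv-edges") {
    a <- vapply(fields, `[[`, character(1), 1L)
    b <- vapply(fields, `[[`, character(1), 2L)
    raw_sc <- vapply(fields, function(f)
      if (length(f) >= 3L) f[[3L]] else NA_character_, character(1))
  } else {
    strip <- function(x) sub("^[^:]*:", "", sub("\\|.*$", "", x))
    a <- strip(vapply(fields, `[[`, character(1), 1L))
    b <- strip(vapply(fields, `[[`, character(1), 2L))
    raw_sc <- vapply(fields, function(f) {
      if (length(f) < 15L) return(NA_character_)
      m <- regmatches(f[[15L]], regexpr("[0-9]*\\.?[0-9]+", f[[15L]]))
      if (length(m)) m else NA_character_
    }, character(1))
  }
  sc <- suppressWarnings(as.numeric(raw_sc))
  unreadable <- is.na(sc) & !is.na(raw_sc) & nzchar(raw_sc)
  if (any(unreadable))
    warning(sum(unreadable), " edge score(s) unreadable; confidence set to 1")
  sc[is.na(sc)] <- 1
  keep <- a != b
  a <- a[keep]; b <- b[keep]; sc <- sc[keep]
  if (!length(a)) {
    edges <- data.frame(a = character(0), b = character(0),
                        confidence = numeric(0))
  } else {
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    conf <- tapply(sc, key, max)
    pairs <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))
    edges <- data.frame(a = pairs[, 1L], b = pairs[, 2L],
                        confidence = as.numeric(conf),
                        stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!is.null(mapping)) {
    mapping <- data.frame(gene_id = as.character(mapping[[1L]]),
                          protein_id = as.character(mapping[[2L]]),
                          stringsAsFactors = FALSE)
  }
  structure(list(edges = edges, mapping = mapping), class = "PPINetwork")
}

ppin_node <- function(ppin, gene) {
  if (is.null(ppin$mapping)) return(gene)
  hit <- match(gene, ppin$mapping$gene_id)
  ifelse(is.na(hit), gene, ppin$mapping$protein_id[hit])
}

ppin_neighbors <- function(ppin) {
  nb <- list()
  for (i in seq_len(nrow(ppin$edges))) {
    a <- ppin$edges$a[i]; b <- ppin$edges$b[i]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nb
}
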