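# On-disk fixtures written into tempfiles at test time.

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

expression_fixture <- function() {
  write_tsv_fixture(c(
    "gene\ts1\ts2",
    "gA\t1.0\t2.0",
    "gB\t3.0\t4.0",
    "gC\t5.0\t6.0"))
}

# five-term two-namespace ontology; T5 is obsolete
obo_fixture <- function() {
  path <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: bp root",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: bp child",
    "namespace: biological_process",
    "is_a: GO:0000001 ! bp root",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: bp grandchild",
    "namespace: biological_process",
    "is_a: GO:0000002 ! bp child",
    "relationship: part_of GO:0000001 ! bp root",
    "",
    "[Term]",
    "id: GO:0000004",
    "name: mf root",
    "namespace: molecular_function",
    "",
    "[Term]",
    "id: GO:0000005",
    "name: gone",
    "namespace: biological_process",
    "is_obsolete: true"), path)
  path
}

gaf_line <- function(gene, term, aspect = "P") {
  paste("DB", gene, gene, "", term, "PMID:1", "IEA", "", aspect,
        "", "", "protein", "taxon:9606", "20200101", "DB", "", "",
        sep = "\t")
}

gaf_fixture <- function(lines) {
  path <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1", lines), path)
  path
}

ppin_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
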