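#' Construct a regulator gene list
#'
#' @param name List name ("positive", "negative", or user-defined).
#' @param symbols Character vector of gene symbols; upper-cased and
#'   de-duplicated.
#' @param provenance Free-text provenance (GO term ids and/or "curated").
#' @return An object of class `regulator_list` with elements `name`,
#'   `symbols`, `provenance`.
#' @export
regulator_list <- function(name, symbols, provenance = "") {
  symbols <- unique(toupper(as.character(symbols)))
  symbols <- symbols[nzchar(symbols)]
  structure(list(name = name, symbols = symbols, provenance = provenance),
            class = "regulator_list")
}

#' @export
print.regulator_list <- function(x, ...) {
  cat("Regulator gene list '", x$name, "': ", length(x$symbols),
      " symbols\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  cat("  ", paste(utils::head(x$symbols, 10L), collapse = ", "),
      if (length(x$symbols) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.regulator_list <- function(x) length(x$symbols)

#' Descendant closure of an ontology term
#'
#' Returns the root plus every term from which the root is reachable along
#' child-to-parent `is_a`/`part_of` edges (i.e. the root and all of its
#' descendants).
#'
#' @param graph An `ontology_graph` from [read_obo()].
#' @param root Term identifier present in the graph.
#' @return Character vector of term ids (root included), each once.
#' @export
term_closure <- function(graph, root) {
  if (!root %in% names(graph$terms))
    stop("unknown ontology term: ", root)
  edges <- graph$edges[graph$edges$relation %in% c("is_a", "part_of"), ,
                       drop = FALSE]
  closed <- character(); frontier <- root
  while (length(frontier) > 0L) {
    closed <- c(closed, frontier)
    frontier <- unique(edges$child[edges$parent %in% frontier])
    frontier <- setdiff(frontier, closed)
  }
  unique(closed)
}

#' Genes annotated to any of a set of terms
#'
#' @param annotations Annotation data.frame from [read_gaf()] (NOT-qualified
#'   annotations are already excluded on load).
#' @param terms Character vector of term ids.
#' @return Character vector of upper-case gene symbols (possibly empty).
#' @export
genes_for <- function(annotations, terms) {
  sort(unique(annotations$gene_symbol[annotations$term_id %in% terms]))
}

#' Build the positive-regulator gene list by term-closure subtraction
#'
#' Collects all genes annotated under the positive-regulation root, then
#' removes any gene also annotated under the negative-regulation root. Only
#' `is_a` and `part_of` edges are followed, so the two families cannot
#' engulf each other through regulatory cross-links.
#'
#' @param annotations Annotation data.frame from [read_gaf()].
#' @param graph An `ontology_graph`.
#' @param positive_root Root term of positive regulation of immune system
#'   process (default `GO:0002684`).
#' @param negative_root Root term of negative regulation of immune system
#'   process (default `GO:0002683`).
#' @return A `regulator_list` named "positive"; provenance records both
#'   roots. Warns if the subtraction empties the list.
#' @export
build_positive_list <- function(annotations, graph,
                                positive_root = "GO:0002684",
                                negative_root = "GO:0002683") {
  pos_genes <- genes_for(annotations, term_closure(graph, positive_root))
  neg_genes <- genes_for(annotations, term_closure(graph, negative_root))
  symbols <- setdiff(pos_genes, neg_genes)
  if (length(symbols) == 0L)
    warning("positive-regulator list is empty after subtracting ",
            negative_root)
  stopifnot(length(intersect(symbols, neg_genes)) == 0L)
  regulator_list("positive", symbols,
                 provenance = paste0("closure(", positive_root,
                                     ") minus closure(", negative_root, ")"))
}

#' The curated negative-regulator gene list
#'
#' The unique gene symbols of the packaged negative-regulator table, plus
#' the qPCR/immunohistochemistry panel members not measured on the array
#' table under their official symbols (LAG3, PDCD1, IDO1, IL10; PD1 is
#' PDCD1, PDL1 is CD274, PDL2 is PDCD1LG2 — the ligands are already present
#' via the table).
#'
#' @return A `regulator_list` named "negative".
#' @export
load_negative_list <- function() {
  tab <- load_table1_fixture()
  regulator_list("negative",
                 c(tab$gene_symbol, "LAG3", "PDCD1", "IDO1", "IL10"),
                 provenance = "curated: packaged table + literature panel")
}

#' Map gene symbols to array probes
#'
#' @param list A `regulator_list`.
#' @param platform A `differential_table` or any data.frame with `probe_id`
#'   and `gene_symbol` columns.
#' @return Character vector of probe ids whose symbol is in the list. The
#'   `coverage` attribute is a list with `matched` and `missing` symbols
#'   (symbols with no probe are reported, not an error).
#' @export
map_symbols_to_probes <- function(list, platform) {
  stopifnot(all(c("probe_id", "gene_symbol") %in% colnames(platform)))
  hit <- platform$gene_symbol %in% list$symbols
  probes <- unique(platform$probe_id[hit])
  matched <- intersect(list$symbols, platform$gene_symbol)
  structure(probes,
            coverage = list(matched = matched,
                            missing = setdiff(list$symbols, matched)))
}
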