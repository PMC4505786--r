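#' Read a log2 expression matrix from a tab-separated file
#'
#' The file layout is one header row of sample identifiers, a first column of
#' probe identifiers, and one log2 intensity per (probe, sample) cell.
#'
#' @param path Path to a tab-separated text file.
#' @return A numeric matrix (probes x samples) with unique row and column
#'   names and no missing or non-finite values.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L)
    stop("expression matrix file must have a probe column and >= 1 sample column")
  probes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(probes))
    stop("duplicate probe IDs: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample IDs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(probes, samples))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric or non-finite value at probe '%s', sample '%s'",
                 probes[bad[1L, 1L]], samples[bad[1L, 2L]]))
  vals
}

#' Write an expression matrix to a tab-separated file
#'
#' @param mat Numeric matrix with probe row names and sample column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(Probe = rownames(mat),
                   format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' Expected columns: `sample_id`, `subject_id`, `treatment`, and optionally
#' `day` and `batch`.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with one row per sample.
#' @export
read_sample_design <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "subject_id", "treatment")
  miss <- setdiff(req, colnames(d))
  if (length(miss) > 0L)
    stop("design table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample IDs in design table")
  d
}

#' Write a sample design table
#' @param design Data.frame as returned by [read_sample_design()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Parses a tab-separated table with columns `Probe`, `Symbol`, `Description`,
#' then a `(FCH, p, FDR)` column triple per contrast, suffixed with the
#' contrast name (e.g. `FCH_dpcp_d3`). Scientific notation such as `5.3E-11`
#' is parsed exactly; printed `0.0E+00` values are retained as 0.
#'
#' @param path Path to the table.
#' @param contrasts Character vector of contrast name suffixes expected in the
#'   header (e.g. `c("dpcp_d3", "pso")`).
#' @return A data.frame of class `differential_table` with columns `probe_id`,
#'   `gene_symbol`, `description`, and per contrast `fch_<c>`, `p_<c>`,
#'   `fdr_<c>`; the `contrasts` attribute records the contrast names.
#' @export
read_differential_table <- function(path, contrasts) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("Probe", "Symbol"))
    if (!col %in% colnames(d)) stop("missing required column: ", col)
  out <- data.frame(probe_id = as.character(d$Probe),
                    gene_symbol = toupper(as.character(d$Symbol)),
                    stringsAsFactors = FALSE)
  out$description <- if ("Description" %in% colnames(d))
    as.character(d$Description) else rep(NA_character_, nrow(out))
  for (ct in contrasts) {
    for (fld in c("FCH", "p", "FDR")) {
      col <- paste(fld, ct, sep = "_")
      if (!col %in% colnames(d)) stop("missing required column: ", col)
      out[[paste(tolower(fld), ct, sep = "_")]] <- as.numeric(d[[col]])
    }
  }
  validate_differential_table(out, contrasts, check_fdr_ge_p = FALSE)
  structure(out, contrasts = contrasts, class = c("differential_table",
                                                  "data.frame"))
}

validate_differential_table <- function(tab, contrasts, check_fdr_ge_p = TRUE) {
  for (ct in contrasts) {
    fch <- tab[[paste0("fch_", ct)]]
    p <- tab[[paste0("p_", ct)]]
    fdr <- tab[[paste0("fdr_", ct)]]
    if (any(!is.finite(fch)) || any(fch <= 0))
      stop("FCH must be finite and > 0 (contrast ", ct, ")")
    if (any(p < 0 | p > 1) || any(fdr < 0 | fdr > 1))
      stop("p and FDR must lie in [0, 1] (contrast ", ct, ")")
    # Printed tables round (e.g. 0.0E+00), so FDR >= p is only enforced for
    # tables this pipeline computed.
    if (check_fdr_ge_p && any(fdr < p))
      stop("FDR below raw p (contrast ", ct, ")")
  }
  invisible(tab)
}

#' Write a differential-expression table
#'
#' Inverse of [read_differential_table()]: emits `Probe`, `Symbol`,
#' `Description` and `(FCH, p, FDR)_<contrast>` columns, tab-separated.
#'
#' @param tab A `differential_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(tab, path) {
  contrasts <- attr(tab, "contrasts")
  out <- data.frame(Probe = tab$probe_id, Symbol = tab$gene_symbol,
                    Description = tab$description,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (ct in contrasts) {
    out[[paste0("FCH_", ct)]] <- format(tab[[paste0("fch_", ct)]], digits = 15)
    out[[paste0("p_", ct)]] <- format(tab[[paste0("p_", ct)]], digits = 15)
    out[[paste0("FDR_", ct)]] <- format(tab[[paste0("fdr_", ct)]], digits = 15)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the packaged negative-regulator differential table
#'
#' A curated table of negative immune-regulator probes with linear fold
#' change, raw p, and BH-adjusted FDR for the DPCP day-3 vs placebo contrast
#' (`dpcp_d3`) and the psoriasis lesional vs non-lesional contrast (`pso`).
#'
#' @return A `differential_table` with contrasts `dpcp_d3` and `pso`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "negative_regulators_dpcp_psoriasis.tsv",
                      package = "immunobalance")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged negative-regulator table not found; reinstall the package")
  tab <- read_differential_table(path, contrasts = c("dpcp_d3", "pso"))
  if (nrow(tab) != 80L)
    stop("packaged negative-regulator table is corrupt: expected 80 rows, got ",
         nrow(tab))
  tab
}

#' Read a plain-text gene list
#'
#' One symbol per line; lines starting with `#` are treated as provenance
#' comments. Symbols are upper-cased and de-duplicated.
#'
#' @param path Path to the list file.
#' @param name List name (defaults to the file name without extension).
#' @return A `regulator_list` object; see [regulator_list()].
#' @export
read_gene_list <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  prov <- sub("^#\\s*", "", lines[startsWith(lines, "#")])
  syms <- trimws(lines[!startsWith(lines, "#")])
  syms <- syms[nzchar(syms)]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  regulator_list(name, syms,
                 provenance = if (length(prov)) paste(prov, collapse = "; ")
                 else "file")
}

#' Write a gene list to a plain-text file
#' @param list A `regulator_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(list, path) {
  writeLines(c(paste0("# ", list$name, ": ", list$provenance), list$symbols),
             path)
  invisible(path)
}

#' Read GO annotations from a GAF 2.x file
#'
#' Keeps the (gene symbol, term id) pairs; comment lines (`!`) are skipped
#' and annotations qualified `NOT` are excluded. Symbols are upper-cased.
#'
#' @param path Path to a GAF file.
#' @return A data.frame with columns `gene_symbol`, `term_id`, `evidence`.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(gene_symbol = character(), term_id = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 0L)
  if (any(nf < 7L))
    stop("malformed GAF line (fewer than 7 columns): line ",
         which(nf < 7L)[1L])
  sym <- toupper(vapply(parts, `[[`, "", 3L))
  qual <- vapply(parts, `[[`, "", 4L)
  term <- vapply(parts, `[[`, "", 5L)
  evid <- vapply(parts, `[[`, "", 7L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
  bad <- !grepl("^GO:[0-9]{7}$", term[keep])
  if (any(bad))
    stop("invalid GO term identifier: ", term[keep][bad][1L])
  out <- data.frame(gene_symbol = sym[keep], term_id = term[keep],
                    evidence = evid[keep], stringsAsFactors = FALSE)
  unique(out)
}

#' Read an ontology from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas, keeping `id`, `name`, `is_a` edges and
#' `relationship: part_of` edges. Obsolete terms are dropped. The edge set
#' must be acyclic.
#'
#' @param path Path to an OBO file.
#' @return A list of class `ontology_graph` with elements `terms` (named
#'   character vector: names are term ids, values are term names) and `edges`
#'   (data.frame `child`, `parent`, `relation`).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character(); term_names <- character()
  child <- character(); parent <- character(); relation <- character()
  cur_id <- NA_character_; cur_name <- NA_character_
  in_term <- FALSE; obsolete <- FALSE
  cur_edges <- list()
  flush <- function() {
    if (in_term && !obsolete) {
      if (is.na(cur_id)) stop("malformed OBO stanza: [Term] without id")
      terms[[length(terms) + 1L]] <<- cur_id
      term_names[[length(term_names) + 1L]] <<-
        if (is.na(cur_name)) cur_id else cur_name
      for (e in cur_edges) {
        child[[length(child) + 1L]] <<- cur_id
        parent[[length(parent) + 1L]] <<- e[[1L]]
        relation[[length(relation) + 1L]] <<- e[[2L]]
      }
    }
  }
  for (line in lines) {
    line <- sub("!.*$", "", line)
    line <- trimws(line)
    if (line == "[Term]") {
      flush()
      in_term <- TRUE; obsolete <- FALSE
      cur_id <- NA_character_; cur_name <- NA_character_; cur_edges <- list()
    } else if (startsWith(line, "[")) {
      flush(); in_term <- FALSE
    } else if (in_term && nzchar(line)) {
      if (startsWith(line, "id:")) {
        cur_id <- trimws(sub("^id:", "", line))
      } else if (startsWith(line, "name:")) {
        cur_name <- trimws(sub("^name:", "", line))
      } else if (startsWith(line, "is_a:")) {
        cur_edges[[length(cur_edges) + 1L]] <-
          list(trimws(sub("^is_a:", "", line)), "is_a")
      } else if (startsWith(line, "relationship:")) {
        rest <- strsplit(trimws(sub("^relationship:", "", line)), "\\s+")[[1L]]
        if (length(rest) >= 2L && rest[1L] == "part_of")
          cur_edges[[length(cur_edges) + 1L]] <- list(rest[2L], "part_of")
      } else if (line == "is_obsolete: true") {
        obsolete <- TRUE
      }
    }
  }
  flush()
  if (anyDuplicated(terms)) stop("malformed OBO: duplicated term id")
  known <- terms
  dangling <- !(parent %in% known)
  if (any(dangling)) {
    # parents referenced but not declared get a stub entry so every edge
    # endpoint exists
    extra <- unique(parent[dangling])
    known <- c(known, extra)
    term_names <- c(term_names, extra)
  }
  g <- structure(list(
    terms = stats::setNames(term_names, known),
    edges = data.frame(child = child, parent = parent, relation = relation,
                       stringsAsFactors = FALSE)),
    class = "ontology_graph")
  assert_acyclic(g)
  g
}

# Kahn's algorithm; stops on a cycle over is_a/part_of edges.
assert_acyclic <- function(graph) {
  edges <- graph$edges
  nodes <- names(graph$terms)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tb <- table(edges$parent)
  indeg[names(tb)] <- as.integer(tb)
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    n <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    ps <- edges$parent[edges$child == n]
    for (p in ps) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < length(nodes))
    stop("cyclic is_a/part_of chain in ontology")
  invisible(TRUE)
}

#' Write an ontology graph to an OBO 1.2 file
#' @param graph An `ontology_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (id in names(graph$terms)) {
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", graph$terms[[id]])), con)
    e <- graph$edges[graph$edges$child == id, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      if (e$relation[i] == "is_a")
        writeLines(paste0("is_a: ", e$parent[i]), con)
      else
        writeLines(paste0("relationship: part_of ", e$parent[i]), con)
    }
  }
  invisible(path)
}

#' Write an annotation set to a minimal GAF 2.2 file
#' @param annotations Data.frame with `gene_symbol`, `term_id`, optional
#'   `evidence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path) {
  ev <- if ("evidence" %in% colnames(annotations)) annotations$evidence
        else rep("IEA", nrow(annotations))
  lines <- sprintf("DB\t%s\t%s\t\t%s\t REF\t%s\tP\t%s\t\tprotein\ttaxon:9606\t20150611\tDB",
                   annotations$gene_symbol, annotations$gene_symbol,
                   annotations$term_id, ev, annotations$gene_symbol)
  writeLines(c("!gaf-version: 2.2", lines), path)
  invisible(path)
}

#' Read a qPCR cycle-threshold table
#'
#' Expected tab-separated columns: `sample_id`, `group`, `target_gene`,
#' `ct_target`, `ct_housekeeping`. Rows with a missing housekeeping Ct are
#' dropped with a warning.
#'
#' @param path Path to the table.
#' @return A data.frame with the columns above; Ct values finite and > 0.
#' @export
read_qpcr_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "group", "target_gene", "ct_target", "ct_housekeeping")
  miss <- setdiff(req, colnames(d))
  if (length(miss) > 0L)
    stop("qPCR table missing column(s): ", paste(miss, collapse = ", "))
  drop <- !is.finite(d$ct_housekeeping)
  if (any(drop)) {
    warning(sum(drop), " row(s) dropped: missing housekeeping Ct")
    d <- d[!drop, , drop = FALSE]
  }
  if (any(!is.finite(d$ct_target) | d$ct_target <= 0 | d$ct_housekeeping <= 0))
    stop("Ct values must be finite and > 0")
  d
}
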