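#' Collapse probes to genes by the representative-probe rule
#'
#' One representative probe per gene: the probe with the maximum
#' `|log2(FCH)|` for the given contrast, ties broken lexicographically by
#' probe id. This matches how a gene's fold change is conventionally quoted
#' (its strongest probe).
#'
#' @param table A `differential_table`.
#' @param contrast Contrast name (suffix of the fch/p/fdr columns).
#' @return A data.frame with one row per gene symbol: `gene_symbol`,
#'   `probe_id`, `fch`, `p`, `fdr`.
#' @export
collapse_to_genes <- function(table, contrast) {
  fch <- table[[paste0("fch_", contrast)]]
  if (is.null(fch)) stop("unknown contrast: ", contrast)
  ord <- order(table$gene_symbol, -abs(log2(fch)), table$probe_id)
  t2 <- table[ord, , drop = FALSE]
  first <- !duplicated(t2$gene_symbol)
  data.frame(gene_symbol = t2$gene_symbol[first],
             probe_id = t2$probe_id[first],
             fch = t2[[paste0("fch_", contrast)]][first],
             p = t2[[paste0("p_", contrast)]][first],
             fdr = t2[[paste0("fdr_", contrast)]][first],
             stringsAsFactors = FALSE)
}

#' Define a transcriptome by fold-change and FDR thresholds
#'
#' At probe level, keeps probes passing `fdr < fdr_max` and the directional
#' fold-change test (`FCH >= fch_min` up, `FCH <= 1/fch_min` down, either
#' for both). At gene level, probes are first collapsed to their
#' representative probe ([collapse_to_genes()]) and the thresholds applied
#' to the representative.
#'
#' @param table A `differential_table`.
#' @param contrast Contrast name.
#' @param fch_min Minimum linear fold change (>= 1; default 2).
#' @param fdr_max FDR threshold (default 0.05).
#' @param direction `"up"`, `"down"`, or `"both"`.
#' @param level `"probe"` or `"gene"`.
#' @return Object of class `transcriptome`: `members` (probe ids or gene
#'   symbols), `fch` (named per-member linear fold change), plus the
#'   thresholds, contrast, direction and level used.
#' @export
define_transcriptome <- function(table, contrast, fch_min = 2,
                                 fdr_max = 0.05,
                                 direction = c("up", "down", "both"),
                                 level = c("probe", "gene")) {
  direction <- match.arg(direction)
  level <- match.arg(level)
  stopifnot(fch_min >= 1, fdr_max > 0, fdr_max <= 1)
  if (!paste0("fch_", contrast) %in% colnames(table))
    stop("unknown contrast: ", contrast)
  if (level == "gene") {
    g <- collapse_to_genes(table, contrast)
    ids <- g$gene_symbol; fch <- g$fch; fdr <- g$fdr
  } else {
    ids <- table$probe_id
    fch <- table[[paste0("fch_", contrast)]]
    fdr <- table[[paste0("fdr_", contrast)]]
  }
  pass_dir <- switch(direction,
                     up = fch >= fch_min,
                     down = fch <= 1 / fch_min,
                     both = fch >= fch_min | fch <= 1 / fch_min)
  keep <- fdr < fdr_max & pass_dir
  structure(list(contrast = contrast, level = level, direction = direction,
                 members = ids[keep],
                 fch = stats::setNames(fch[keep], ids[keep]),
                 fch_min = fch_min, fdr_max = fdr_max),
            class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("Transcriptome '%s' (%s level, %s): %d members (FCH >= %g, FDR < %g)\n",
              x$contrast, x$level, x$direction, length(x$members),
              x$fch_min, x$fdr_max))
  invisible(x)
}

#' @export
length.transcriptome <- function(x) length(x$members)

#' Overlap of a transcriptome with a regulator gene list
#'
#' @param t A `transcriptome`. Must be gene-level, or a probe-to-symbol map
#'   must be supplied.
#' @param list A `regulator_list`.
#' @param probe_map Named character vector probe id -> gene symbol, required
#'   when `t` is probe-level.
#' @return List with `n` (overlap count) and `members` (the intersecting
#'   gene symbols).
#' @export
overlap <- function(t, list, probe_map = NULL) {
  if (t$level == "gene") {
    syms <- t$members
  } else {
    if (is.null(probe_map))
      stop("probe-level transcriptome needs a probe_map (probe -> symbol)")
    syms <- unique(toupper(unname(probe_map[t$members])))
    syms <- syms[!is.na(syms)]
  }
  inter <- intersect(syms, list$symbols)
  list(n = length(inter), members = sort(inter))
}

#' Gene-list enrichment in a transcriptome (2x2 odds ratio)
#'
#' Fills the 2x2 table of list membership versus transcriptome membership
#' over a stated gene universe: `a` in both, `b` list only, `c`
#' transcriptome only, `d` neither. The sample odds ratio is `(a d)/(b c)`
#' with a Haldane-Anscombe +0.5 correction on every cell when any cell is
#' zero; the 95% CI is Woolf's (normal on the log odds ratio); the p-value
#' is the exact conditional two-sided test on the table.
#'
#' @param t A gene-level `transcriptome` (members must lie in `universe`).
#' @param list A `regulator_list` (restricted to `universe` before
#'   counting).
#' @param universe Character vector of gene symbols defining the universe.
#' @return Object of class `enrichment_result`: `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `ci95`, `p`, `continuity_corrected`.
#' @export
enrichment <- function(t, list, universe) {
  universe <- unique(toupper(universe))
  if (t$level != "gene")
    stop("enrichment requires a gene-level transcriptome")
  members <- toupper(t$members)
  if (!all(members %in% universe))
    stop("transcriptome members outside the stated universe")
  in_t <- universe %in% members
  in_l <- universe %in% list$symbols
  a <- sum(in_l & in_t); b <- sum(in_l & !in_t)
  c_ <- sum(!in_l & in_t); d <- sum(!in_l & !in_t)
  corrected <- any(c(a, b, c_, d) == 0L)
  cc <- if (corrected) 0.5 else 0
  or <- ((a + cc) * (d + cc)) / ((b + cc) * (c_ + cc))
  se_log <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c_ + cc) + 1 / (d + cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))$p.value
  structure(list(a = a, b = b, c = c_, d = d, odds_ratio = or,
                 ci95 = ci, p = p, continuity_corrected = corrected,
                 universe_size = length(universe)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment 2x2 [a=%d b=%d c=%d d=%d]: OR = %.3g (95%% CI %.3g-%.3g), p = %.3g%s\n",
              x$a, x$b, x$c, x$d, x$odds_ratio, x$ci95[1], x$ci95[2], x$p,
              if (x$continuity_corrected) " [continuity-corrected]" else ""))
  invisible(x)
}

#' Negative-to-positive regulator balance score
#'
#' Summarizes one contrast's expression of two gene lists after gene
#' collapse: mean log2 fold change over each list's genes and their ratio
#' (`expr_ratio = mean_neg / mean_pos`), plus transcriptome overlap counts
#' and their ratio (`count_ratio = n_neg / n_pos`).
#'
#' The averaging scope is a choice the data do not force: `"list"` averages
#' over every list gene present on the array table, `"transcriptome"` only
#' over list genes inside the thresholded transcriptome.
#'
#' @param table A `differential_table`.
#' @param contrast Contrast name.
#' @param neg,pos `regulator_list`s (non-empty after restriction to the
#'   table).
#' @param scope `"list"` or `"transcriptome"` (averaging scope for mean
#'   log2 FCH).
#' @param fch_min,fdr_max,direction Transcriptome thresholds used for the
#'   counts (and for `scope = "transcriptome"` averaging).
#' @return Object of class `balance_score`: `n_neg`, `n_pos`,
#'   `count_ratio`, `mean_log2fch_neg`, `mean_log2fch_pos`, `expr_ratio`,
#'   `ratio_defined` flag, and the parameters used.
#' @export
balance_score <- function(table, contrast, neg, pos,
                          scope = c("list", "transcriptome"),
                          fch_min = 2, fdr_max = 0.05, direction = "up") {
  scope <- match.arg(scope)
  genes <- collapse_to_genes(table, contrast)
  tr <- define_transcriptome(table, contrast, fch_min = fch_min,
                             fdr_max = fdr_max, direction = direction,
                             level = "gene")
  n_neg <- overlap(tr, neg)$n
  n_pos <- overlap(tr, pos)$n
  base <- if (scope == "list") genes$gene_symbol else tr$members
  g_neg <- intersect(base, neg$symbols)
  g_pos <- intersect(base, pos$symbols)
  if (length(intersect(genes$gene_symbol, neg$symbols)) == 0L ||
      length(intersect(genes$gene_symbol, pos$symbols)) == 0L)
    stop("a regulator list has no genes on the table")
  lf <- stats::setNames(log2(genes$fch), genes$gene_symbol)
  mean_neg <- if (length(g_neg)) mean(lf[g_neg]) else NA_real_
  mean_pos <- if (length(g_pos)) mean(lf[g_pos]) else NA_real_
  defined <- is.finite(mean_neg) && is.finite(mean_pos) &&
    abs(mean_pos) > 1e-8
  structure(list(contrast = contrast, scope = scope,
                 n_neg = n_neg, n_pos = n_pos,
                 count_ratio = if (n_pos > 0) n_neg / n_pos else NA_real_,
                 mean_log2fch_neg = mean_neg, mean_log2fch_pos = mean_pos,
                 expr_ratio = if (defined) mean_neg / mean_pos else NA_real_,
                 ratio_defined = defined,
                 fch_min = fch_min, fdr_max = fdr_max,
                 direction = direction),
            class = "balance_score")
}

#' @export
print.balance_score <- function(x, ...) {
  cat(sprintf("Balance score for '%s' (scope %s):\n", x$contrast, x$scope))
  cat(sprintf("  counts: neg %d, pos %d, ratio %s\n", x$n_neg, x$n_pos,
              format(x$count_ratio, digits = 3)))
  cat(sprintf("  mean log2FCH: neg %.3f, pos %.3f, expr_ratio %s%s\n",
              x$mean_log2fch_neg, x$mean_log2fch_pos,
              format(x$expr_ratio, digits = 3),
              if (!x$ratio_defined) " [undefined/unstable]" else ""))
  invisible(x)
}

#' Compare balance scores across contrasts
#'
#' Tabulates per-contrast balance scores and reports which contrast has the
#' higher negative-to-positive expression ratio (ties reported explicitly).
#'
#' @param scores Named list of `balance_score` objects (>= 2).
#' @return Object of class `balance_comparison`: a data.frame `table` (one
#'   row per contrast) and `ordering`, the contrast names sorted by
#'   decreasing `expr_ratio`, plus a `ties` flag.
#' @export
compare_balance <- function(scores) {
  if (length(scores) < 2L) stop("need >= 2 contrasts to compare")
  if (is.null(names(scores)))
    names(scores) <- vapply(scores, `[[`, "", "contrast")
  tab <- do.call(rbind, lapply(names(scores), function(nm) {
    s <- scores[[nm]]
    data.frame(contrast = nm, n_neg = s$n_neg, n_pos = s$n_pos,
               count_ratio = s$count_ratio,
               mean_log2fch_neg = s$mean_log2fch_neg,
               mean_log2fch_pos = s$mean_log2fch_pos,
               expr_ratio = s$expr_ratio, stringsAsFactors = FALSE)
  }))
  ord <- order(-tab$expr_ratio)
  ties <- anyDuplicated(tab$expr_ratio[!is.na(tab$expr_ratio)]) > 0L
  structure(list(table = tab[ord, , drop = FALSE],
                 ordering = tab$contrast[ord], ties = ties),
            class = "balance_comparison")
}

#' @export
print.balance_comparison <- function(x, ...) {
  cat("Negative-to-positive regulator balance, by contrast:\n")
  print(x$table, row.names = FALSE, digits = 3)
  if (x$ties) cat("Note: tied expression ratios.\n")
  else cat("Highest expression ratio:", x$ordering[1L], "\n")
  invisible(x)
}
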