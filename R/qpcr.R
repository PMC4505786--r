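#' Housekeeping-normalized qPCR expression
#'
#' `expression = 2^-(ct_target - ct_housekeeping)`, the delta-Ct rule at
#' amplification efficiency 2. Adding any constant to both Ct columns
#' leaves the result unchanged.
#'
#' @param table qPCR data.frame (see [read_qpcr_table()]).
#' @return The table with a `normalized` column appended (strictly
#'   positive). Rows missing the housekeeping Ct are dropped with a
#'   warning.
#' @export
normalize_ct <- function(table) {
  drop <- !is.finite(table$ct_housekeeping)
  if (any(drop)) {
    warning(sum(drop), " row(s) dropped: missing housekeeping Ct")
    table <- table[!drop, , drop = FALSE]
  }
  table$normalized <- 2^(-(table$ct_target - table$ct_housekeeping))
  table
}

#' Two-group comparison of qPCR expression
#'
#' Unpaired two-tailed pooled-variance (equal-variance) t-test on the two
#' groups' values, with group means and standard errors of the mean.
#'
#' @param values_a,values_b Numeric vectors (each n >= 2), e.g. normalized
#'   expression per sample in each group.
#' @return One-row data.frame: `n_a`, `mean_a`, `sem_a`, `n_b`, `mean_b`,
#'   `sem_b`, `t`, `df`, `p`, `degenerate` (zero pooled variance with
#'   unequal means).
#' @export
group_compare <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop("both groups need n >= 2")
  pooled <- ((na - 1) * stats::var(values_a) +
             (nb - 1) * stats::var(values_b)) / (na + nb - 2)
  degenerate <- FALSE
  if (pooled == 0) {
    if (mean(values_a) == mean(values_b)) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean(values_a) - mean(values_b)) * Inf
      p <- 0; degenerate <- TRUE
    }
    df <- na + nb - 2L
  } else {
    ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
    t_stat <- unname(ht$statistic); df <- unname(ht$parameter)
    p <- ht$p.value
  }
  data.frame(n_a = na, mean_a = mean(values_a),
             sem_a = stats::sd(values_a) / sqrt(na),
             n_b = nb, mean_b = mean(values_b),
             sem_b = stats::sd(values_b) / sqrt(nb),
             t = t_stat, df = df, p = p, degenerate = degenerate)
}

#' Per-target qPCR summary across two groups
#'
#' Normalizes a Ct table ([normalize_ct()]) and, for each target gene,
#' compares the two groups' expression with [group_compare()]. By default
#' the test is run on the linear normalized expression (how bar plots of
#' qPCR data are usually drawn); `log_scale = TRUE` tests the delta-Ct
#' (i.e. log2 expression) instead.
#'
#' @param table qPCR data.frame.
#' @param groups Length-2 character vector selecting and ordering the
#'   groups (defaults to the two groups present).
#' @param log_scale Test on log2 expression (delta-Ct) instead of linear.
#' @return Data.frame with one row per target gene: group ns, means, SEMs,
#'   `t`, `df`, `p`.
#' @export
qpcr_summary <- function(table, groups = NULL, log_scale = FALSE) {
  tab <- normalize_ct(table)
  if (is.null(groups)) groups <- unique(tab$group)
  if (length(groups) != 2L) stop("exactly two groups required")
  val <- if (log_scale) log2(tab$normalized) else tab$normalized
  out <- lapply(split(seq_len(nrow(tab)), tab$target_gene), function(idx) {
    a <- val[idx][tab$group[idx] == groups[1L]]
    b <- val[idx][tab$group[idx] == groups[2L]]
    cmp <- group_compare(a, b)
    cbind(data.frame(target_gene = tab$target_gene[idx][1L],
                     group_a = groups[1L], group_b = groups[2L],
                     stringsAsFactors = FALSE), cmp)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
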