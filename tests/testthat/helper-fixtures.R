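# Shared fixture builders (all generated in code at test time).

toy_matrix <- function(n_probes = 3L, n_samples = 4L, values = NULL) {
  if (is.null(values)) values <- seq_len(n_probes * n_samples)
  matrix(values, n_probes, n_samples,
         dimnames = list(sprintf("p%d", seq_len(n_probes)),
                         sprintf("s%d", seq_len(n_samples))))
}

# tab-separated matrix file on disk
write_toy_matrix_file <- function(mat, path = tempfile(fileext = ".tsv")) {
  immunobalance::write_expression_matrix(mat, path)
  path
}

# minimal paired design: one placebo + one treated sample per subject
toy_paired_design <- function(n_subjects, day = 3L) {
  subj <- sprintf("S%02d", seq_len(n_subjects))
  data.frame(
    sample_id = c(paste0(subj, "_p"), paste0(subj, "_t")),
    subject_id = rep(subj, 2L),
    treatment = rep(c("placebo", "DPCP"), each = n_subjects),
    day = day, stringsAsFactors = FALSE)
}

# differential table built in code (one contrast "c1")
toy_diff_table <- function(probe_id, gene_symbol, fch, fdr, p = fdr) {
  structure(data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                       description = NA_character_,
                       fch_c1 = fch, p_c1 = p, fdr_c1 = fdr,
                       stringsAsFactors = FALSE),
            contrasts = "c1", class = c("differential_table", "data.frame"))
}

# exact two-sided p of the conditional test on a 2x2 table, by exhaustive
# hypergeometric enumeration (minimum-likelihood rule)
hypergeom_p_oracle <- function(a, b, c_, d) {
  K <- a + b; n <- a + c_; N <- a + b + c_ + d
  xs <- max(0L, n - (N - K)):min(K, n)
  dens <- stats::dhyper(xs, K, N - K, n)
  sum(dens[dens <= stats::dhyper(a, K, N - K, n) * (1 + 1e-7)])
}

# brute-force step-up BH
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  fdr_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    fdr_sorted[i] <- min(1, min(m / js * p[ord][js]))
  }
  fdr_sorted[order(ord)]
}
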