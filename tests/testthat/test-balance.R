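test_that("transcriptome thresholds reproduce the curated-table counts", {
  tab <- load_table1_fixture()
  tr_pso <- define_transcriptome(tab, "pso", 2, 0.05, "up", "gene")
  expect_length(tr_pso, 7L)
  expect_setequal(tr_pso$members,
                  c("CD274", "PTPRC", "LILRB2", "PRDM1", "IL4R", "PTPN22",
                    "ITCH"))
  tr_dpcp <- define_transcriptome(tab, "dpcp_d3", 2, 0.05, "up", "probe")
  expect_length(tr_dpcp, 52L)

  # vacuous thresholds retain everything at probe level
  all_tr <- define_transcriptome(tab, "dpcp_d3", 1, 1, "both", "probe")
  expect_setequal(all_tr$members, tab$probe_id)
  expect_error(define_transcriptome(tab, "nope"), "unknown contrast")
})

test_that("transcriptomes are monotone in their thresholds", {
  tab <- load_table1_fixture()
  for (ct in c("dpcp_d3", "pso")) {
    strict <- define_transcriptome(tab, ct, 3, 0.01, "up", "probe")
    relaxed_f <- define_transcriptome(tab, ct, 2, 0.01, "up", "probe")
    relaxed_q <- define_transcriptome(tab, ct, 3, 0.10, "up", "probe")
    expect_true(all(strict$members %in% relaxed_f$members))
    expect_true(all(strict$members %in% relaxed_q$members))
    # gene-level size never exceeds probe-level size
    genes <- define_transcriptome(tab, ct, 2, 0.05, "up", "gene")
    probes <- define_transcriptome(tab, ct, 2, 0.05, "up", "probe")
    expect_lte(length(genes), length(probes))
  }
})

test_that("representative-probe collapse picks the max |log2 FCH| with probe-id ties", {
  t1 <- toy_diff_table(c("p2", "p1", "p3"), c("GA", "GA", "GB"),
                       fch = c(4, 0.2, 3), fdr = c(0.01, 0.001, 0.2))
  g <- collapse_to_genes(t1, "c1")
  # |log2 0.2| = 2.32 > |log2 4| = 2 -> down-probe wins for GA
  expect_equal(g$probe_id[g$gene_symbol == "GA"], "p1")
  # tie on |log2 FCH| broken lexicographically
  t2 <- toy_diff_table(c("pB", "pA"), c("G", "G"), fch = c(2, 2),
                       fdr = c(0.5, 0.5))
  expect_equal(collapse_to_genes(t2, "c1")$probe_id, "pA")
})

test_that("overlap equals brute-force set intersection", {
  tab <- load_table1_fixture()
  tr <- define_transcriptome(tab, "dpcp_d3", 2, 0.05, "up", "gene")
  expect_equal(overlap(tr, regulator_list("e", character(0)))$n, 0L)
  self <- regulator_list("s", tr$members)
  expect_equal(overlap(tr, self)$n, length(tr))

  set.seed(50)
  for (i in 1:10) {
    sub <- sample(unique(tab$gene_symbol), 8)
    l <- regulator_list("r", sub)
    expect_equal(overlap(tr, l)$n, length(intersect(tr$members, sub)))
  }

  # probe-level transcriptome needs a map
  trp <- define_transcriptome(tab, "dpcp_d3", 2, 0.05, "up", "probe")
  expect_error(overlap(trp, self), "probe_map")
  pm <- setNames(tab$gene_symbol, tab$probe_id)
  expect_equal(overlap(trp, self, probe_map = pm)$n,
               length(intersect(unique(pm[trp$members]), self$symbols)))
})

test_that("enrichment fills the 2x2 table and handles zero cells", {
  mk <- function(a, b, c_, d) {
    universe <- sprintf("g%03d", seq_len(a + b + c_ + d))
    t_members <- universe[seq_len(a + c_)]
    l_members <- c(universe[seq_len(a)],
                   universe[a + c_ + seq_len(b)])
    tr <- structure(list(contrast = "x", level = "gene", direction = "up",
                         members = t_members,
                         fch = setNames(rep(2, length(t_members)), t_members),
                         fch_min = 2, fdr_max = 0.05),
                    class = "transcriptome")
    enrichment(tr, regulator_list("l", l_members), universe)
  }
  sym <- mk(10, 10, 10, 10)
  expect_equal(sym$odds_ratio, 1.0)
  hand <- mk(5, 1, 2, 12)
  expect_equal(hand$odds_ratio, 30.0)
  expect_equal(hand$p, hypergeom_p_oracle(5, 1, 2, 12), tolerance = 1e-10)
  expect_true(hand$ci95[1] <= 30 && 30 <= hand$ci95[2])

  zero <- mk(0, 5, 4, 11)
  expect_true(zero$continuity_corrected)
  expect_true(is.finite(zero$odds_ratio) && zero$odds_ratio > 0)

  # exact p equals brute-force hypergeometric enumeration, universes <= 50
  set.seed(51)
  for (i in 1:15) {
    n <- sample(8:50, 1)
    a <- sample(0:3, 1); b <- sample(0:6, 1); c_ <- sample(0:6, 1)
    d <- n - a - b - c_
    if (d < 0) next
    expect_equal(mk(a, b, c_, d)$p, hypergeom_p_oracle(a, b, c_, d),
                 tolerance = 1e-10)
  }
})

test_that("balance score identities and flags hold", {
  tab <- load_table1_fixture()
  nl <- regulator_list("neg", unique(tab$gene_symbol)[1:20])
  same <- balance_score(tab, "dpcp_d3", nl, nl)
  expect_equal(same$expr_ratio, 1)
  expect_equal(same$count_ratio, 1)

  # null table: ratio flagged unstable
  nullt <- toy_diff_table(sprintf("p%d", 1:6),
                          c("A", "B", "C", "D", "E", "F"),
                          fch = rep(1, 6), fdr = rep(1, 6))
  ns <- balance_score(nullt, "c1", regulator_list("n", c("A", "B")),
                      regulator_list("p", c("C", "D")))
  expect_false(ns$ratio_defined)
  expect_true(is.na(ns$expr_ratio))
})

test_that("generative balance: a 3:1 log2FC contrast yields expr_ratio near 3", {
  p <- sim_params(n_probes = 1500, days = 3L, d0 = 20, s0_sq = 0.01,
                  effect_spec = list(negative = c("3" = 3),
                                     positive = c("3" = 1)),
                  seed = 52)
  sim <- simulate_expression(p)
  fit <- paired_modt(sim$matrix, sim$design, days = 3,
                     probe_symbols = setNames(sim$truth$gene_symbol,
                                              sim$truth$probe_id))
  neg <- regulator_list("negative",
                        sim$truth$gene_symbol[sim$truth$set == "negative"])
  pos <- regulator_list("positive",
                        sim$truth$gene_symbol[sim$truth$set == "positive"])
  bs <- balance_score(fit$table, "d3", neg, pos, scope = "list")
  expect_equal(bs$expr_ratio, 3, tolerance = 0.1)
})

test_that("comparison orders contrasts by expression ratio and reports ties", {
  mk_score <- function(ct, r) structure(
    list(contrast = ct, scope = "list", n_neg = 1L, n_pos = 1L,
         count_ratio = 1, mean_log2fch_neg = r, mean_log2fch_pos = 1,
         expr_ratio = r, ratio_defined = TRUE, fch_min = 2, fdr_max = 0.05,
         direction = "up"), class = "balance_score")
  cmp <- compare_balance(list(a = mk_score("a", 2.0), b = mk_score("b", 0.5)))
  expect_equal(cmp$ordering[1], "a")
  expect_false(cmp$ties)
  tie <- compare_balance(list(a = mk_score("a", 1), b = mk_score("b", 1)))
  expect_true(tie$ties)
  expect_error(compare_balance(list(mk_score("a", 1))), ">= 2")
})
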