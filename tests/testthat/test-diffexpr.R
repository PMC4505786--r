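test_that("paired effects match hand-computed closed forms", {
  design <- toy_paired_design(2)
  # probe A: differences {1, 1}; probe B: differences {0, 2}
  m <- rbind(A = c(0, 0, 1, 1), B = c(0, 0, 0, 2))
  colnames(m) <- design$sample_id
  eff <- paired_effects(m, design, day = 3)
  expect_equal(unname(eff$effect), c(1, 1))
  expect_equal(unname(eff$s_g_sq), c(0, 2))
  expect_equal(eff$d_g, 1L)

  # treated identical to reference: all effects 0, FCH 1
  m0 <- rbind(A = c(2, 3, 2, 3), B = c(5, 6, 5, 6))
  colnames(m0) <- design$sample_id
  eff0 <- paired_effects(m0, design, day = 3)
  expect_equal(unname(eff0$effect), c(0, 0))
  mod0 <- estimate_moderation(c(eff0$s_g_sq, rep(0.5, 10)), 1)
  res0 <- contrast_test(eff0, estimate_moderation(rep(0.5, 2), 1, d0 = 0))
  expect_equal(res0$fch, c(1, 1))
  expect_equal(res0$p, c(1, 1))
})

test_that("unpaired subjects are dropped with a warning; <2 pairs errors", {
  design <- toy_paired_design(3)
  design <- design[design$sample_id != "S03_t", ]  # S03 loses its pair
  m <- toy_matrix(4, 5, rnorm(20))
  colnames(m) <- design$sample_id
  expect_warning(eff <- paired_effects(m, design, day = 3), "S03")
  expect_equal(eff$n_pairs, 2L)

  d1 <- toy_paired_design(2)[-1L, ]
  m1 <- toy_matrix(2, 3); colnames(m1) <- d1$sample_id
  expect_warning(expect_error(paired_effects(m1, d1, day = 3),
                              "fewer than 2"))
})

test_that("moderation handles degenerate limits", {
  # identical variances: complete shrinkage to the common value
  expect_message(mod <- estimate_moderation(rep(0.3, 50), 10), "Inf")
  expect_true(is.infinite(mod$d0))
  expect_equal(mod$s0_sq, 0.3, tolerance = 1e-6)
  expect_equal(mod$s_tilde_sq, rep(0.3, 50), tolerance = 1e-6)

  # d0 = 0 override: no shrinkage at all
  s <- runif(20, 0.1, 2)
  mod0 <- estimate_moderation(s, 5, d0 = 0)
  expect_identical(mod0$s_tilde_sq, s)

  # shrunk variances always lie between the prior and the observed value
  set.seed(40)
  s2 <- 0.05 * 4 / rchisq(500, 4) * rchisq(500, 10) / 10
  modf <- estimate_moderation(s2, 10)
  expect_true(all(modf$s_tilde_sq >= pmin(modf$s0_sq, s2) - 1e-12))
  expect_true(all(modf$s_tilde_sq <= pmax(modf$s0_sq, s2) + 1e-12))
})

test_that("prior hyperparameters are recovered from simulated variances", {
  set.seed(41)
  n <- 20000; d0 <- 4; s0 <- 0.05; d_g <- 10
  sigma2 <- d0 * s0 / rchisq(n, d0)
  s_g_sq <- sigma2 * rchisq(n, d_g) / d_g
  mod <- estimate_moderation(s_g_sq, d_g)
  expect_equal(mod$d0, d0, tolerance = 0.10)
  expect_equal(mod$s0_sq, s0, tolerance = 0.10)
})

test_that("moderation matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(42)
  s_g_sq <- 0.05 * 4 / rchisq(2000, 4) * rchisq(2000, 10) / 10
  mod <- estimate_moderation(s_g_sq, 10)
  ref <- limma::squeezeVar(s_g_sq, df = 10)
  expect_equal(mod$d0, ref$df.prior, tolerance = 1e-4)
  expect_equal(mod$s0_sq, ref$var.prior, tolerance = 1e-4)
  expect_equal(mod$s_tilde_sq, ref$var.post, tolerance = 1e-6)
})

test_that("moderated t and p match an independent Student-tail oracle", {
  eff <- list(effect = c(x = 1.0), n_pairs = 11L)
  mod <- structure(list(d0 = 4, s0_sq = 0.25,
                        s_tilde_sq = 0.25, d_g = 10),
                   class = "moderation_params")
  res <- contrast_test(eff, mod)
  t_expect <- 1.0 / sqrt(0.25 / 11)
  expect_equal(res$t, t_expect, tolerance = 1e-12)
  # numeric integration of the Student density as the tail oracle (14 df)
  oracle <- 2 * integrate(function(x) dt(x, df = 14), t_expect, Inf,
                          rel.tol = 1e-12)$value
  expect_equal(res$p, oracle, tolerance = 1e-9)

  # zero-variance contract
  eff2 <- list(effect = c(a = 2, b = 0), n_pairs = 5L)
  mod2 <- structure(list(d0 = 0, s0_sq = NA, s_tilde_sq = c(0, 0), d_g = 4),
                    class = "moderation_params")
  res2 <- contrast_test(eff2, mod2)
  expect_true(res2$zero_variance[1])
  expect_equal(res2$p, c(0, 1))
})

test_that("d0 = 0 reproduces the classical paired t-test to 12 digits", {
  set.seed(43)
  design <- toy_paired_design(11)
  m <- toy_matrix(60, 22, rnorm(60 * 22, 8, 1))
  colnames(m) <- design$sample_id
  fit <- paired_modt(m, design, days = 3, d0 = 0)
  res <- fit$fits$d3$result
  for (g in c(1, 17, 60)) {
    tr <- m[g, design$sample_id[design$treatment == "DPCP"]]
    pl <- m[g, design$sample_id[design$treatment == "placebo"]]
    ht <- t.test(tr, pl, paired = TRUE)
    expect_equal(res$t[g], unname(ht$statistic), tolerance = 1e-12)
    expect_equal(res$p[g], ht$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(adjust_bh(numeric(0)), numeric(0))

  # exhaustive small vectors against the step-up oracle
  set.seed(44)
  for (m in c(1:6, 20)) {
    p <- runif(m)
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  # with ties
  p <- c(0.1, 0.1, 0.05, 0.9, 0.05)
  expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
})

test_that("fdr dominates p and test statistics are effect-monotone", {
  set.seed(45)
  p <- sim_params(n_probes = 800, days = 3L, seed = 45)
  sim <- simulate_expression(p)
  fit <- paired_modt(sim$matrix, sim$design, days = 3)
  res <- fit$fits$d3$result
  expect_true(all(res$fdr >= res$p - 1e-15))
  expect_true(all(sign(res$effect) == sign(res$t) | res$effect == 0))
  # order preservation of fdr w.r.t. p
  ord <- order(res$p)
  expect_true(all(diff(res$fdr[ord]) >= -1e-15))
  # monotonicity: scaling |effect| up at fixed variance never lowers |t|
  eff <- fit$fits$d3$effects
  mod <- fit$fits$d3$moderation
  bigger <- eff; bigger$effect <- eff$effect * 2
  expect_true(all(abs(contrast_test(bigger, mod)$t) >=
                    abs(res$t) - 1e-12))
})

test_that("null simulations hold the type-I error near nominal", {
  p <- sim_params(n_probes = 5000, days = 3L,
                  effect_spec = list(negative = c("3" = 0),
                                     positive = c("3" = 0)),
                  seed = 46)
  sim <- simulate_expression(p)
  fit <- paired_modt(sim$matrix, sim$design, days = 3)
  frac <- mean(fit$fits$d3$result$p < 0.05)
  se <- sqrt(0.05 * 0.95 / 5000)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("true log2 fold changes are recovered with small bias", {
  p <- sim_params(n_probes = 2000, days = 3L, n_subjects = 11,
                  d0 = 20, s0_sq = 0.25,     # residual sd 0.5
                  effect_spec = list(negative = c("3" = 1.5),
                                     positive = c("3" = 0.5)),
                  seed = 47)
  sim <- simulate_expression(p)
  fit <- paired_modt(sim$matrix, sim$design, days = 3)
  est <- log2(fit$table$fch_d3)
  truth <- sim$truth$lfc_d3
  for (s in c("negative", "positive", "background")) {
    idx <- sim$truth$set == s
    expect_lt(abs(mean(est[idx] - truth[idx])), 0.05)
  }
})
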