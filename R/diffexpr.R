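#' Per-subject paired log2 differences
#'
#' Reduces the random-intercept model for a balanced complete paired design
#' to per-subject treated-minus-reference differences: for each probe the
#' effect is the mean difference over subjects, with its sample variance and
#' `n - 1` residual degrees of freedom. On this design the reduction
#' coincides with the generalized-least-squares estimate of the treatment
#' effect under a subject random intercept.
#'
#' @param mat Expression matrix (probes x samples, log2).
#' @param design Sample design data.frame (`sample_id`, `subject_id`,
#'   `treatment`, optional `day`).
#' @param day Integer day to contrast, or `NULL` if the design has no day
#'   structure.
#' @param treatment_levels Length-2 character vector, reference level first
#'   (default `c("placebo", "DPCP")`).
#' @return List with `effect` (per-probe mean paired difference), `s_g_sq`
#'   (per-probe sample variance of differences), `d_g` (residual df,
#'   `n_pairs - 1`), `n_pairs`, and `subjects` used. Subjects missing either
#'   arm are excluded with a warning; fewer than 2 complete pairs is an
#'   error.
#' @export
paired_effects <- function(mat, design, day = NULL,
                           treatment_levels = c("placebo", "DPCP")) {
  d <- design
  if (!is.null(day)) {
    if (!"day" %in% colnames(d)) stop("design has no 'day' column")
    d <- d[d$day == day, , drop = FALSE]
    if (nrow(d) == 0L) stop("no samples at day ", day)
  }
  d <- d[d$sample_id %in% colnames(mat), , drop = FALSE]
  ref <- d[d$treatment == treatment_levels[1L], , drop = FALSE]
  trt <- d[d$treatment == treatment_levels[2L], , drop = FALSE]
  subjects <- intersect(unique(trt$subject_id), unique(ref$subject_id))
  dropped <- setdiff(unique(d$subject_id), subjects)
  if (length(dropped) > 0L)
    warning("unpaired subject(s) excluded: ", paste(dropped, collapse = ", "))
  if (length(subjects) < 2L)
    stop("fewer than 2 complete pairs; paired inference impossible")
  diffs <- vapply(subjects, function(s) {
    ti <- trt$sample_id[trt$subject_id == s][1L]
    ri <- ref$sample_id[ref$subject_id == s][1L]
    mat[, ti] - mat[, ri]
  }, numeric(nrow(mat)))
  n <- length(subjects)
  effect <- rowMeans(diffs)
  s_g_sq <- rowSums((diffs - effect)^2) / (n - 1L)
  list(effect = effect, s_g_sq = s_g_sq, d_g = n - 1L, n_pairs = n,
       subjects = subjects)
}

# Newton inversion of the trigamma function (monotone decreasing on x > 0).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (i in 1:75) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, 0)
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Fits a scaled inverse chi-square prior (`d0`, `s0_sq`) to the observed
#' residual variances by moments matching on the log scale: the excess
#' spread of `log(s_g_sq)` beyond its sampling contribution
#' `trigamma(d_g/2)` determines `d0` via `trigamma(d0/2)`, and the mean
#' determines `s0_sq`. Probes are then shrunk:
#' `s_tilde_sq = (d0*s0_sq + d_g*s_g_sq) / (d0 + d_g)`.
#'
#' @param s_g_sq Per-probe sample variances.
#' @param d_g Residual degrees of freedom (scalar or per-probe vector).
#' @param d0 Optional override of the prior degrees of freedom: `0` gives
#'   no shrinkage (ordinary t), `Inf` complete shrinkage.
#' @return List of class `moderation_params`: `d0`, `s0_sq`, `s_tilde_sq`,
#'   `d_g`.
#' @export
estimate_moderation <- function(s_g_sq, d_g, d0 = NULL) {
  n <- length(s_g_sq)
  d_g <- rep_len(d_g, n)
  ok <- is.finite(s_g_sq) & s_g_sq > 0 & d_g > 0
  if (is.null(d0) && sum(ok) < 10L)
    stop("need >= 10 probes with positive variance to estimate the prior")
  if (!is.null(d0)) {
    if (d0 == 0) {
      return(structure(list(d0 = 0, s0_sq = NA_real_, s_tilde_sq = s_g_sq,
                            d_g = d_g), class = "moderation_params"))
    }
    z <- log(s_g_sq[ok])
    e <- z - digamma(d_g[ok] / 2) + log(d_g[ok] / 2)
    # with infinite prior df every probe shares one variance: its moment
    # estimate is the plain mean
    s0_sq <- if (is.infinite(d0)) mean(s_g_sq[ok]) else
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    z <- log(s_g_sq[ok])
    e <- z - digamma(d_g[ok] / 2) + log(d_g[ok] / 2)
    excess <- stats::var(e) - mean(trigamma(d_g[ok] / 2))
    if (!is.finite(excess) || excess <= 0) {
      d0 <- Inf
      s0_sq <- mean(s_g_sq[ok])
      message("no finite prior df solution; complete shrinkage (d0 = Inf)")
    } else {
      d0 <- 2 * trigamma_inverse(excess)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  s_tilde_sq <- if (is.infinite(d0)) rep(s0_sq, n) else
    (d0 * s0_sq + d_g * s_g_sq) / (d0 + d_g)
  structure(list(d0 = d0, s0_sq = s0_sq, s_tilde_sq = s_tilde_sq, d_g = d_g),
            class = "moderation_params")
}

#' Moderated paired t-test for one contrast
#'
#' `t = effect / sqrt(s_tilde_sq / n_pairs)`, with a two-sided p from the
#' Student reference on `d0 + d_g` degrees of freedom (normal reference when
#' `d0` is infinite). With `d0 = 0` this is the classical paired t-test.
#'
#' @param effects Output of [paired_effects()].
#' @param moderation Output of [estimate_moderation()].
#' @return Data.frame with per-probe `effect` (log2), `t`, `p`, `fdr`
#'   (BH-adjusted), `fch` (`2^effect`), and `zero_variance` flag (variance
#'   exactly 0: `t` is infinite, `p` reported 0).
#' @export
contrast_test <- function(effects, moderation) {
  st <- moderation$s_tilde_sq
  n <- effects$n_pairs
  eff <- effects$effect
  t_stat <- eff / sqrt(st / n)
  df <- moderation$d0 + moderation$d_g
  p <- if (is.infinite(moderation$d0)) 2 * stats::pnorm(-abs(t_stat)) else
    2 * stats::pt(-abs(t_stat), df = df)
  zero <- st == 0
  if (any(zero)) {
    t_stat[zero] <- sign(eff[zero]) * Inf
    p[zero] <- 0
    p[zero & eff == 0] <- 1  # 0/0: no evidence either way
    t_stat[zero & eff == 0] <- 0
  }
  out <- data.frame(effect = eff, t = t_stat, p = p, fdr = adjust_bh(p),
                    fch = 2^eff, zero_variance = zero)
  rownames(out) <- names(eff)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated front end to the standard step-up procedure:
#' `fdr_(i) = min_{j >= i} (m/j) p_(j)`, clipped at 1, in original order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted values, `fdr >= p` elementwise.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fit the moderated paired model for one or more day contrasts
#'
#' The package's one-call differential-expression fit: per-subject paired
#' differences, empirical-Bayes variance moderation pooled across the
#' requested contrasts' probes per day, moderated t, and BH adjustment.
#'
#' @param mat Expression matrix (probes x samples, log2).
#' @param design Sample design data.frame.
#' @param days Integer vector of days to contrast (each one paired
#'   treated-vs-reference contrast), or `NULL` for a single day-less
#'   contrast.
#' @param probe_symbols Optional named character vector mapping probe id to
#'   gene symbol (defaults to the probe id itself).
#' @param d0 Optional moderation override passed to
#'   [estimate_moderation()].
#' @param treatment_levels Reference and treated labels.
#' @return An object of class `paired_modt`: a list with `table` (a
#'   `differential_table` with one fch/p/fdr triple per contrast named
#'   `d<day>`), per-contrast `fits` (effects + moderation + test), and the
#'   call.
#' @export
paired_modt <- function(mat, design, days = NULL, probe_symbols = NULL,
                        d0 = NULL, treatment_levels = c("placebo", "DPCP")) {
  contrast_days <- if (is.null(days)) list(NULL) else as.list(days)
  names(contrast_days) <- if (is.null(days)) "contrast" else paste0("d", days)
  fits <- list()
  tab <- data.frame(probe_id = rownames(mat), stringsAsFactors = FALSE)
  syms <- if (is.null(probe_symbols)) rownames(mat) else
    unname(probe_symbols[rownames(mat)])
  tab$gene_symbol <- toupper(syms)
  tab$description <- NA_character_
  for (nm in names(contrast_days)) {
    eff <- paired_effects(mat, design, day = contrast_days[[nm]],
                          treatment_levels = treatment_levels)
    mod <- estimate_moderation(eff$s_g_sq, eff$d_g, d0 = d0)
    res <- contrast_test(eff, mod)
    fits[[nm]] <- list(effects = eff, moderation = mod, result = res)
    tab[[paste0("fch_", nm)]] <- res$fch
    tab[[paste0("p_", nm)]] <- res$p
    tab[[paste0("fdr_", nm)]] <- res$fdr
  }
  table <- structure(tab, contrasts = names(contrast_days),
                     class = c("differential_table", "data.frame"))
  validate_differential_table(table, names(contrast_days))
  structure(list(table = table, fits = fits, call = match.call()),
            class = "paired_modt")
}

#' @export
print.paired_modt <- function(x, ...) {
  cat("Moderated paired differential-expression fit\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  contrast %-8s n_pairs = %d, d0 = %.3g, s0_sq = %.4g\n",
                nm, f$effects$n_pairs, f$moderation$d0, f$moderation$s0_sq))
  }
  cat("  probes:", nrow(x$table), "\n")
  invisible(x)
}

#' @export
summary.paired_modt <- function(object, fdr_max = 0.05, ...) {
  cat("Moderated paired differential-expression fit\n")
  for (nm in names(object$fits)) {
    res <- object$fits[[nm]]$result
    cat(sprintf("  %-8s significant at FDR < %.2g: %d / %d (up %d, down %d)\n",
                nm, fdr_max, sum(res$fdr < fdr_max), nrow(res),
                sum(res$fdr < fdr_max & res$effect > 0),
                sum(res$fdr < fdr_max & res$effect < 0)))
  }
  invisible(object)
}

#' @export
coef.paired_modt <- function(object, ...) {
  sapply(object$fits, function(f) f$effects$effect)
}

#' @export
as.data.frame.paired_modt <- function(x, ...) as.data.frame(x$table)
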