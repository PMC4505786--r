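#' Filter probes with low expression and low variation
#'
#' Keeps probes that exceed `expr_floor` in at least `min_fraction` of
#' samples AND whose sample variance exceeds `var_floor`. Row order is
#' preserved. The thresholds are deliberately exposed: array filters are
#' study-specific.
#'
#' @param mat Expression matrix (probes x samples, log2).
#' @param expr_floor Expression floor in log2 units (default 4.0).
#' @param min_fraction Minimum fraction of samples above the floor
#'   (default 0.25).
#' @param var_floor Variance floor (default 0.01).
#' @return The filtered matrix; warns (does not error) if no probe survives.
#' @export
filter_low <- function(mat, expr_floor = 4.0, min_fraction = 0.25,
                       var_floor = 0.01) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  frac_above <- rowMeans(mat > expr_floor)
  v <- apply(mat, 1L, stats::var)
  keep <- frac_above >= min_fraction & v > var_floor
  if (!any(keep)) warning("no probe passed the expression/variance filter")
  mat[keep, , drop = FALSE]
}

#' Empirical-Bayes batch adjustment (parametric location/scale model)
#'
#' Removes additive and multiplicative per-(batch, probe) effects while
#' protecting specified design covariates: per-probe standardization
#' regressing out the protected covariates, method-of-moments hyperpriors
#' for batch locations (normal) and scales (inverse gamma), iterative
#' empirical-Bayes shrinkage of the batch parameters, then subtraction,
#' rescaling, and restoration of the standardization.
#'
#' @param mat Expression matrix (probes x samples, log2).
#' @param design Sample design data.frame; must contain `batch` plus the
#'   protected covariate columns; rows matched to columns of `mat` by
#'   `sample_id`.
#' @param covariates Character vector of design columns whose effects are
#'   protected from removal (e.g. `c("treatment", "day")`).
#' @return List with `matrix` (adjusted, same dimensions) and `model` (the
#'   estimated batch model: shrunken per-(batch, probe) locations `gamma`
#'   and scales `delta_sq`, plus the per-probe standardization mean and
#'   pooled variance). With a single batch the input is returned unchanged.
#' @export
adjust_batch <- function(mat, design, covariates = c("treatment")) {
  stopifnot(all(colnames(mat) %in% design$sample_id))
  design <- design[match(colnames(mat), design$sample_id), , drop = FALSE]
  if (!"batch" %in% colnames(design)) stop("design has no 'batch' column")
  batch <- factor(design$batch)
  n_batches <- nlevels(batch)
  if (n_batches < 2L)
    return(list(matrix = mat, model = NULL))
  n_b <- table(batch)
  if (any(n_b < 2L))
    stop("batch(es) with a single sample: scale not estimable: ",
         paste(names(n_b)[n_b < 2L], collapse = ", "))

  n <- ncol(mat)
  B <- stats::model.matrix(~ 0 + batch)           # batch indicators
  X <- B
  for (cv in covariates) {
    if (!cv %in% colnames(design)) stop("unknown protected covariate: ", cv)
    v <- design[[cv]]
    if (is.numeric(v) && length(unique(v)) > 8L) {
      X <- cbind(X, v)
    } else {
      f <- factor(v)
      if (nlevels(f) > 1L)
        X <- cbind(X, stats::model.matrix(~ f)[, -1L, drop = FALSE])
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("batch and protected covariates are confounded (rank-deficient design)")
  # per-probe OLS; shared design => one solve
  beta_hat <- t(solve(crossprod(X), crossprod(X, t(mat))))
  grand_mean <- as.numeric(beta_hat[, seq_len(n_batches), drop = FALSE] %*%
                             (as.numeric(n_b) / n))
  resid <- mat - beta_hat %*% t(X)
  var_pooled <- rowSums(resid^2) / n
  if (any(var_pooled <= 0))
    stop("zero pooled variance; filter constant probes first")
  stand_mean <- outer(grand_mean, rep(1, n))
  if (ncol(X) > n_batches) {
    extra <- seq.int(n_batches + 1L, ncol(X))
    stand_mean <- stand_mean +
      beta_hat[, extra, drop = FALSE] %*% t(X[, extra, drop = FALSE])
  }
  Z <- (mat - stand_mean) / sqrt(var_pooled)

  levs <- levels(batch)
  gamma_hat <- t(solve(crossprod(B), crossprod(B, t(Z))))  # batch means of Z
  # MLE (1/n_b) scale estimates keep a duplicated-batch input an exact no-op
  delta_hat <- sapply(levs, function(b) {
    Zb <- Z[, batch == b, drop = FALSE]
    rowSums((Zb - rowMeans(Zb))^2) / ncol(Zb)
  })
  gamma_star <- gamma_hat; delta_star <- delta_hat
  for (j in seq_along(levs)) {
    g <- gamma_hat[, j]; d <- delta_hat[, j]
    gbar <- mean(g); tau2 <- stats::var(g)
    m <- mean(d); s2 <- stats::var(d)
    nb <- as.numeric(n_b[[j]])
    if (!is.finite(s2) || s2 < 1e-12 * m^2) {
      # scales essentially identical across probes: shrink completely
      gamma_star[, j] <- if (tau2 < 1e-12) rep(gbar, length(g)) else
        (nb * tau2 * g + m * gbar) / (nb * tau2 + m)
      delta_star[, j] <- rep(m, length(d))
      next
    }
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    Zb <- Z[, batch == levs[j], drop = FALSE]
    g_new <- g; d_new <- d
    change <- 1; iter <- 0L
    while (change > 1e-6 && iter < 200L) {
      g_old <- g_new; d_old <- d_new
      g_new <- (nb * tau2 * g + d_new * gbar) / (nb * tau2 + d_new)
      ss <- rowSums((Zb - g_new)^2)
      d_new <- (0.5 * ss + b_prior) / (nb / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      iter <- iter + 1L
    }
    gamma_star[, j] <- g_new
    delta_star[, j] <- d_new
  }

  adj <- Z
  for (j in seq_along(levs)) {
    idx <- batch == levs[j]
    adj[, idx] <- (Z[, idx, drop = FALSE] - gamma_star[, j]) /
      sqrt(delta_star[, j])
  }
  out <- adj * sqrt(var_pooled) + stand_mean
  dimnames(out) <- dimnames(mat)
  colnames(gamma_star) <- colnames(delta_star) <- levs
  list(matrix = out,
       model = list(gamma = gamma_star, delta_sq = delta_star,
                    grand_mean = grand_mean, var_pooled = var_pooled,
                    batches = levs))
}
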