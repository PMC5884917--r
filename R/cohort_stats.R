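#' Bivariate Pearson correlation with two-tailed p value
#'
#' @param x,y numeric vectors of equal length (n >= 3, finite, non-constant).
#' @return an object of class `correlation_result`: list with `r`, `n`,
#'   `df` (n - 2), two-tailed `p`, and `method`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have the same length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = length(x),
                 df = unname(ct$parameter), p = ct$p.value,
                 covariates = 0L, method = "pearson"),
            class = "correlation_result")
}

#' Partial correlation controlling for covariates
#'
#' Correlation of the residuals of `x` and `y` after linear removal of the
#' covariates (double residualization), with degrees of freedom
#' `n - 2 - c` for `c` covariates and a two-tailed t-based p value.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector, matrix or data.frame of covariates.
#' @return a `correlation_result` with `df = n - 2 - c`.
#' @export
partial_corr <- function(x, y, covariates) {
  z <- as.matrix(as.data.frame(covariates))
  n <- length(x)
  c_ <- ncol(z)
  if (length(y) != n || nrow(z) != n) stopf("x, y and covariates must align")
  if (n <= 2 + c_) stopf("need n > 2 + number of covariates")
  X <- cbind(1, z)
  if (qr(X)$rank < ncol(X)) stopf("collinear covariates")
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (sum(rx^2) < 1e-12 * max(1, sum(x^2)) ||
      sum(ry^2) < 1e-12 * max(1, sum(y^2))) {
    stopf("zero residual variance: partial correlation undefined")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - c_
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(r = r, n = n, df = df, p = p, covariates = c_,
                 method = "partial pearson"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r(%d) = %.3f, p = %.4g (%s, n = %d%s)\n",
              x$df, x$r, x$p, x$method, x$n,
              if (x$covariates > 0) {
                sprintf(", %d covariate(s)", x$covariates)
              } else ""))
  invisible(x)
}

#' Repeated-measures ANCOVA with a continuous covariate
#'
#' Mixed design with one within-subject factor (`k` levels, e.g. the four
#' forward ARD conditions) and one continuous between-subject covariate
#' (age). The covariate is tested on the subject means with
#' `df = (1, n - 2)`. Within-subject effects (the factor and its
#' interaction with the covariate) are tested on orthonormal
#' within-subject contrasts with uncorrected `df = (k - 1, (k - 1)(n - 2))`
#' and Greenhouse-Geisser correction: the sphericity parameter
#' \deqn{\hat\epsilon = \mathrm{tr}(S)^2 / ((k-1)\,\mathrm{tr}(S^2))}
#' is estimated from the pooled error covariance `S` of the contrasts and
#' multiplies both degrees of freedom.
#'
#' @param measure n x k numeric matrix (or data.frame), one row per subject,
#'   one column per within-subject level; no missing cells.
#' @param age numeric covariate, length n.
#' @return an object of class `rm_ancova_result`: data.frame `effects` with
#'   one row per effect (`covariate`, `within`, `interaction`): `F`, `df1`,
#'   `df2` (GG-corrected for within effects), `epsilon`, `p`; plus
#'   `epsilon`, `n`, `k`, and the uncorrected dfs as attributes.
#' @export
rm_ancova <- function(measure, age) {
  Y <- as.matrix(measure)
  if (any(!is.finite(Y))) stopf("missing or non-finite cells: complete data required")
  n <- nrow(Y)
  k <- ncol(Y)
  if (length(age) != n) stopf("age must have one value per subject")
  if (n < 5) stopf("need at least 5 subjects")
  if (k < 2) stopf("need at least 2 within-subject levels")
  xc <- age - mean(age)
  if (sum(xc^2) == 0) stopf("age covariate is constant")

  ## between-subjects covariate effect, on subject means
  m <- rowMeans(Y)
  fit_b <- stats::lm.fit(cbind(1, xc), m)
  sse_b <- sum(fit_b$residuals^2)
  ssx <- sum(xc^2)
  ss_cov <- fit_b$coefficients[2]^2 * ssx
  df2_b <- n - 2
  F_cov <- (ss_cov / 1) / (sse_b / df2_b)
  p_cov <- stats::pf(F_cov, 1, df2_b, lower.tail = FALSE)

  ## within-subject effects on orthonormal contrasts
  M <- stats::contr.poly(k)                 # k x (k-1), orthonormal columns
  Z <- Y %*% M
  X <- cbind(1, xc)
  B <- solve(crossprod(X), crossprod(X, Z)) # 2 x (k-1)
  E <- crossprod(Z) - t(B) %*% crossprod(X) %*% B
  df_e <- n - 2
  S <- E / df_e
  eps <- sum(diag(S))^2 / ((k - 1) * sum(S * S))
  eps <- min(max(eps, 1 / (k - 1)), 1)

  H_within <- n * tcrossprod(B[1, ])        # (X'X)^-1 [1,1] = 1/n (centered x)
  H_inter <- ssx * tcrossprod(B[2, ])
  df1_w <- k - 1
  df2_w <- (k - 1) * (n - 2)
  F_w <- (sum(diag(H_within)) / df1_w) / (sum(diag(E)) / df2_w)
  F_i <- (sum(diag(H_inter)) / df1_w) / (sum(diag(E)) / df2_w)
  p_w <- stats::pf(F_w, eps * df1_w, eps * df2_w, lower.tail = FALSE)
  p_i <- stats::pf(F_i, eps * df1_w, eps * df2_w, lower.tail = FALSE)

  eff <- data.frame(
    effect = c("covariate", "within", "interaction"),
    F = c(F_cov, F_w, F_i),
    df1 = c(1, eps * df1_w, eps * df1_w),
    df2 = c(df2_b, eps * df2_w, eps * df2_w),
    epsilon = c(NA, eps, eps),
    p = c(p_cov, p_w, p_i),
    stringsAsFactors = FALSE
  )
  structure(list(effects = eff, epsilon = eps, n = n, k = k,
                 df_uncorrected = c(within = df1_w, error = df2_w)),
            class = "rm_ancova_result")
}

#' @export
print.rm_ancova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANCOVA (n = %d, k = %d, GG epsilon = %.3f)\n",
              x$n, x$k, x$epsilon))
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-12s F(%.3f, %.3f) = %.3f, p = %.4g\n",
                e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i]))
  }
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q` on a family of p values supplied
#' explicitly as one vector.
#'
#' @param pvals p values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` (BH-adjusted p values, same order as input)
#'   and `rejected` (logical).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) {
    return(list(adjusted = numeric(0), rejected = logical(0)))
  }
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stopf("p values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' Permutation p value for a Pearson correlation
#'
#' Two-sided permutation test: `y` is permuted `n_perm` times and
#' \deqn{p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\}) / (n_{perm} + 1).}
#'
#' @param x,y numeric vectors (n >= 5).
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @return a `correlation_result` with an extra `p_perm` element (`p` holds
#'   the parametric value for reference).
#' @export
permutation_pearson <- function(x, y, n_perm = 5000, seed) {
  if (length(x) < 5) stopf("need at least 5 observations")
  base <- pearson_corr(x, y)
  r_obs <- base$r
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stats::cor(x, y[sample.int(length(y))])
    }, numeric(1))
  })
  p_perm <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  base$p_perm <- p_perm
  base$n_perm <- n_perm
  base$method <- "pearson + permutation"
  base
}
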