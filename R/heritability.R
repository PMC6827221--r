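## cis-GRM construction, univariate and bivariate REML variance components,
## genetic correlation, and the logit-scale beta regression of heritability
## on age.

#' Genetic relatedness matrix from cis genotypes
#'
#' Each polymorphic SNP is standardized to mean 0, variance 1; the GRM is
#' `Z'Z / m` over the m SNPs retained.
#'
#' @param genotypes SNPs x individuals dosage matrix.
#' @return list of class `longage_grm`: `K` (individuals x individuals),
#'   `n_snps`, `n_dropped` (monomorphic SNPs removed).
#' @export
compute_grm <- function(genotypes) {
  v <- apply(genotypes, 1, stats::var)
  keep <- v > 0
  if (!any(keep)) stop("all SNPs are monomorphic")
  Z <- t(scale(t(genotypes[keep, , drop = FALSE])))
  K <- crossprod(Z) / sum(keep)
  structure(list(K = K, n_snps = sum(keep), n_dropped = sum(!keep)),
            class = "longage_grm")
}

#' @export
print.longage_grm <- function(x, ...) {
  cat("GRM over", ncol(x$K), "individuals from", x$n_snps, "SNPs (",
      x$n_dropped, "monomorphic dropped ); mean diagonal",
      round(mean(diag(x$K)), 3), "\n")
  invisible(x)
}

## REML profile log-likelihood over h2 for rotated data.
## After rotating by the GRM eigenvectors, Var(y*_i) = s2 (h2 lam_i + 1 - h2).
uni_profile <- function(h2, yr, Xr, lam) {
  v <- h2 * lam + (1 - h2)
  if (any(v <= 0)) return(-1e10)   # outside the PSD region (h2 < 0 allowed)
  w <- 1 / v
  XtWX <- t(Xr * w) %*% Xr
  beta <- solve(XtWX, t(Xr * w) %*% yr)
  r <- yr - Xr %*% beta
  rss <- sum(w * r^2)
  N <- length(yr); p <- ncol(Xr)
  s2 <- rss / (N - p)
  -0.5 * ((N - p) * (log(s2) + 1) + sum(log(v)) +
            determinant(XtWX, logarithm = TRUE)$modulus)
}

#' Univariate cis-heritability by eigendecomposition REML
#'
#' Rotates the data by the GRM eigenvectors and profiles the REML
#' log-likelihood over `h2 = sg2 / (sg2 + se2)` with a 1-D bounded
#' optimization; the standard error comes from the observed information
#' (numerical second derivative of the profile).
#'
#' @param y phenotype per individual.
#' @param grm a `longage_grm` or an individuals x individuals matrix.
#' @param covariates optional individuals x k matrix.
#' @param bounds internal clamping of h2 (default `c(1e-6, 1 - 1e-6)`).
#' @param tol optimization tolerance.
#' @return list of class `longage_h2`: `h2`, `se`, `loglik`, `boundary`
#'   (h2 at a bound), `convergence`.
#' @export
reml_h2_univariate <- function(y, grm, covariates = NULL,
                               bounds = c(1e-6, 1 - 1e-6), tol = 1e-10) {
  K <- if (inherits(grm, "longage_grm")) grm$K else grm
  eg <- eigen(K, symmetric = TRUE)
  lam <- eg$values
  if (stats::sd(lam) < 1e-10)
    stop("GRM is proportional to the identity: h2 is unidentifiable")
  U <- eg$vectors
  X <- cbind(rep(1, length(y)), covariates)
  yr <- as.numeric(crossprod(U, y))
  Xr <- crossprod(U, X)
  opt <- stats::optimize(uni_profile, interval = bounds, yr = yr, Xr = Xr,
                         lam = lam, maximum = TRUE, tol = tol)
  h2 <- opt$maximum
  ## observed information on h2 by central second difference of the profile
  h <- 1e-4
  lo <- max(h2 - h, bounds[1]); hi <- min(h2 + h, bounds[2])
  f0 <- opt$objective
  f1 <- uni_profile(lo, yr, Xr, lam)
  f2 <- uni_profile(hi, yr, Xr, lam)
  d2 <- (f1 - 2 * f0 + f2) / ((hi - lo) / 2)^2
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  boundary <- h2 <= bounds[1] + 1e-3 || h2 >= bounds[2] - 1e-3
  structure(list(h2 = h2, se = se, loglik = f0, boundary = boundary,
                 convergence = TRUE), class = "longage_h2")
}

#' @export
print.longage_h2 <- function(x, ...) {
  cat(sprintf("cis-h2 = %.4f (se %.3g)%s, loglik %.3f\n", x$h2, x$se,
              if (x$boundary) " [boundary]" else "", x$loglik))
  invisible(x)
}

## Bivariate REML negative log-likelihood on rotated data.
## theta = (log sg2_70, log sg2_80, log se2_70, log se2_80,
##          atanh rho_g, atanh rho_e)
biv_negll <- function(theta, y1r, y2r, X1r, X2r, lam) {
  sg <- exp(theta[1:2]); se <- exp(theta[3:4])
  rg <- tanh(theta[5]); re <- tanh(theta[6])
  n <- length(lam)
  a11 <- sg[1] * lam + se[1]
  a22 <- sg[2] * lam + se[2]
  a12 <- rg * sqrt(sg[1] * sg[2]) * lam + re * sqrt(se[1] * se[2])
  det2 <- a11 * a22 - a12^2
  if (!all(is.finite(det2)) || any(det2 <= 0)) return(1e10)
  i11 <- a22 / det2; i22 <- a11 / det2; i12 <- -a12 / det2
  p <- ncol(X1r)
  ## stacked fixed effects: separate coefficients per age
  ## X'V^-1 X blocks
  A <- t(X1r * i11) %*% X1r
  B <- t(X1r * i12) %*% X2r
  C <- t(X2r * i22) %*% X2r
  XtVX <- rbind(cbind(A, B), cbind(t(B), C))
  XtVy <- c(t(X1r) %*% (i11 * y1r + i12 * y2r),
            t(X2r) %*% (i12 * y1r + i22 * y2r))
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
  r1 <- y1r - X1r %*% beta[seq_len(p)]
  r2 <- y2r - X2r %*% beta[p + seq_len(p)]
  quad <- sum(r1 * (i11 * r1 + i12 * r2) + r2 * (i12 * r1 + i22 * r2))
  0.5 * (sum(log(det2)) + 2 * sum(log(diag(ch))) + quad)
}

#' Bivariate cis-GREML across ages
#'
#' Six-parameter REML (per-age genetic and residual variances, genetic and
#' residual cross-age correlations) on the shared GRM eigenbasis, giving
#' O(n) likelihood evaluations; optimized by quasi-Newton on transformed
#' parameters (log variances, atanh correlations) with restarts.
#'
#' @param y70,y80 phenotype per individual at each age (same individuals).
#' @param grm a `longage_grm` or matrix.
#' @param covariates optional individuals x k matrix (entered per age).
#' @param n_restarts random restarts after the default start (default 2).
#' @return list of class `longage_h2_biv`: `h2_70`, `h2_80`, `se_70`,
#'   `se_80`, `rho_g`, `rho_e`, `loglik`, `convergence`, `params`.
#' @export
reml_bivariate <- function(y70, y80, grm, covariates = NULL,
                           n_restarts = 2) {
  K <- if (inherits(grm, "longage_grm")) grm$K else grm
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors; lam <- eg$values
  X <- cbind(rep(1, length(y70)), covariates)
  y1r <- as.numeric(crossprod(U, y70)); y2r <- as.numeric(crossprod(U, y80))
  X1r <- crossprod(U, X); X2r <- X1r
  v1 <- max(stats::var(y70), 1e-6); v2 <- max(stats::var(y80), 1e-6)
  starts <- list(c(log(0.3 * v1), log(0.3 * v2), log(0.7 * v1),
                   log(0.7 * v2), atanh(0.5), atanh(0.3)))
  for (i in seq_len(n_restarts))
    starts[[i + 1]] <- starts[[1]] + stats::rnorm(6, sd = 0.5)
  best <- NULL
  for (s in starts) {
    op <- tryCatch(stats::optim(s, biv_negll, method = "BFGS",
                                y1r = y1r, y2r = y2r, X1r = X1r, X2r = X2r,
                                lam = lam,
                                control = list(maxit = 500, reltol = 1e-12)),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best))
    return(structure(list(convergence = FALSE), class = "longage_h2_biv"))
  th <- best$par
  sg <- exp(th[1:2]); se2 <- exp(th[3:4])
  h2 <- sg / (sg + se2)
  ## delta-method SEs for h2 from the numerical Hessian in theta
  H <- tryCatch(stats::optimHess(th, biv_negll, y1r = y1r, y2r = y2r,
                                 X1r = X1r, X2r = X2r, lam = lam),
                error = function(e) NULL)
  ses <- c(NA_real_, NA_real_)
  if (!is.null(H)) {
    Vth <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vth)) {
      for (a in 1:2) {
        ## h2_a = sg_a/(sg_a+se_a); d h2/d log sg = h2(1-h2); d/d log se =
        ## -h2(1-h2)
        g <- numeric(6)
        g[a] <- h2[a] * (1 - h2[a]); g[a + 2] <- -h2[a] * (1 - h2[a])
        v <- as.numeric(t(g) %*% Vth %*% g)
        if (is.finite(v) && v >= 0) ses[a] <- sqrt(v)
      }
    }
  }
  structure(list(h2_70 = h2[1], h2_80 = h2[2], se_70 = ses[1],
                 se_80 = ses[2], rho_g = tanh(th[5]), rho_e = tanh(th[6]),
                 loglik = -best$value,
                 convergence = best$convergence == 0, params = th),
            class = "longage_h2_biv")
}

#' @export
print.longage_h2_biv <- function(x, ...) {
  if (!isTRUE(x$convergence)) { cat("bivariate REML: not converged\n")
    return(invisible(x)) }
  cat(sprintf(
    "bivariate REML: h2_70 = %.3f, h2_80 = %.3f, rho_g = %.3f, rho_e = %.3f\n",
    x$h2_70, x$h2_80, x$rho_g, x$rho_e))
  invisible(x)
}

#' Beta regression of heritability on age (logit link)
#'
#' Maximum-likelihood beta regression with logit mean link and common
#' precision: `logit(E[h2]) = alpha + beta * age`.  Fitted group means are
#' `1/(1+exp(-alpha))` and `1/(1+exp(-(alpha+beta)))`.  Observations may be
#' weighted (e.g. by `1/SE^2` of the heritability estimates, normalized to
#' mean 1).  Boundary h2 values are shrunk inward by `eps`.
#'
#' @param h2 vector of heritability estimates in (0, 1).
#' @param age01 0/1 age coding per estimate.
#' @param weights optional non-negative weights.
#' @param eps boundary shrinkage (default 1e-4).
#' @return list of class `longage_h2trend`: `alpha`, `beta`, `precision`,
#'   `fitted_h2_70`, `fitted_h2_80`, `se_beta`, `p_wald`, `p_lrt`,
#'   `loglik`, `n_shrunk`, `degenerate`.
#' @export
beta_regression_h2 <- function(h2, age01, weights = NULL, eps = 1e-4) {
  stopifnot(length(h2) == length(age01))
  n_shrunk <- sum(h2 <= 0 | h2 >= 1 | h2 < eps | h2 > 1 - eps)
  h2 <- pmin(pmax(h2, eps), 1 - eps)
  if (stats::sd(h2) == 0)
    return(structure(list(degenerate = TRUE, n_shrunk = n_shrunk),
                     class = "longage_h2trend"))
  w <- if (is.null(weights)) rep(1, length(h2))
       else weights / mean(weights)
  nll <- function(par, with_age = TRUE) {
    mu <- logistic(par[1] + if (with_age) par[2] * age01 else 0)
    phi <- exp(par[if (with_age) 3 else 2])
    -sum(w * stats::dbeta(h2, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  start <- c(logit(mean(h2)), 0, log(10))
  op <- stats::optim(start, nll, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12))
  op0 <- stats::optim(start[-2], nll, with_age = FALSE, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  H <- stats::optimHess(op$par, nll)
  Vb <- tryCatch(solve(H), error = function(e) matrix(NA, 3, 3))
  se_beta <- sqrt(Vb[2, 2])
  z <- op$par[2] / se_beta
  lrt <- 2 * (op0$value - op$value)
  structure(list(alpha = op$par[1], beta = op$par[2],
                 precision = exp(op$par[3]),
                 fitted_h2_70 = logistic(op$par[1]),
                 fitted_h2_80 = logistic(op$par[1] + op$par[2]),
                 se_beta = se_beta, p_wald = 2 * stats::pnorm(-abs(z)),
                 p_lrt = stats::pchisq(max(lrt, 0), 1, lower.tail = FALSE),
                 loglik = -op$value, n_shrunk = n_shrunk,
                 degenerate = FALSE),
            class = "longage_h2trend")
}

#' @export
print.longage_h2trend <- function(x, ...) {
  if (isTRUE(x$degenerate)) { cat("h2 trend: degenerate fit\n")
    return(invisible(x)) }
  cat(sprintf(
    "h2 trend: fitted h2_70 = %.4f, h2_80 = %.4f (beta = %.4f, p = %.3g)\n",
    x$fitted_h2_70, x$fitted_h2_80, x$beta, x$p_lrt))
  invisible(x)
}

## Exact one-sample signed-rank distribution by subset-sum convolution
## over doubled midranks (handles ties); used for n <= 25.
signed_rank_exact_p <- function(d, alternative) {
  r2 <- as.integer(round(2 * rank(abs(d))))   # doubled midranks: integers
  v2 <- sum(r2[d > 0])
  counts <- numeric(sum(r2) + 1)               # index = doubled V
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(d)
  p_le <- sum(probs[seq_len(v2 + 1)])
  p_ge <- sum(probs[(v2 + 1):length(probs)])
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

#' Paired Wilcoxon signed-rank test
#'
#' Exact null distribution (permutation of difference signs, ties handled
#' by midranks) for 25 or fewer non-zero differences, normal approximation
#' with continuity and tie correction otherwise; zero differences are
#' dropped (classical convention).
#'
#' @param x,y paired vectors, or `y = NULL` for a one-sample test of `x`
#'   against zero.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return list: `statistic` (V), `p_value`, `n_used`.
#' @export
paired_wilcoxon <- function(x, y = NULL,
                            alternative = c("two.sided", "greater",
                                            "less")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  if (length(d) == 0) return(list(statistic = NA_real_, p_value = 1,
                                  n_used = 0L))
  v <- sum(rank(abs(d))[d > 0])
  p <- if (length(d) <= 25) signed_rank_exact_p(d, alternative)
  else suppressWarnings(stats::wilcox.test(
    d, alternative = alternative, exact = FALSE, correct = TRUE))$p.value
  list(statistic = v, p_value = p, n_used = length(d))
}
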