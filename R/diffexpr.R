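## Paired linear mixed model for differential expression by age, Storey
## q-values, variance explained by age, and age-trajectory outliers.

## Rotate a paired design into independent "sum" and "difference" rows.
## With one sample per individual per age and a compound-symmetric 2x2
## per-individual covariance sigma^2 [[1, rho], [rho, 1]], the orthonormal
## rotation ((y70+y80)/sqrt2, (y80-y70)/sqrt2) diagonalizes the covariance
## into two variance groups sigma^2(1+rho) and sigma^2(1-rho).
rotate_pairs <- function(y, X, design) {
  inds <- unique(design$individual_id)
  idx70 <- match(paste0(inds, "_0"),
                 paste0(design$individual_id, "_", design$age01))
  idx80 <- match(paste0(inds, "_1"),
                 paste0(design$individual_id, "_", design$age01))
  if (any(is.na(idx70)) || any(is.na(idx80)))
    stop("non-paired design: each individual needs one sample per age")
  s <- 1 / sqrt(2)
  ys <- s * (y[idx70] + y[idx80]); yd <- s * (y[idx80] - y[idx70])
  Xs <- s * (X[idx70, , drop = FALSE] + X[idx80, , drop = FALSE])
  Xd <- s * (X[idx80, , drop = FALSE] - X[idx70, , drop = FALSE])
  list(y = c(ys, yd), X = rbind(Xs, Xd),
       group = rep(1:2, each = length(inds)), n_pairs = length(inds))
}

reml_weighted <- function(y, X, group, rho) {
  v <- ifelse(group == 1, 1 + rho, 1 - rho)   # relative variances
  w <- 1 / v
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  beta <- solve(XtWX, XtW %*% y)
  r <- y - X %*% beta
  rss <- sum(w * r^2)
  N <- length(y); p <- ncol(X)
  sigma2 <- rss / (N - p)
  ll <- -0.5 * ((N - p) * (log(sigma2) + 1) + sum(log(v)) +
                  determinant(XtWX, logarithm = TRUE)$modulus)
  list(beta = beta, sigma2 = sigma2, rho = rho, loglik = as.numeric(ll),
       XtWX = XtWX, v = v, w = w)
}

#' Paired linear mixed model for one response
#'
#' Fits `y ~ age + covariates` with a per-individual random intercept by
#' REML, profiling the intra-class correlation of the compound-symmetric 2x2
#' per-individual covariance (1-D optimization over (-1+eps, 1-eps)).  The
#' age effect is tested with a Wald t-statistic whose denominator degrees of
#' freedom come from Satterthwaite's approximation based on the REML
#' information of the two variance components.  With no covariates the fit
#' reproduces the paired t-test exactly (df = n - 1).
#'
#' @param y numeric response per sample.
#' @param design design table (`individual_id`, `age01`, `sample_id`).
#' @param covariates optional numeric matrix (samples x k) of fixed
#'   covariates (e.g. hidden factors, RIN).
#' @param tol optimization tolerance on the intra-class correlation.
#' @return list of class `longage_lmm`: `beta_age`, `se`, `df`, `t`,
#'   `p_value`, `rho`, `sigma2`, `beta` (all fixed effects), `loglik`.
#' @export
fit_paired_lmm <- function(y, design, covariates = NULL, tol = 1e-10) {
  X <- cbind(`(Intercept)` = 1, age = design$age01)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular covariates: ", paste(bad, collapse = ", "))
  }
  rot <- rotate_pairs(y, X, design)
  if (rot$n_pairs < 3) stop("need at least 3 complete pairs")
  eps <- 1e-8
  opt <- stats::optimize(function(r)
    reml_weighted(rot$y, rot$X, rot$group, r)$loglik,
    interval = c(-1 + eps, 1 - eps), maximum = TRUE, tol = tol)
  fit <- reml_weighted(rot$y, rot$X, rot$group, opt$maximum)

  ## polish by Fisher scoring on the two rotated-group variances
  ## theta = sigma^2 * (1+rho, 1-rho) until the REML score vanishes to
  ## machine precision (golden-section alone stops near sqrt(eps))
  theta <- fit$sigma2 * c(1 + fit$rho, 1 - fit$rho)
  theta <- pmax(theta, max(theta, 1e-300) * 1e-8)  # keep XtWX invertible
  Xr <- rot$X
  grp <- rot$group
  cvec <- as.numeric(colnames(X) == "age")
  state <- NULL
  eval_state <- function(theta) {
    W <- 1 / theta[grp]
    WX <- Xr * W
    Binv <- tryCatch(solve(t(WX) %*% Xr), error = function(e) NULL)
    if (is.null(Binv)) return(NULL)
    beta <- Binv %*% (t(WX) %*% rot$y)
    r <- as.numeric(rot$y - Xr %*% beta)
    P <- diag(W) - WX %*% Binv %*% t(WX)
    info <- matrix(0, 2, 2)
    score <- numeric(2)
    for (j in 1:2) {
      rj <- grp == j
      score[j] <- -0.5 * (sum(diag(P)[rj]) - sum((W[rj] * r[rj])^2))
      for (k in j:2)
        info[j, k] <- info[k, j] <- 0.5 * sum(P[rj, grp == k]^2)
    }
    list(W = W, Binv = Binv, beta = beta, P = P, info = info,
         score = score)
  }
  floor_th <- max(theta, 1e-300) * 1e-8
  for (it in 1:25) {
    st <- eval_state(theta)
    if (is.null(st)) break
    state <- st
    if (max(abs(state$score)) < 1e-10 * max(1, 1 / min(theta))) break
    step <- tryCatch(solve(state$info, state$score),
                     error = function(e) NULL)
    if (is.null(step)) break
    new <- pmax(theta + step, floor_th)
    if (all(new == theta)) break
    theta <- new
  }
  if (is.null(state)) stop("variance estimation failed")
  Binv <- state$Binv
  f <- as.numeric(t(cvec) %*% Binv %*% cvec)  # Var(beta_age)
  ## gradient of f wrt theta_j: c' B X' (A_j / theta_j^2) X B c
  gr <- vapply(1:2, function(j) {
    rows <- grp == j
    Xj <- Xr[rows, , drop = FALSE]
    as.numeric(t(cvec) %*% Binv %*% (t(Xj) %*% Xj / theta[j]^2) %*%
                 Binv %*% cvec)
  }, numeric(1))
  ## in degenerate fits (e.g. zero within-pair variance) the information
  ## matrix is near-singular; fall back to the diff-component-only df
  iinv_g <- tryCatch(solve(state$info, gr), error = function(e) NULL)
  df <- if (!is.null(iinv_g)) 2 * f^2 / as.numeric(t(gr) %*% iinv_g)
        else rot$n_pairs - ncol(X) + 1
  b <- as.numeric(state$beta[colnames(X) == "age"])
  se <- sqrt(f)
  fit$beta <- state$beta
  fit$sigma2 <- mean(theta)
  fit$rho <- (theta[1] - theta[2]) / sum(theta)
  tstat <- b / se
  structure(list(beta_age = b, se = se, df = df, t = tstat,
                 p_value = 2 * stats::pt(-abs(tstat), df),
                 rho = fit$rho, sigma2 = fit$sigma2,
                 beta = stats::setNames(as.numeric(fit$beta), colnames(X)),
                 loglik = fit$loglik),
            class = "longage_lmm")
}

#' @export
print.longage_lmm <- function(x, ...) {
  cat(sprintf(
    "paired LMM: beta_age = %.4g (se %.3g), t = %.3f, df = %.2f, p = %.3g\n",
    x$beta_age, x$se, x$t, x$df, x$p_value))
  invisible(x)
}

#' Storey q-values
#'
#' pi0 is estimated on the lambda grid 0.05-0.95 (step 0.05) with a cubic
#' smoother extrapolated to lambda = 1; `q_i = pi0 * min_{p >= p_i} m p /
#' rank(p)`, clipped to \[0, 1\].
#'
#' @param p vector of p-values in \[0, 1\].
#' @param lambda grid for pi0 estimation.
#' @param pi0 optionally pin pi0 (e.g. 1 gives Benjamini-Hochberg).
#' @return list: `qvalues` (same order as `p`), `pi0`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  if (length(p) == 0) return(list(qvalues = numeric(0), pi0 = NA_real_))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = 1)$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- cummin(q)
  q <- pmin(q, 1)
  qv <- numeric(m)
  qv[o] <- q
  list(qvalues = qv, pi0 = pi0)
}

#' Differential-expression scan across genes
#'
#' Fits [fit_paired_lmm()] per kept gene with hidden factors and measured
#' covariates as fixed effects, attaches Storey q-values and the per-gene
#' variance explained by age.
#'
#' @param normalized genes x samples matrix (log2 scale).
#' @param design design table.
#' @param hidden_factors a `longage_factors` object or a samples x k matrix
#'   (or `NULL`).
#' @param covariates character vector of design columns to add as fixed
#'   covariates (default RIN and RNA concentration when present).
#' @param fdr FDR threshold for the `significant` flag (default 0.05).
#' @return data.frame of class `longage_de`: gene, beta_age, se,
#'   satterthwaite_df, t, p_value, q_value, var_explained_by_age,
#'   significant.
#' @export
de_scan <- function(normalized, design, hidden_factors = NULL,
                    covariates = intersect(c("rin", "rna_conc"),
                                           colnames(design)),
                    fdr = 0.05) {
  fac <- if (inherits(hidden_factors, "longage_factors"))
    hidden_factors$factors else hidden_factors
  covm <- NULL
  if (!is.null(fac) && ncol(fac) > 0) covm <- cbind(covm, fac)
  if (length(covariates) > 0)
    covm <- cbind(covm, as.matrix(design[, covariates, drop = FALSE]))
  rows <- lapply(rownames(normalized), function(g) {
    fit <- tryCatch(fit_paired_lmm(normalized[g, ], design, covm),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    ve <- variance_explained_by_age(normalized[g, ], design, covm)
    data.frame(gene = g, beta_age = fit$beta_age, se = fit$se,
               satterthwaite_df = fit$df, t = fit$t, p_value = fit$p_value,
               var_explained_by_age = ve, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(structure(data.frame(), class = c("longage_de", "data.frame")))
  st <- storey_qvalues(res$p_value)
  res$q_value <- st$qvalues
  res$significant <- res$q_value <= fdr
  attr(res, "pi0") <- st$pi0
  class(res) <- c("longage_de", "data.frame")
  res
}

#' Variance in expression explained by age
#'
#' Semi-partial R-squared after individual-effect removal: expression is
#' centered within individual, then the drop in residual variance from
#' adding age to the covariate-only model is divided by the total variance
#' of the centered response.  Bounded to \[0, 1\].
#'
#' @param y per-sample values.
#' @param design design table.
#' @param covariates optional samples x k matrix.
#' @return fraction in \[0, 1\].
#' @export
variance_explained_by_age <- function(y, design, covariates = NULL) {
  ind_mean <- stats::ave(y, design$individual_id)
  yc <- y - ind_mean
  tss <- sum(yc^2)
  if (tss < .Machine$double.eps) {
    warning("degenerate within-individual variance; returning 0")
    return(0)
  }
  X0 <- matrix(1, length(y), 1)
  if (!is.null(covariates)) X0 <- cbind(X0, as.matrix(covariates))
  X1 <- cbind(X0, age = design$age01)
  rss0 <- sum(stats::lm.fit(X0, yc)$residuals^2)
  rss1 <- sum(stats::lm.fit(X1, yc)$residuals^2)
  min(max((rss0 - rss1) / tss, 0), 1)
}

#' Detect individuals with outlying age trajectories
#'
#' Per gene, the within-individual change `delta = E_age1 - E_age0` is
#' computed; individuals whose delta falls outside
#' `(Q1 - k IQR, Q3 + k IQR)` (linear-interpolation, type-7 quantiles;
#' default k = 3) are flagged.  Extremeness is the signed exceedance beyond
#' the violated fence.
#'
#' @param normalized genes x samples matrix (typically hidden-factor-
#'   corrected residuals plus the age effect).
#' @param design design table.
#' @param individuals optional subset of individual ids to consider (e.g.
#'   those passing clustering concordance).
#' @param k fence multiplier (default 3).
#' @return data.frame: gene, individual_id, delta, fence_low, fence_high,
#'   extremeness.
#' @export
detect_trajectory_outliers <- function(normalized, design,
                                       individuals = NULL, k = 3) {
  inds <- unique(design$individual_id)
  if (!is.null(individuals)) inds <- intersect(inds, individuals)
  if (length(inds) < 10)
    stop("fewer than 10 individuals: outlier fences are unstable")
  idx0 <- match(paste0(inds, "_0"),
                paste0(design$individual_id, "_", design$age01))
  idx1 <- match(paste0(inds, "_1"),
                paste0(design$individual_id, "_", design$age01))
  out <- lapply(rownames(normalized), function(g) {
    delta <- normalized[g, idx1] - normalized[g, idx0]
    qs <- stats::quantile(delta, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- qs[2] - qs[1]
    lo <- qs[1] - k * iqr
    hi <- qs[2] + k * iqr
    flag <- delta < lo | delta > hi
    if (!any(flag)) return(NULL)
    data.frame(gene = g, individual_id = inds[flag], delta = delta[flag],
               fence_low = lo, fence_high = hi,
               extremeness = ifelse(delta[flag] > hi, delta[flag] - hi,
                                    delta[flag] - lo),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(), individual_id = character(),
                      delta = numeric(), fence_low = numeric(),
                      fence_high = numeric(), extremeness = numeric())
  rownames(res) <- NULL
  res
}
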