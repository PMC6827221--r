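## Intron-cluster filtering, usage ratios, Dirichlet-multinomial
## differential splicing by age, and gene/cluster hierarchical FDR.

#' Build an intron cluster set from a junction count matrix
#'
#' @param counts introns x samples integer matrix with rownames
#'   `"chrom:start:end:cluster"`.
#' @param gene_map optional data.frame (cluster_id, gene_id); clusters
#'   without a mapping keep their cluster id as gene id.
#' @return list of class `longage_clusters`: `counts`, `introns` (chrom,
#'   start, end, cluster_id, gene_id per row).
#' @export
intron_cluster_set <- function(counts, gene_map = NULL) {
  parts <- strsplit(rownames(counts), ":", fixed = TRUE)
  stopifnot(all(lengths(parts) == 4))
  introns <- data.frame(
    intron_id = rownames(counts),
    chrom = vapply(parts, `[`, "", 1),
    start = as.integer(vapply(parts, `[`, "", 2)),
    end = as.integer(vapply(parts, `[`, "", 3)),
    cluster_id = vapply(parts, `[`, "", 4),
    stringsAsFactors = FALSE)
  introns$gene_id <- introns$cluster_id
  if (!is.null(gene_map)) {
    m <- match(introns$cluster_id, gene_map$cluster_id)
    introns$gene_id[!is.na(m)] <- gene_map$gene_id[m[!is.na(m)]]
  }
  structure(list(counts = counts, introns = introns),
            class = "longage_clusters")
}

#' @export
print.longage_clusters <- function(x, ...) {
  cat("intron cluster set:", nrow(x$counts), "introns in",
      length(unique(x$introns$cluster_id)), "clusters,",
      ncol(x$counts), "samples\n")
  invisible(x)
}

#' Hellinger variability of a cluster
#'
#' Mean over samples of the Hellinger distance
#' `H(p_s, pbar) = sqrt(1 - sum_i sqrt(p_si * pbar_i))` between each
#' sample's intron-usage proportion vector and the cluster-mean vector
#' (mean of per-sample proportions).  Samples with zero cluster reads are
#' excluded.
#'
#' @param cluster_counts introns x samples counts of one cluster (>= 2
#'   introns).
#' @param aggregate `"mean"` (default) or `"max"` over samples.
#' @return score in \[0, 1\].
#' @export
hellinger_variability <- function(cluster_counts,
                                  aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(nrow(cluster_counts) >= 2)
  tot <- colSums(cluster_counts)
  P <- sweep(cluster_counts[, tot > 0, drop = FALSE], 2, tot[tot > 0], "/")
  if (ncol(P) == 0) return(0)
  pbar <- rowMeans(P)
  h <- sqrt(pmax(1 - colSums(sqrt(P * pbar)), 0))
  if (aggregate == "mean") mean(h) else max(h)
}

#' Filter intron clusters for differential-splicing analysis
#'
#' In sequence: (1) drop clusters with more than `max_introns` introns;
#' (2) mark an intron active if it carries at least `active_frac` of its
#' cluster's reads in at least `active_sample_frac` of samples, each age
#' evaluated separately (an intron must qualify at both ages); (3) drop
#' clusters with fewer than 2 active introns; (4) drop clusters whose
#' Hellinger variability (computed on active introns) is below
#' `hellinger_min`.
#'
#' @param clusters a `longage_clusters` object.
#' @param design design table (for the per-age evaluation).
#' @param max_introns rule-1 cap (default 10).
#' @param active_frac rule-2 read fraction (default 0.10).
#' @param active_sample_frac rule-2 sample fraction (default 0.25).
#' @param hellinger_min rule-4 threshold (default 0.01).
#' @return list: `qc` (data.frame per cluster: n_introns, active_introns,
#'   hellinger, pass_size, pass_active, pass_hellinger, pass), `filtered`
#'   (a `longage_clusters` with only active introns of passing clusters).
#' @export
cluster_filter <- function(clusters, design, max_introns = 10,
                           active_frac = 0.10, active_sample_frac = 0.25,
                           hellinger_min = 0.01) {
  counts <- clusters$counts
  introns <- clusters$introns
  if (nrow(counts) == 0)
    return(list(qc = data.frame(), filtered = clusters))
  stopifnot(identical(colnames(counts), design$sample_id))
  qc <- list(); keep_rows <- list()
  for (cl in unique(introns$cluster_id)) {
    rows <- which(introns$cluster_id == cl)
    sub <- counts[rows, , drop = FALSE]
    n_i <- length(rows)
    pass_size <- n_i <= max_introns
    ## activity per age: share of cluster reads >= active_frac in >=
    ## active_sample_frac of that age's samples
    active <- rep(TRUE, n_i)
    for (a in unique(design$age01)) {
      ss <- sub[, design$age01 == a, drop = FALSE]
      tot <- colSums(ss)
      share <- sweep(ss, 2, pmax(tot, 1), "/")
      share[, tot == 0] <- 0
      active <- active & rowMeans(share >= active_frac) >= active_sample_frac
    }
    n_act <- sum(active)
    pass_active <- n_act >= 2
    hel <- if (pass_active)
      hellinger_variability(sub[active, , drop = FALSE]) else NA_real_
    pass_h <- isTRUE(hel >= hellinger_min)
    pass <- pass_size && pass_active && pass_h
    qc[[cl]] <- data.frame(cluster_id = cl, n_introns = n_i,
                           active_introns = n_act, hellinger = hel,
                           pass_size = pass_size, pass_active = pass_active,
                           pass_hellinger = pass_h, pass = pass,
                           stringsAsFactors = FALSE)
    if (pass) keep_rows[[cl]] <- rows[active]
  }
  qc <- do.call(rbind, qc); rownames(qc) <- NULL
  rows <- unlist(keep_rows, use.names = FALSE)
  filtered <- structure(list(counts = counts[rows, , drop = FALSE],
                             introns = introns[rows, , drop = FALSE]),
                        class = "longage_clusters")
  list(qc = qc, filtered = filtered)
}

#' Intron usage ratios
#'
#' Intron count / cluster total per sample; samples with zero cluster total
#' give missing values.  Optionally rank-normalized (inverse-normal) across
#' samples per intron, as used for sQTL scanning.
#'
#' @param clusters a (filtered) `longage_clusters` object.
#' @param rank_normalize apply a per-intron inverse-normal transform.
#' @return introns x samples numeric matrix.
#' @export
compute_usage_ratios <- function(clusters, rank_normalize = FALSE) {
  counts <- clusters$counts
  introns <- clusters$introns
  ratios <- counts * NA_real_
  for (cl in unique(introns$cluster_id)) {
    rows <- which(introns$cluster_id == cl)
    tot <- colSums(counts[rows, , drop = FALSE])
    r <- sweep(counts[rows, , drop = FALSE], 2, tot, "/")
    r[, tot == 0] <- NA_real_
    ratios[rows, ] <- r
  }
  if (rank_normalize) {
    ratios <- t(apply(ratios, 1, function(x) {
      ok <- !is.na(x)
      x[ok] <- stats::qnorm((rank(x[ok]) - 0.5) / sum(ok))
      x
    }))
  }
  ratios
}

## Dirichlet-multinomial log-likelihood for one sample:
## log Gamma(a0) - log Gamma(T + a0) + sum_i [log Gamma(x_i + a_i) -
## log Gamma(a_i)], a = a0 * p.
dm_ll_sample <- function(x, alpha) {
  a0 <- sum(alpha)
  lgamma(a0) - lgamma(sum(x) + a0) + sum(lgamma(x + alpha) - lgamma(alpha))
}

#' Dirichlet-multinomial GLM for one intron cluster
#'
#' Softmax-linked intron-proportion linear predictors with per-intron
#' intercepts, age coefficients (alternative model only) and optional
#' per-intron covariate coefficients; the last intron's coefficients are
#' fixed at zero for identifiability.  A single cluster-level concentration
#' is estimated.  ML by quasi-Newton with a multinomial-proportions
#' initialization.
#'
#' @param cluster_counts introns x samples counts.
#' @param age01 0/1 age per sample.
#' @param covariates optional samples x k numeric matrix.
#' @param model `"alt"` or `"null"` (no age term).
#' @return list of class `longage_dm`: `loglik`, `concentration`,
#'   `intercepts`, `age_effects`, `convergence`.
#' @export
fit_dm_glm <- function(cluster_counts, age01, covariates = NULL,
                       model = c("alt", "null")) {
  model <- match.arg(model)
  I <- nrow(cluster_counts); S <- ncol(cluster_counts)
  stopifnot(I >= 2, length(age01) == S)
  Z <- if (is.null(covariates)) matrix(0, S, 0) else as.matrix(covariates)
  if (ncol(Z) > 0) Z <- scale(Z)   # optimizer stability; ll unchanged
  k <- ncol(Z)
  nf <- I - 1                          # free introns
  with_age <- model == "alt"
  npar <- nf * (1 + with_age + k) + 1  # + log concentration
  unpack <- function(par) {
    mu <- par[seq_len(nf)]
    off <- nf
    b <- if (with_age) par[off + seq_len(nf)] else rep(0, nf)
    if (with_age) off <- off + nf
    G <- if (k > 0) matrix(par[off + seq_len(nf * k)], nf, k)
         else matrix(0, nf, 0)
    ## concentration capped at exp(15): beyond that the DM is numerically
    ## indistinguishable from its multinomial limit and the lgamma
    ## difference terms lose all precision
    list(mu = mu, b = b, G = G, a0 = exp(min(par[npar], 15)))
  }
  tot <- colSums(cluster_counts)
  negll <- function(par) {
    pp <- unpack(par)
    eta <- matrix(0, I, S)
    eta[seq_len(nf), ] <- pp$mu + outer(pp$b, age01) +
      if (k > 0) pp$G %*% t(Z) else 0
    E <- exp(sweep(eta, 2, apply(eta, 2, max)))
    P <- sweep(E, 2, colSums(E), "/")
    A <- pmax(pp$a0 * P, 1e-10)
    ll <- S * lgamma(pp$a0) - sum(lgamma(tot + pp$a0)) +
      sum(lgamma(cluster_counts + A) - lgamma(A))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  pbar <- rowMeans(sweep(cluster_counts, 2,
                         pmax(colSums(cluster_counts), 1), "/"))
  pbar <- pmax(pbar, 1e-4); pbar <- pbar / sum(pbar)
  start <- c(log(pbar[seq_len(nf)] / pbar[I]),
             if (with_age) rep(0, nf),
             rep(0, nf * k), log(20))
  op <- stats::optim(start, negll, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-12))
  pp <- unpack(op$par)
  structure(list(loglik = -op$value, concentration = pp$a0,
                 intercepts = pp$mu, age_effects = pp$b,
                 df_age = nf, convergence = op$convergence == 0),
            class = "longage_dm")
}

#' @export
print.longage_dm <- function(x, ...) {
  cat(sprintf("DM GLM: loglik %.3f, concentration %.1f, %d free introns\n",
              x$loglik, x$concentration, x$df_age))
  invisible(x)
}

#' Differential-splicing scan with gene/cluster hierarchical FDR
#'
#' Per filtered cluster, a likelihood ratio test between the alternative
#' and null Dirichlet-multinomial fits (df = active introns - 1); genes get
#' Simes p-values over their clusters, and the gene/cluster hierarchy is
#' controlled by the same two-level procedure as the QTL module (default
#' 5% / 5%).
#'
#' @param clusters a filtered `longage_clusters` object.
#' @param design design table.
#' @param covariates optional samples x k matrix.
#' @param q_gene,q_cluster FDR levels (defaults 0.05).
#' @return list of class `longage_ds`: `clusters` (cluster_id, gene_id,
#'   lrt, df, p, significant), `genes` (gene_id, simes_p, significant),
#'   `n_failed`.
#' @export
ds_scan <- function(clusters, design, covariates = NULL,
                    q_gene = 0.05, q_cluster = 0.05) {
  introns <- clusters$introns
  rows <- lapply(unique(introns$cluster_id), function(cl) {
    ii <- which(introns$cluster_id == cl)
    sub <- clusters$counts[ii, , drop = FALSE]
    fa <- tryCatch(fit_dm_glm(sub, design$age01, covariates, "alt"),
                   error = function(e) NULL)
    f0 <- tryCatch(fit_dm_glm(sub, design$age01, covariates, "null"),
                   error = function(e) NULL)
    if (is.null(fa) || is.null(f0)) return(NULL)
    lrt <- max(2 * (fa$loglik - f0$loglik), 0)
    data.frame(cluster_id = cl, gene_id = introns$gene_id[ii[1]],
               lrt = lrt, df = fa$df_age,
               p = stats::pchisq(lrt, fa$df_age, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  failed <- sum(vapply(rows, is.null, logical(1)))
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(structure(list(clusters = data.frame(), genes = data.frame(),
                          n_failed = failed), class = "longage_ds"))
  ## reuse the hierarchical machinery: genes are "phenotypes", clusters the
  ## within-family tests
  scan <- list(
    pairs = data.frame(phenotype_id = res$gene_id, snp_id = res$cluster_id,
                       p = res$p, stringsAsFactors = FALSE),
    phenotypes = do.call(rbind, lapply(split(res, res$gene_id), function(d)
      data.frame(phenotype_id = d$gene_id[1],
                 simes_p = simes_pvalue(d$p), n_snps = nrow(d),
                 stringsAsFactors = FALSE))))
  hf <- hierarchical_fdr(scan, q_phenotype = q_gene, q_within = q_cluster)
  res$significant <- res$cluster_id %in% hf$pairs$snp_id
  genes <- scan$phenotypes
  genes$significant <- genes$phenotype_id %in% hf$selected
  names(genes)[names(genes) == "phenotype_id"] <- "gene_id"
  structure(list(clusters = res, genes = genes[, c("gene_id", "simes_p",
                                                   "significant")],
                 n_failed = failed), class = "longage_ds")
}

#' @export
print.longage_ds <- function(x, ...) {
  cat("differential splicing:", sum(x$clusters$significant),
      "significant clusters in", sum(x$genes$significant), "genes (of",
      nrow(x$clusters), "clusters /", nrow(x$genes), "genes tested )\n")
  invisible(x)
}
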