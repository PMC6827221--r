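## cis-QTL association, Simes gene-level p-values, hierarchical FDR,
## two-step replication FDR across ages, and concordance tests.

#' Map cis QTLs for one age group
#'
#' Phenotypes and genotypes are residualized on the covariates (plus
#' intercept); each phenotype-SNP pair within the cis window is then tested
#' by OLS slope with a t-test on `n - k - 2` degrees of freedom (k =
#' number of covariates), the convention that accounts for the projected-out
#' covariates.
#'
#' @param phenotypes phenotypes x individuals matrix (one age).
#' @param genotypes SNPs x individuals dosage matrix (same individuals).
#' @param pheno_pos data.frame: phenotype_id, chrom, pos (TSS or intron
#'   position) for each phenotype row.
#' @param snp_pos data.frame: snp_id, chrom, pos.
#' @param covariates optional individuals x k matrix.
#' @param window cis window in bp (1e6 for eQTL, 1e5 for sQTL).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @return list of class `longage_qtl_scan`: `pairs` (phenotype_id, snp_id,
#'   distance, beta, se, t, p), `phenotypes` (phenotype_id, n_snps,
#'   simes_p), `n`, `df`.
#' @export
map_cis_qtl <- function(phenotypes, genotypes, pheno_pos, snp_pos,
                        covariates = NULL, window = 1e6, maf_min = 0.05) {
  n <- ncol(phenotypes)
  stopifnot(ncol(genotypes) == n)
  X <- matrix(1, n, 1)
  k <- 0
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
    k <- ncol(covariates)
  }
  maf <- rowMeans(genotypes) / 2
  maf <- pmin(maf, 1 - maf)
  poly <- maf >= maf_min
  resid_mat <- function(M) t(stats::lm.fit(X, t(M))$residuals)
  Yr <- resid_mat(phenotypes)
  Gr <- resid_mat(genotypes[poly, , drop = FALSE])
  snp_ok <- snp_pos[poly, , drop = FALSE]
  df <- n - k - 2
  pair_list <- list(); ph_list <- list()
  for (i in seq_len(nrow(phenotypes))) {
    pid <- pheno_pos$phenotype_id[i]
    same <- snp_ok$chrom == pheno_pos$chrom[i]
    dist <- snp_ok$pos - pheno_pos$pos[i]
    sel <- which(same & abs(dist) <= window)
    if (length(sel) == 0) next
    y <- Yr[i, ]
    G <- Gr[sel, , drop = FALSE]
    gc <- G - rowMeans(G)
    yc <- y - mean(y)
    sxx <- rowSums(gc^2)
    beta <- as.numeric(gc %*% yc) / sxx
    rss <- sum(yc^2) - beta^2 * sxx
    se <- sqrt(rss / df / sxx)
    tt <- beta / se
    p <- 2 * stats::pt(-abs(tt), df)
    pair_list[[pid]] <- data.frame(
      phenotype_id = pid, snp_id = snp_ok$snp_id[sel],
      distance = dist[sel], beta = beta, se = se, t = tt, p = p,
      stringsAsFactors = FALSE)
    ph_list[[pid]] <- data.frame(
      phenotype_id = pid, n_snps = length(sel), simes_p = simes_pvalue(p),
      stringsAsFactors = FALSE)
  }
  structure(list(pairs = do.call(rbind, pair_list),
                 phenotypes = do.call(rbind, ph_list),
                 n = n, df = df, window = window),
            class = "longage_qtl_scan")
}

#' @export
print.longage_qtl_scan <- function(x, ...) {
  cat("cis-QTL scan:", nrow(x$phenotypes), "phenotypes,", nrow(x$pairs),
      "pairs, n =", x$n, ", residual df =", x$df, "\n")
  invisible(x)
}

#' Simes combination of a family of p-values
#'
#' `p_Simes = min_k (m p_(k) / k)` over the sorted p-values; a valid
#' family-level p-value robust to positive dependence.
#'
#' @param p vector of pair p-values (length >= 1).
#' @return scalar p-value.
#' @export
simes_pvalue <- function(p) {
  if (length(p) == 0) stop("empty p-value family")
  ps <- sort(p)
  min(min(length(p) * ps / seq_along(ps)), 1)
}

#' Hierarchical (two-level) FDR over phenotypes and pairs
#'
#' Level 1: Benjamini-Hochberg on the per-phenotype Simes p-values at
#' `q_phenotype`.  Level 2: within each selected phenotype,
#' Benjamini-Hochberg on its pair p-values at `q_within * R / M` where `R`
#' is the number of selected phenotypes and `M` the number tested
#' (Benjamini-Bogomolov-style budget; set `adjust_level2 = FALSE` for plain
#' within-family BH).
#'
#' @param scan a `longage_qtl_scan` (or compatible list with `pairs` and
#'   `phenotypes`).
#' @param q_phenotype level-1 FDR (default 0.01).
#' @param q_within level-2 FDR (default 0.01).
#' @param adjust_level2 apply the R/M budget correction (default TRUE).
#' @return list: `selected` (phenotype ids), `pairs` (significant pair rows),
#'   `R`, `M`.
#' @export
hierarchical_fdr <- function(scan, q_phenotype = 0.01, q_within = 0.01,
                             adjust_level2 = TRUE) {
  if (q_phenotype <= 0 || q_phenotype >= 1 || q_within <= 0 || q_within >= 1)
    stop("FDR levels must lie in (0, 1)")
  ph <- scan$phenotypes
  M <- nrow(ph)
  padj <- stats::p.adjust(ph$simes_p, method = "BH")
  sel <- ph$phenotype_id[padj <= q_phenotype]
  R <- length(sel)
  sig_pairs <- NULL
  if (R > 0) {
    budget <- if (adjust_level2) q_within * R / M else q_within
    sub <- scan$pairs[scan$pairs$phenotype_id %in% sel, , drop = FALSE]
    keep <- unlist(lapply(split(seq_len(nrow(sub)), sub$phenotype_id),
                          function(ii) {
      ii[stats::p.adjust(sub$p[ii], method = "BH") <= budget]
    }))
    sig_pairs <- sub[sort(keep), , drop = FALSE]
  }
  list(selected = sel, pairs = sig_pairs, R = R, M = M)
}

#' Two-step replication FDR across ages
#'
#' Discover phenotypes at `q_discovery` (BH on Simes p-values) in the
#' discovery scan, then re-run multiple testing in the validation scan
#' restricted to the discovered set at `q_validation`.
#'
#' @param discovery_scan,validation_scan `longage_qtl_scan` objects on the
#'   same phenotype universe.
#' @param q_discovery discovery FDR (default 0.01).
#' @param q_validation validation FDR (default 0.10).
#' @return list: `proportion` (replicated / discovered; `NA` when nothing is
#'   discovered), `discovered`, `replicated` (phenotype ids), `flags`
#'   (data.frame per discovered phenotype).
#' @export
replicate_two_step <- function(discovery_scan, validation_scan,
                               q_discovery = 0.01, q_validation = 0.10) {
  dph <- discovery_scan$phenotypes
  disc <- dph$phenotype_id[
    stats::p.adjust(dph$simes_p, method = "BH") <= q_discovery]
  if (length(disc) == 0)
    return(list(proportion = NA_real_, discovered = character(),
                replicated = character(), flags = data.frame()))
  vph <- validation_scan$phenotypes
  sub <- vph[vph$phenotype_id %in% disc, , drop = FALSE]
  rep_ids <- sub$phenotype_id[
    stats::p.adjust(sub$simes_p, method = "BH") <= q_validation]
  flags <- data.frame(phenotype_id = disc,
                      replicated = disc %in% rep_ids,
                      stringsAsFactors = FALSE)
  list(proportion = length(rep_ids) / length(disc), discovered = disc,
       replicated = rep_ids, flags = flags)
}

#' Exact McNemar test on paired discovery flags
#'
#' Discordant counts `b` (flagged in A only) and `c` (flagged in B only);
#' `OR = c / b`; exact two-sided binomial p-value
#' `2 P(Bin(b + c, 1/2) <= min(b, c))`, capped at 1.
#'
#' @param status_a,status_b logical vectors over the same phenotype universe.
#' @return list: `or` (`NA` when `b = c = 0` or `b = 0`), `b`, `c`,
#'   `p_value`.
#' @export
mcnemar_exact <- function(status_a, status_b) {
  stopifnot(length(status_a) == length(status_b))
  b <- sum(status_a & !status_b)
  cc <- sum(!status_a & status_b)
  if (b + cc == 0) return(list(or = NA_real_, b = b, c = cc, p_value = 1))
  p <- min(2 * stats::pbinom(min(b, cc), b + cc, 0.5), 1)
  list(or = if (b > 0) cc / b else NA_real_, b = b, c = cc, p_value = p)
}

#' Spearman correlation of per-phenotype top-SNP effects across ages
#'
#' For each phenotype the top SNP (smallest pair p-value) is chosen in scan
#' A; its effect in both scans is correlated by Spearman's rank correlation.
#'
#' @param scan_a,scan_b `longage_qtl_scan` objects.
#' @param subset `"all"` phenotypes or `"either_significant"` (significant
#'   at `q` in at least one age by BH on Simes p-values).
#' @param q FDR used by the `either_significant` subset rule.
#' @return list: `rho`, `n`, `effects` (data.frame phenotype_id, beta_a,
#'   beta_b).
#' @export
effect_correlation <- function(scan_a, scan_b,
                               subset = c("all", "either_significant"),
                               q = 0.01) {
  subset <- match.arg(subset)
  ids <- intersect(scan_a$phenotypes$phenotype_id,
                   scan_b$phenotypes$phenotype_id)
  if (subset == "either_significant") {
    sig <- function(s) s$phenotypes$phenotype_id[
      stats::p.adjust(s$phenotypes$simes_p, method = "BH") <= q]
    ids <- intersect(ids, union(sig(scan_a), sig(scan_b)))
  }
  rows <- lapply(ids, function(pid) {
    pa <- scan_a$pairs[scan_a$pairs$phenotype_id == pid, , drop = FALSE]
    top <- pa$snp_id[which.min(pa$p)]
    pb <- scan_b$pairs[scan_b$pairs$phenotype_id == pid &
                         scan_b$pairs$snp_id == top, , drop = FALSE]
    if (nrow(pb) == 0) return(NULL)
    data.frame(phenotype_id = pid, beta_a = pa$beta[pa$snp_id == top][1],
               beta_b = pb$beta[1], stringsAsFactors = FALSE)
  })
  eff <- do.call(rbind, rows)
  if (is.null(eff) || nrow(eff) < 3)
    stop("fewer than 3 matched phenotype pairs")
  list(rho = stats::cor(eff$beta_a, eff$beta_b, method = "spearman"),
       n = nrow(eff), effects = eff)
}
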