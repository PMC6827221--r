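make_scan_inputs <- function(n = 50, n_pheno = 8, n_snp = 6, seed = 1) {
  set.seed(seed)
  G <- matrix(rbinom(n_snp * n_pheno * n, 2, 0.3), ncol = n)
  rownames(G) <- sprintf("s%03d", seq_len(nrow(G)))
  snp_pos <- data.frame(snp_id = rownames(G), chrom = "chr1",
                        pos = rep(seq_len(n_pheno) * 1e7,
                                  each = n_snp) + seq_len(n_snp) * 1000)
  Y <- matrix(rnorm(n_pheno * n), ncol = n)
  rownames(Y) <- sprintf("p%02d", seq_len(n_pheno))
  pheno_pos <- data.frame(phenotype_id = rownames(Y), chrom = "chr1",
                          pos = seq_len(n_pheno) * 1e7)
  list(Y = Y, G = G, pheno_pos = pheno_pos, snp_pos = snp_pos)
}

test_that("residualize-then-OLS matches full multiple regression", {
  d <- make_scan_inputs()
  covs <- cbind(rnorm(50), rnorm(50))
  scan <- map_cis_qtl(d$Y, d$G, d$pheno_pos, d$snp_pos, covariates = covs,
                      window = 1e6, maf_min = 0)
  for (r in sample(nrow(scan$pairs), 10)) {
    pid <- scan$pairs$phenotype_id[r]; sid <- scan$pairs$snp_id[r]
    fit <- lm(d$Y[pid, ] ~ d$G[sid, ] + covs)
    sm <- coef(summary(fit))[2, ]
    expect_equal(scan$pairs$beta[r], unname(sm["Estimate"]),
                 tolerance = 1e-8)
    expect_equal(scan$pairs$t[r], unname(sm["t value"]), tolerance = 1e-8)
    expect_equal(scan$pairs$p[r], unname(sm["Pr(>|t|)"]), tolerance = 1e-8)
  }
  expect_equal(scan$df, 50 - 2 - 2)
})

test_that("cis window and MAF rules exclude pairs", {
  d <- make_scan_inputs()
  ## place one SNP just beyond the window
  d$snp_pos$pos[1] <- d$pheno_pos$pos[1] + 1000001
  scan <- map_cis_qtl(d$Y, d$G, d$pheno_pos, d$snp_pos, window = 1e6,
                      maf_min = 0)
  p1 <- scan$pairs[scan$pairs$phenotype_id == "p01", ]
  expect_false(d$snp_pos$snp_id[1] %in% p1$snp_id)
  expect_true(all(abs(scan$pairs$distance) <= 1e6))
  ## monomorphic-ish SNP removed by the MAF filter
  d$G[2, ] <- c(1, rep(0, 49))
  scan2 <- map_cis_qtl(d$Y, d$G, d$pheno_pos, d$snp_pos, window = 1e6,
                       maf_min = 0.05)
  expect_false(d$snp_pos$snp_id[2] %in% scan2$pairs$snp_id)
})

test_that("a planted eQTL is recovered with the right sign and locus", {
  set.seed(2)
  d <- make_scan_inputs(n = 63)
  g <- scale(d$G["s001", ])[, 1]
  d$Y[1, ] <- d$Y[1, ] + 1.0 * g     # 1 SD effect
  scan <- map_cis_qtl(d$Y, d$G, d$pheno_pos, d$snp_pos, window = 1e6)
  p1 <- scan$pairs[scan$pairs$phenotype_id == "p01", ]
  top <- p1[which.min(p1$p), ]
  expect_equal(top$snp_id, "s001")
  expect_gt(top$beta, 0)
  expect_lt(scan$phenotypes$simes_p[1], 0.001)
})

test_that("Simes rule follows its closed form", {
  expect_equal(simes_pvalue(0.2), 0.2)
  expect_equal(simes_pvalue(c(0.01, 0.04, 0.9)), 0.03)
  expect_equal(simes_pvalue(rep(1, 4)), 1)
  expect_error(simes_pvalue(numeric(0)), "empty")
  ## never below the minimum p, never above 1
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    s <- simes_pvalue(p)
    expect_gte(s, min(p))
    expect_lte(s, 1)
  }
})

test_that("Simes p-values are valid (sub-uniform) under the null", {
  set.seed(4)
  sp <- replicate(2000, simes_pvalue(runif(15)))
  ## P(Simes <= a) <= a under independence: check a grid with MC slack
  for (a in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(sp <= a), a + 3 * sqrt(a * (1 - a) / 2000))
})

test_that("hierarchical FDR selects the hand-computed phenotypes", {
  scan <- list(
    phenotypes = data.frame(phenotype_id = c("a", "b", "c"),
                            simes_p = c(0.001, 0.02, 0.8), n_snps = 2),
    pairs = data.frame(phenotype_id = rep(c("a", "b", "c"), each = 2),
                       snp_id = paste0("s", 1:6),
                       p = c(0.0005, 0.5, 0.01, 0.9, 0.8, 0.9)))
  hf <- hierarchical_fdr(scan, q_phenotype = 0.05, q_within = 0.05)
  ## BH on (0.001, 0.02, 0.8) at 5%: 0.001 <= 0.05/3 and 0.02 <= 0.10/3
  expect_setequal(hf$selected, c("a", "b"))
  expect_equal(hf$R, 2)
  ## all pair p = 1: nothing anywhere
  scan$phenotypes$simes_p <- rep(1, 3)
  scan$pairs$p <- rep(1, 6)
  hf2 <- hierarchical_fdr(scan, 0.05, 0.05)
  expect_equal(hf2$R, 0)
  expect_error(hierarchical_fdr(scan, 1.5, 0.05), "0, 1")
})

test_that("two-step replication behaves at its boundaries and is monotone", {
  mk <- function(p) list(phenotypes = data.frame(
    phenotype_id = sprintf("p%03d", seq_along(p)), simes_p = p))
  pA <- c(rep(1e-6, 20), runif(80, 0.2, 1))
  ## identical data at both ages: full replication
  r <- replicate_two_step(mk(pA), mk(pA))
  expect_equal(r$proportion, 1)
  ## empty discovery set: sentinel
  r0 <- replicate_two_step(mk(runif(50, 0.5, 1)), mk(runif(50)))
  expect_true(is.na(r0$proportion))
  expect_equal(length(r0$discovered), 0)
  ## monotone nondecreasing in the validation threshold
  set.seed(5)
  pB <- pA * exp(rnorm(100))
  pB[pB > 1] <- 1
  props <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5),
                  function(q) replicate_two_step(mk(pA), mk(pB),
                                                 q_validation = q)$proportion,
                  numeric(1))
  expect_true(all(diff(props) >= 0))
})

test_that("exact McNemar matches binomial tail arithmetic", {
  m <- mcnemar_exact(c(rep(TRUE, 10), rep(FALSE, 3)),
                     c(rep(FALSE, 10), rep(TRUE, 2), FALSE))
  expect_equal(m$b, 10); expect_equal(m$c, 2)
  expect_equal(m$or, 0.2)
  expect_equal(m$p_value, 158 / 4096, tolerance = 1e-12)
  ## symmetric discordance: capped at 1
  m2 <- mcnemar_exact(c(rep(TRUE, 5), rep(FALSE, 5)),
                      c(rep(FALSE, 5), rep(TRUE, 5)))
  expect_equal(m2$p_value, 1)
  ## identical flags
  f <- c(TRUE, FALSE, TRUE)
  m3 <- mcnemar_exact(f, f)
  expect_equal(m3$p_value, 1)
  expect_true(is.na(m3$or))
})

test_that("effect correlation is rank-invariant and near zero for independent effects", {
  mk_scan <- function(betas) {
    ids <- sprintf("p%03d", seq_along(betas))
    list(phenotypes = data.frame(phenotype_id = ids,
                                 simes_p = rep(1e-4, length(betas))),
         pairs = data.frame(phenotype_id = ids, snp_id = paste0("s", ids),
                            beta = betas, p = rep(1e-5, length(betas))))
  }
  set.seed(6)
  ba <- rnorm(50)
  ec <- effect_correlation(mk_scan(ba), mk_scan(ba))
  expect_equal(ec$rho, 1)
  ## monotone transform leaves rho unchanged
  ec2 <- effect_correlation(mk_scan(ba), mk_scan(exp(2 * ba)))
  expect_equal(ec2$rho, 1)
  ## independent effects over replicates: |rho| small
  rhos <- replicate(30, effect_correlation(mk_scan(rnorm(80)),
                                           mk_scan(rnorm(80)))$rho)
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(30))
  expect_error(effect_correlation(mk_scan(ba[1:2]), mk_scan(ba[1:2])),
               "3 matched")
})

test_that("genotype permutation gives uniform pair p-values", {
  set.seed(7)
  ks <- replicate(5, {
    d <- make_scan_inputs(n = 60, n_pheno = 10, n_snp = 5,
                          seed = sample.int(1e6, 1))
    scan <- map_cis_qtl(d$Y, d$G[, sample(60)], d$pheno_pos, d$snp_pos,
                        window = 1e6, maf_min = 0)
    suppressWarnings(ks.test(scan$pairs$p, "punif")$p.value)
  })
  expect_gt(max(ks), 0.01)   # not systematically non-uniform
  expect_gt(mean(ks > 0.01), 0.5)
})
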