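## counts for one cluster with given per-sample intron proportions
mk_cluster <- function(p_by_sample, totals, cluster = "clu_1",
                       chrom = "chr1") {
  counts <- vapply(seq_along(totals), function(s)
    rmultinom(1, totals[s], p_by_sample[, s])[, 1],
    numeric(nrow(p_by_sample)))
  start <- seq_len(nrow(p_by_sample)) * 100
  rownames(counts) <- sprintf("%s:%d:%d:%s", chrom, start, start + 50,
                              cluster)
  counts
}

test_that("hellinger variability matches its closed forms", {
  ## identical proportions in every sample
  same <- matrix(c(30, 70, 30, 70, 30, 70), 2, 3)
  rownames(same) <- sprintf("chr1:%d:%d:clu_1", 1:2, 2:3)
  expect_equal(hellinger_variability(same), 0, tolerance = 1e-12)
  ## disjoint support (1,0) vs (0,1): both samples at sqrt(1 - sqrt(0.5))
  disj <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(hellinger_variability(disj), sqrt(1 - sqrt(0.5)),
               tolerance = 1e-6)
  expect_equal(sqrt(1 - sqrt(0.5)), 0.5411961, tolerance = 1e-6)
  ## direct two-vector arithmetic: H((.5,.5), (.9,.1))
  h <- sqrt(1 - (sqrt(0.5 * 0.9) + sqrt(0.5 * 0.1)))
  expect_equal(h, 0.3249197, tolerance = 1e-6)
  ## max aggregation bounds the mean
  set.seed(1)
  rnd <- matrix(rpois(40, 20) + 1, 4, 10)
  expect_gte(hellinger_variability(rnd, "max"),
             hellinger_variability(rnd, "mean"))
})

test_that("cluster filters drop oversized, inactive, and invariant clusters", {
  set.seed(2)
  design <- toy_design(20)
  ns <- nrow(design)
  ## 11-intron cluster: dropped by the size rule
  p11 <- matrix(rep(1 / 11, 11 * ns), 11, ns)
  c11 <- mk_cluster(p11, rep(200, ns), "clu_big")
  ## intron at 5% of reads everywhere: inactive; its 3-intron cluster
  ## keeps 2 active introns
  p3 <- matrix(rep(c(0.05, 0.55, 0.40), ns), 3, ns)
  c3 <- mk_cluster(p3, rep(400, ns), "clu_low")
  ## 2-intron cluster where one intron is inactive: dropped (< 2 active)
  p2 <- matrix(rep(c(0.05, 0.95), ns), 2, ns)
  c2 <- mk_cluster(p2, rep(400, ns), "clu_two")
  ## invariant cluster: Hellinger ~ 0, dropped
  c_inv <- mk_cluster(matrix(rep(c(0.5, 0.5), ns), 2, ns) * 0 + 0.5,
                      rep(1e5, ns), "clu_flat")
  counts <- rbind(c11, c3, c2, c_inv)
  colnames(counts) <- design$sample_id
  cf <- cluster_filter(intron_cluster_set(counts), design)
  qc <- cf$qc
  expect_false(qc$pass_size[qc$cluster_id == "clu_big"])
  expect_equal(qc$active_introns[qc$cluster_id == "clu_low"], 2)
  expect_false(qc$pass_active[qc$cluster_id == "clu_two"])
  expect_false(qc$pass[qc$cluster_id == "clu_flat"])
  expect_lt(qc$hellinger[qc$cluster_id == "clu_flat"], 0.01)
  expect_true(qc$pass[qc$cluster_id == "clu_low"])
  ## filtered set retains only active introns of passing clusters
  expect_setequal(unique(cf$filtered$introns$cluster_id), "clu_low")
  expect_equal(nrow(cf$filtered$counts), 2)
})

test_that("usage ratios normalize per cluster and ignore zero totals", {
  counts <- matrix(c(8, 2, 0, 0, 30, 10), 2, 3)
  rownames(counts) <- sprintf("chr1:%d:%d:clu_1", 1:2, 2:3)
  ics <- intron_cluster_set(counts)
  r <- compute_usage_ratios(ics)
  expect_equal(r[, 1], c(0.8, 0.2), ignore_attr = TRUE)
  expect_true(all(is.na(r[, 2])))
  expect_equal(colSums(r, na.rm = TRUE)[3], 1, ignore_attr = TRUE)
  ## duplicating all counts leaves ratios unchanged
  ics2 <- intron_cluster_set(counts * 2)
  expect_equal(compute_usage_ratios(ics2), compute_usage_ratios(ics),
               ignore_attr = TRUE)
})

test_that("DM log-likelihood matches a direct rising-factorial oracle", {
  ## DM pmf (without the multinomial coefficient):
  ## prod_i prod_{j<x_i} (a_i + j) / prod_{j<T} (a0 + j)
  oracle <- function(x, alpha) {
    num <- sum(unlist(lapply(seq_along(x), function(i)
      if (x[i] > 0) log(alpha[i] + 0:(x[i] - 1)) else 0)))
    num - sum(log(sum(alpha) + 0:(sum(x) - 1)))
  }
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    alpha <- rgamma(k, 2, 0.5)
    x <- as.numeric(rmultinom(1, sample(10:80, 1), rgamma(k, 1) + 0.1))
    expect_equal(longage:::dm_ll_sample(x, alpha), oracle(x, alpha),
                 tolerance = 1e-8)
  }
})

test_that("DM GLM detects a planted usage shift and approaches the multinomial limit", {
  set.seed(4)
  design <- toy_design(65)
  ns <- nrow(design)
  ## planted: usage 0.7 -> 0.5 across ages
  p70 <- c(0.7, 0.3); p80 <- c(0.5, 0.5)
  counts <- vapply(seq_len(ns), function(s) {
    p <- if (design$age01[s] == 0) p70 else p80
    pr <- longage:::rdirichlet(1, 40 * p)[1, ]
    rmultinom(1, 150, pr)[, 1]
  }, numeric(2))
  rownames(counts) <- sprintf("chr1:%d:%d:clu_1", 1:2, 2:3)
  fa <- fit_dm_glm(counts, design$age01, model = "alt")
  f0 <- fit_dm_glm(counts, design$age01, model = "null")
  lrt <- 2 * (fa$loglik - f0$loglik)
  expect_gt(lrt, qchisq(0.999, 1))
  ## huge concentration: age coefficients approach the multinomial
  ## logistic solution (logit difference of the group proportions)
  set.seed(5)
  counts2 <- vapply(seq_len(ns), function(s) {
    p <- if (design$age01[s] == 0) p70 else p80
    rmultinom(1, 400, p)[, 1]
  }, numeric(2))
  rownames(counts2) <- rownames(counts)
  fit <- fit_dm_glm(counts2, design$age01, model = "alt")
  tot <- rbind(rowSums(counts2[, design$age01 == 0]),
               rowSums(counts2[, design$age01 == 1]))
  emp <- log(tot[2, 1] / tot[2, 2]) - log(tot[1, 1] / tot[1, 2])
  expect_gt(fit$concentration, 1e3)
  expect_equal(fit$age_effects[1], emp, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("DM GLM null LRT p-values are approximately uniform", {
  set.seed(6)
  design <- toy_design(40)
  ns <- nrow(design)
  ps <- replicate(60, {
    p <- longage:::rdirichlet(1, c(3, 3, 3))[1, ]
    counts <- vapply(seq_len(ns), function(s) {
      pr <- longage:::rdirichlet(1, 30 * p)[1, ]
      rmultinom(1, 120, pr)[, 1]
    }, numeric(3))
    rownames(counts) <- sprintf("chr1:%d:%d:clu_1", 1:3, 2:4)
    fa <- fit_dm_glm(counts, design$age01, model = "alt")
    f0 <- fit_dm_glm(counts, design$age01, model = "null")
    pchisq(max(2 * (fa$loglik - f0$loglik), 0), fa$df_age,
           lower.tail = FALSE)
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("ds_scan flags planted clusters through the gene/cluster hierarchy", {
  co <- small_cohort()
  ics <- intron_cluster_set(co$junctions,
                            unique(co$introns[, c("cluster_id", "gene_id")]))
  cf <- cluster_filter(ics, co$design)
  scan <- ds_scan(cf$filtered, co$design)
  expect_true(all(scan$clusters$p >= 0 & scan$clusters$p <= 1))
  ## single-cluster genes: gene Simes p equals the cluster p
  expect_equal(sort(scan$genes$simes_p), sort(scan$clusters$p),
               tolerance = 1e-12)
  planted <- intersect(co$truth$ds$cluster_id, scan$clusters$cluster_id)
  if (length(planted) > 0) {
    pr <- scan$clusters$p[match(planted, scan$clusters$cluster_id)]
    expect_lt(median(pr), 0.01)
  }
})

test_that("filters are order-independent on a fixture where order is not binding", {
  set.seed(7)
  design <- toy_design(15)
  ns <- nrow(design)
  cl <- lapply(1:6, function(i) {
    k <- sample(2:4, 1)
    p <- longage:::rdirichlet(1, rep(2, k))[1, ]
    mk_cluster(matrix(rep(p, ns), k, ns), rpois(ns, 150) + 20,
               sprintf("clu_%d", i))
  })
  counts <- do.call(rbind, cl)
  colnames(counts) <- design$sample_id
  ics <- intron_cluster_set(counts)
  cf <- cluster_filter(ics, design)
  ## permuting cluster order leaves per-cluster decisions unchanged
  perm <- sample(nrow(counts))
  cf2 <- cluster_filter(intron_cluster_set(counts[perm, ]), design)
  m <- match(cf$qc$cluster_id, cf2$qc$cluster_id)
  expect_equal(cf$qc$pass, cf2$qc$pass[m])
  expect_equal(cf$qc$hellinger, cf2$qc$hellinger[m])
})
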