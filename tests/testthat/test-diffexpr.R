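test_that("paired LMM reproduces the paired t-test exactly without covariates", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    design <- toy_design(n)
    y <- rnorm(2 * n, sd = runif(1, 0.5, 3)) +
      rep(rnorm(n), each = 2) + design$age01 * rnorm(1)
    fit <- fit_paired_lmm(y, design)
    tt <- t.test(y[design$age01 == 1], y[design$age01 == 0], paired = TRUE)
    expect_equal(fit$beta_age, unname(tt$estimate), tolerance = 1e-8)
    expect_equal(fit$t, unname(tt$statistic), tolerance = 1e-8)
    expect_equal(fit$p_value, tt$p.value, tolerance = 1e-8)
    expect_equal(fit$df, n - 1, tolerance = 1e-6)
  }
})

test_that("paired LMM with covariates matches lmerTest's Satterthwaite fit", {
  skip_if_not_installed("lmerTest")
  set.seed(2)
  n <- 30
  design <- toy_design(n)
  u <- rep(rnorm(n, sd = 1), each = 2)
  covs <- cbind(c1 = rnorm(2 * n), c2 = rnorm(2 * n))
  y <- 2 + 0.4 * design$age01 + 0.3 * covs[, 1] - 0.2 * covs[, 2] + u +
    rnorm(2 * n, sd = 0.7)
  fit <- fit_paired_lmm(y, design, covs)
  df <- data.frame(y = y, age = design$age01, c1 = covs[, 1],
                   c2 = covs[, 2], ind = design$individual_id)
  lf <- lmerTest::lmer(y ~ age + c1 + c2 + (1 | ind), data = df)
  sm <- coef(summary(lf))["age", ]
  expect_equal(fit$beta_age, unname(sm["Estimate"]), tolerance = 1e-5)
  expect_equal(fit$se, unname(sm["Std. Error"]), tolerance = 1e-4)
  expect_equal(fit$df, unname(sm["df"]), tolerance = 0.02)
  expect_equal(fit$p_value, unname(sm["Pr(>|t|)"]), tolerance = 1e-3)
})

test_that("paired LMM degenerate and error cases", {
  design <- toy_design(8)
  y <- rep(rnorm(8), each = 2)   # identical at both ages
  fit <- fit_paired_lmm(y, design)
  expect_equal(fit$beta_age, 0, tolerance = 1e-10)
  covs <- cbind(a = design$age01, b = rnorm(16))
  expect_error(fit_paired_lmm(rnorm(16), design, covs), "singular")
  expect_error(fit_paired_lmm(rnorm(4), toy_design(2)), "3 complete pairs")
})

test_that("storey q-values reduce to BH with pi0 = 1 and estimate pi0 well", {
  ## hand-derived BH arithmetic
  st <- storey_qvalues(c(0.01, 0.02, 0.9), pi0 = 1)
  expect_equal(st$qvalues, c(0.03, 0.03, 0.9), tolerance = 1e-12)
  ## all p = 1
  st1 <- storey_qvalues(rep(1, 5))
  expect_equal(st1$pi0, 1, tolerance = 1e-6)
  expect_equal(st1$qvalues, rep(1, 5))
  ## equality with p.adjust under pinned pi0 on random input
  set.seed(3)
  p <- runif(2000)^1.5
  expect_equal(storey_qvalues(p, pi0 = 1)$qvalues,
               p.adjust(p, method = "BH"), tolerance = 1e-12)
  ## uniform null: pi0 close to 1
  set.seed(4)
  expect_true(abs(storey_qvalues(runif(1e4))$pi0 - 1) < 0.1)
  expect_equal(length(storey_qvalues(numeric(0))$qvalues), 0)
  expect_error(storey_qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("variance explained by age matches its construction", {
  set.seed(5)
  design <- toy_design(40)
  ## y fully determined by age
  expect_equal(variance_explained_by_age(design$age01 * 2 + 5, design),
               1, tolerance = 1e-10)
  ## age label shuffled within pairs: near zero on average
  ve_null <- replicate(30, {
    y <- rep(rnorm(40), each = 2) + rnorm(80)
    variance_explained_by_age(y, design)
  })
  expect_lt(mean(ve_null), 0.05)
  ## planted variance share: within-pair age signal of known proportion
  ## after within-pair centering, age contributes delta^2/4 of variance, so
  ## delta = 2 sqrt(s * v_noise / (1 - s)) plants share s
  ve <- replicate(50, {
    noise <- rnorm(80)
    nc <- noise - ave(noise, design$individual_id)
    delta <- 2 * sqrt(0.1 / 0.9) * sd(nc)
    y <- rep(rnorm(40), each = 2) + design$age01 * delta + noise
    variance_explained_by_age(y, design)
  })
  expect_lt(abs(mean(ve) - 0.1), 3 * sd(ve) / sqrt(length(ve)) + 0.02)
})

test_that("trajectory outlier fences follow the quantile/IQR rule", {
  design <- toy_design(10)
  mk <- function(deltas) {
    y70 <- sample(-20:20, 10, replace = TRUE) / 4  # exactly representable
    m <- rbind(g = as.numeric(rbind(y70, y70 + deltas)))
    colnames(m) <- design$sample_id
    m
  }
  deltas <- c(1:9, 100)
  out <- detect_trajectory_outliers(mk(deltas), design)
  expect_equal(nrow(out), 1)
  expect_equal(out$delta, 100)
  expect_equal(out$fence_high, 7.75 + 3 * 4.5)  # Q3 + 3 IQR = 21.25
  expect_equal(out$fence_low, 3.25 - 3 * 4.5)
  expect_equal(out$extremeness, 100 - 21.25)
  ## all deltas equal: fences collapse, no outliers
  expect_equal(nrow(detect_trajectory_outliers(mk(rep(2, 10)), design)), 0)
  ## translation invariance
  out2 <- detect_trajectory_outliers(mk(deltas + 7), design)
  expect_equal(out2$delta - 7, out$delta)
  expect_equal(out2$fence_high - 7, out$fence_high)
  expect_error(detect_trajectory_outliers(mk(deltas), design,
                                          individuals = sprintf("i%02d", 1:5)),
               "10 individuals")
})

test_that("outlier flags agree with a brute-force oracle and are affine-invariant", {
  set.seed(6)
  design <- toy_design(15)
  for (i in 1:100) {
    ## quarter-grid values are exactly representable, so the recovered
    ## deltas equal the planted ones bit-for-bit (incl. the degenerate case)
    deltas <- round(rnorm(15) * sample(c(1, 10), 15, replace = TRUE,
                                       prob = c(0.9, 0.1)) * 4) / 4
    if (i %% 10 == 0) deltas <- rep(deltas[1], 15)  # degenerate case
    y70 <- sample(-20:20, 15, replace = TRUE) / 4
    m <- rbind(g = as.numeric(rbind(y70, y70 + deltas)))
    colnames(m) <- design$sample_id
    out <- detect_trajectory_outliers(m, design)
    q <- quantile(deltas, c(0.25, 0.75), type = 7, names = FALSE)
    fl <- deltas < q[1] - 3 * diff(q) | deltas > q[2] + 3 * diff(q)
    expect_setequal(out$individual_id, unique(design$individual_id)[fl])
    ## affine transform of the expression leaves flags unchanged
    out_a <- detect_trajectory_outliers(2.5 * m + 3, design)
    expect_identical(out_a$individual_id, out$individual_id)
  }
})

test_that("de_scan recovers planted effects and controls the FDR", {
  co <- small_cohort()
  nm <- normalize_counts(co$counts,
                         filter_expressed_genes(co$counts, co$design))
  de <- de_scan(nm$normalized, co$design, NULL)
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))
  expect_true(all(diff(de$q_value[order(de$p_value)]) >= -1e-12))
  expect_true(all(de$satterthwaite_df > 0))
  ## a strongly planted gene set: power at 2-SD effects
  set.seed(7)
  cfg <- sim_config(n_genes = 50, frac_de_genes = 0.2, de_effect_sd = 1,
                    ase_sites = 1, n_clusters = 2, seed = 8)
  co2 <- simulate_cohort(cfg)
  nm2 <- normalize_counts(co2$counts,
                          filter_expressed_genes(co2$counts, co2$design))
  de2 <- de_scan(nm2$normalized, co2$design, NULL)
  hit <- co2$truth$de$gene_id %in% de2$gene[de2$significant]
  expect_gte(mean(hit), 0.8)
})
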