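mk_ase <- function(site, ind, ref70, alt70, ref80, alt80) {
  data.frame(site_id = site, contig = "chr1", position = 1L, ref = "A",
             alt = "G", individual_id = rep(ind, 2),
             age = rep(c(70, 80), each = length(ind)),
             age01 = rep(c(0, 1), each = length(ind)),
             ref_count = c(ref70, ref80), alt_count = c(alt70, alt80),
             stringsAsFactors = FALSE)
}

test_that("ASE filters apply the proportion and depth rules per mode", {
  tab <- rbind(
    mk_ase("s1", "i1", 60, 60, 55, 65),     # deep, balanced-ish: passes all
    mk_ase("s2", "i2", 114, 6, 60, 60),     # pi = 0.95 at age 70: base fail
    mk_ase("s3", "i3", 50, 49, 60, 60),     # 99 reads at age 70
    mk_ase("s4", "i4", 30, 30, 35, 35))     # 60/70 reads
  g <- filter_ase_sites(tab, "global")
  expect_setequal(unique(g$site_id), "s1")
  ind <- filter_ase_sites(tab, "individual")
  expect_setequal(unique(ind$site_id), c("s1", "s3", "s4"))
  ## population: s1 het in only 1 individual -> excluded at default 20
  expect_equal(nrow(filter_ase_sites(tab, "population")), 0)
  pop19 <- filter_ase_sites(do.call(rbind, lapply(1:19, function(i)
    mk_ase("s9", sprintf("i%02d", i), 15, 10, 12, 13))), "population")
  expect_equal(nrow(pop19), 0)
  pop20 <- filter_ase_sites(do.call(rbind, lapply(1:20, function(i)
    mk_ase("s9", sprintf("i%02d", i), 15, 10, 12, 13))), "population")
  expect_equal(length(unique(pop20$individual_id)), 20)
  expect_error(filter_ase_sites(tab, "nope"))
})

test_that("allelic imbalance arithmetic and the AI ratio are exact", {
  tab <- filter_ase_sites(mk_ase("s1", "i1", 60, 60, 90, 30), "global")
  expect_equal(tab$pi, c(0.5, 0.75))
  expect_equal(tab$phi, c(0, 0.25))
  ## medians 0.100 at 70 and 0.103 at 80 give ratio 1.03
  ai <- data.frame(individual_id = "i1", phi_70 = 0.100, phi_80 = 0.103)
  ai$ratio <- ai$phi_80 / ai$phi_70
  expect_equal(ai$ratio, 1.03)
})

test_that("global AI test matches sign-pattern enumeration", {
  ai <- list(ai = data.frame(ratio = c(1.01, 1.2, 1.05, 1.4, 1.1, 1.3)),
             mu = 1.15)
  expect_equal(global_ai_test(ai)$p_value, 1 / 64, tolerance = 1e-12)
  ai1 <- list(ai = data.frame(ratio = rep(1, 6)), mu = 1)
  expect_equal(global_ai_test(ai1)$p_value, 1)
  expect_error(global_ai_test(list(ai = data.frame(ratio = 1.2))),
               "2 individuals")
})

test_that("latent-phase BB likelihood is phase-symmetric and reaches the binomial limit", {
  y <- c(30, 70); n <- c(100, 100); age <- c(0, 1)
  fa <- fit_bb_phase_model(y, n, age, "alt")
  fs <- fit_bb_phase_model(n - y, n, age, "alt")
  expect_equal(fa$loglik, fs$loglik, tolerance = 1e-10)
  ## balanced counts: effect near zero, LRT near zero
  fb <- fit_bb_phase_model(c(50, 50), c(100, 100), age, "alt")
  f0 <- fit_bb_phase_model(c(50, 50), c(100, 100), age, "null")
  expect_lt(abs(2 * (fb$loglik - f0$loglik)), 0.05)
  ## c -> infinity: beta-binomial equals binomial log-density
  p <- logistic(0.8)
  ll_bb <- dbetabinom_log(35, 60, p, 1e8)
  expect_equal(ll_bb, dbinom(35, 60, p, log = TRUE), tolerance = 1e-6)
  yy <- c(12, 40, 3); nn <- c(30, 80, 10)
  expect_equal(dbetabinom_log(yy, nn, 0.45, 1e8),
               dbinom(yy, nn, 0.45, log = TRUE), tolerance = 1e-6)
})

test_that("population model ELBO is monotone and phase-symmetric", {
  set.seed(1)
  I <- 12
  n <- matrix(rpois(2 * I, 60) + 20, I, 2)
  phi <- sample(c(-1, 1), I, TRUE)
  y <- cbind(longage:::rbetabinom(I, n[, 1], logistic(phi * 0.7), 40),
             longage:::rbetabinom(I, n[, 2], logistic(phi * 1.1), 40))
  long <- data.frame(y = as.numeric(y), n = as.numeric(n),
                     age01 = rep(c(0, 1), each = I),
                     ind = rep(sprintf("i%02d", 1:I), 2))
  fit <- fit_bb_phase_mixed(long$y, long$n, long$age01, long$ind, "alt")
  expect_true(all(diff(fit$elbo_trace) >= -1e-9))
  ## ref/alt relabeling leaves the fit invariant
  fit2 <- fit_bb_phase_mixed(long$n - long$y, long$n, long$age01,
                             long$ind, "alt")
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-6)
})

test_that("VB evidence stays within half a nat of a quadrature oracle", {
  ## oracle: exact sum over phases, Gauss-Hermite integration over u
  oracle_ll <- function(y, n, age01, ind, fit, K = 60) {
    gh <- pracma::gaussHermite(K)
    w <- gh$w / sqrt(pi)
    u <- sqrt(2 * fit$v) * gh$x
    tot <- longage:::log_prior_c(fit$c)
    for (i in unique(ind)) {
      ii <- ind == i
      li <- vapply(seq_along(u), function(k) {
        lp <- log(fit$pi_phase) +
          longage:::bb_ll_phase(y[ii], n[ii], age01[ii], +1, fit$b0,
                                fit$b1, fit$c, u[k])
        lm <- log(1 - fit$pi_phase) +
          longage:::bb_ll_phase(y[ii], n[ii], age01[ii], -1, fit$b0,
                                fit$b1, fit$c, u[k])
        m <- max(lp, lm)
        m + log(exp(lp - m) + exp(lm - m))
      }, numeric(1))
      m <- max(li)
      tot <- tot + m + log(sum(w * exp(li - m)))
    }
    tot
  }
  set.seed(2)
  gaps <- replicate(20, {
    I <- sample(3:6, 1)
    n <- matrix(sample(10:30, 2 * I, TRUE), I, 2)
    phi <- sample(c(-1, 1), I, TRUE)
    u <- rnorm(I, sd = 0.3)
    y <- cbind(longage:::rbetabinom(I, n[, 1],
                                    logistic(phi * 0.6 + u), 30),
               longage:::rbetabinom(I, n[, 2],
                                    logistic(phi * 0.9 + u), 30))
    long <- data.frame(y = as.numeric(y), n = as.numeric(n),
                       age01 = rep(c(0, 1), each = I),
                       ind = rep(sprintf("i%02d", 1:I), 2))
    fit <- fit_bb_phase_mixed(long$y, long$n, long$age01, long$ind, "alt")
    oracle_ll(long$y, long$n, long$age01, long$ind, fit) - fit$loglik
  })
  expect_true(all(gaps >= -1e-3))   # ELBO is a lower bound
  expect_true(all(gaps <= 0.5))     # and a tight one on small instances
})

test_that("the random effect collapses onto the fixed-effect model as v -> 0", {
  set.seed(3)
  I <- 15
  n <- matrix(sample(40:80, 2 * I, TRUE), I, 2)
  phi <- sample(c(-1, 1), I, TRUE)
  y <- cbind(longage:::rbetabinom(I, n[, 1], logistic(phi * 0.8), 60),
             longage:::rbetabinom(I, n[, 2], logistic(phi * 0.8), 60))
  long <- data.frame(y = as.numeric(y), n = as.numeric(n),
                     age01 = rep(c(0, 1), each = I),
                     ind = rep(sprintf("i%02d", 1:I), 2))
  fm <- fit_bb_phase_mixed(long$y, long$n, long$age01, long$ind, "null")
  ff <- fit_bb_phase_mixed(long$y, long$n, long$age01, long$ind, "null",
                           random_effect = FALSE)
  expect_lt(abs(ff$loglik - fm$loglik) / length(long$y), 1e-3 + 0.02)
})

test_that("differential ASE scan handles empty input and recovers planted sites", {
  empty <- filter_ase_sites(mk_ase("s", "i", 5, 5, 5, 5), "global")
  expect_equal(nrow(differential_ase_scan(empty[0, ], "population")), 0)
  ## planted individual-level differential signal: each site heterozygous
  ## in 20 individuals (so the pooled concentration is informative), one
  ## individual of one site shifts strongly with age (but stays inside
  ## the [0.1, 0.9] base filter)
  set.seed(4)
  inds <- sprintf("i%02d", 1:20)
  mk_site <- function(site, shift_ind = NULL) {
    phi <- sample(c(-1, 1), 20, TRUE)
    p <- logistic(phi * 0.4)
    p80 <- p
    if (!is.null(shift_ind)) p80[shift_ind] <- logistic(phi[shift_ind] * 1.6)
    n1 <- rpois(20, 200) + 50; n2 <- rpois(20, 200) + 50
    y1 <- longage:::rbetabinom(20, n1, p, 80)
    y2 <- longage:::rbetabinom(20, n2, p80, 80)
    mk_ase(site, inds, n1 - y1, y1, n2 - y2, y2)
  }
  tabs <- lapply(sprintf("n%02d", 1:4), mk_site)
  tabs$sig <- mk_site("sig", shift_ind = 1)
  tab <- filter_ase_sites(do.call(rbind, tabs), "individual")
  scan <- differential_ase_scan(tab, "individual")
  top <- scan[which.min(scan$p_value), ]
  expect_equal(top$site_id, "sig")
  expect_equal(top$individual_id, "i01")
  expect_lt(top$p_value, 0.01)
  expect_true(all(scan$p_value >= 0 & scan$p_value <= 1))
})
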