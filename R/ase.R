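## ASE site filtering, global allelic-imbalance statistics, and latent-phase
## beta-binomial (mixed) models for differential ASE with age.
##
## Model: for heterozygous individual i at age t, the alt-allele count is
##   y_it ~ BetaBinomial(n_it, sigma(phi_i * beta_t [+ u_i]), c)
## where phi_i in {-1, +1} is the latent phase between the causal cis variant
## and the measured exonic site, beta_t a logit-scale age-specific effect
## (parametrized beta_t = b0 + b1 * 1[t = age80]), c the beta-binomial
## concentration (MAP-estimated under a Gamma(1.0001, 1e-4) prior), and, in
## the population model, u_i ~ N(0, v) a per-individual random effect
## integrated out by variational Bayes EM.

GAMMA_C_SHAPE <- 1.0001
GAMMA_C_RATE <- 1e-4

log_prior_c <- function(c) (GAMMA_C_SHAPE - 1) * log(c) - GAMMA_C_RATE * c

#' Filter ASE sites for a given analysis mode
#'
#' Base filter: records with reference-allele proportion within
#' `[0.1, 0.9]` (removal of mono-allelic / error-dominated sites).  Depth
#' filters, applied to each site-individual (both ages must pass):
#' `"global"`/`"correlation"` at least 100 reads per age; `"individual"` at
#' least 50; `"population"` at least 20, and the site must be heterozygous
#' in at least `min_individuals` (20) qualifying individuals.
#'
#' @param ase long ASE table (site_id, individual_id, age01, ref_count,
#'   alt_count).
#' @param mode one of `"global"`, `"correlation"`, `"individual"`,
#'   `"population"`.
#' @param min_individuals population-mode minimum qualifying heterozygous
#'   individuals (default 20).
#' @return filtered table with added columns `n` (total reads), `pi`
#'   (reference proportion), `phi` (allelic imbalance `|pi - 0.5|`).
#' @export
filter_ase_sites <- function(ase, mode = c("global", "correlation",
                                           "individual", "population"),
                             min_individuals = 20) {
  mode <- match.arg(mode)
  min_reads <- switch(mode, global = 100, correlation = 100,
                      individual = 50, population = 20)
  ase$n <- ase$ref_count + ase$alt_count
  ase$pi <- ifelse(ase$n > 0, ase$ref_count / ase$n, NA_real_)
  ase$phi <- abs(ase$pi - 0.5)
  ase <- ase[!is.na(ase$pi) & ase$pi >= 0.1 & ase$pi <= 0.9, , drop = FALSE]
  key <- paste(ase$site_id, ase$individual_id)
  deep <- ase$n >= min_reads
  ## both ages of a site-individual must pass the depth rule
  ok_pair <- tapply(deep, key, function(x) length(x) == 2 && all(x))
  ase <- ase[ok_pair[key] %in% TRUE, , drop = FALSE]
  if (mode == "population") {
    n_ind <- tapply(ase$individual_id, ase$site_id,
                    function(x) length(unique(x)))
    keep_sites <- names(n_ind)[n_ind >= min_individuals]
    ase <- ase[ase$site_id %in% keep_sites, , drop = FALSE]
  }
  attr(ase, "mode") <- mode
  ase
}

#' Per-individual global allelic-imbalance summary
#'
#' For each individual, the per-age median allelic imbalance `phi` across
#' qualifying sites and the ratio `phi(age80) / phi(age70)`; plus the
#' cohort-level Spearman correlation of reference proportions across
#' age-paired site observations.
#'
#' @param ase table filtered in `"global"` mode.
#' @return list: `ai` (data.frame individual_id, phi_70, phi_80, ratio),
#'   `spearman_pi`, `mu` (cohort median ratio), `n_excluded` (individuals
#'   without defined ratios).
#' @export
global_ai_stats <- function(ase) {
  med <- stats::aggregate(phi ~ individual_id + age01, data = ase,
                          FUN = stats::median)
  wide <- merge(med[med$age01 == 0, c("individual_id", "phi")],
                med[med$age01 == 1, c("individual_id", "phi")],
                by = "individual_id", suffixes = c("_70", "_80"))
  wide$ratio <- ifelse(wide$phi_70 > 0, wide$phi_80 / wide$phi_70, NA_real_)
  n_exc <- sum(is.na(wide$ratio))
  ## pair pi across ages within site-individual
  key <- paste(ase$site_id, ase$individual_id)
  a0 <- ase[ase$age01 == 0, ]; a1 <- ase[ase$age01 == 1, ]
  mm <- merge(data.frame(key = paste(a0$site_id, a0$individual_id),
                         pi70 = a0$pi),
              data.frame(key = paste(a1$site_id, a1$individual_id),
                         pi80 = a1$pi), by = "key")
  rho <- if (nrow(mm) >= 3)
    stats::cor(mm$pi70, mm$pi80, method = "spearman") else NA_real_
  list(ai = wide[!is.na(wide$ratio), , drop = FALSE], spearman_pi = rho,
       mu = stats::median(wide$ratio, na.rm = TRUE), n_excluded = n_exc)
}

#' One-sided test for a global increase in allelic imbalance with age
#'
#' One-sample Wilcoxon signed-rank test of `log(ratio)` against 0
#' (equivalently of the AI ratios against 1), alternative "greater".
#'
#' @param ai_summary output of [global_ai_stats()].
#' @return list: `p_value`, `statistic`, `n`, `mu`.
#' @export
global_ai_test <- function(ai_summary) {
  r <- ai_summary$ai$ratio
  r <- r[is.finite(r) & r > 0]
  if (length(r) < 2) stop("need at least 2 individuals with defined ratios")
  lr <- log(r)
  wt <- paired_wilcoxon(lr, alternative = "greater")
  list(p_value = wt$p_value, statistic = wt$statistic,
       n = length(r), mu = ai_summary$mu)
}

## Sum of beta-binomial log-likelihood terms for one phase value.
## beta_t = b0 + b1 * age01; mean = sigma(phi * beta_t + u)
bb_ll_phase <- function(y, n, age01, phi, b0, b1, c, u = 0) {
  p <- logistic(phi * (b0 + b1 * age01) + u)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(dbetabinom_log(y, n, p, c))
}

#' Latent-phase beta-binomial model for one individual-site
#'
#' Marginal likelihood sums over the phase `phi in {-1, +1}` with prior
#' `pi_phase`; the alternative model frees the age effect (`b1`), the null
#' constrains `b1 = 0`.  The concentration `c` is MAP-estimated under a
#' Gamma(1.0001, 1e-4) prior.
#'
#' @param y,n alt counts and total depths (vectors over observations).
#' @param age01 0/1 age per observation.
#' @param model `"alt"` or `"null"`.
#' @param pi_phase prior probability of phase +1 (default 0.5).
#' @param c_fixed optionally hold the concentration fixed (e.g. at a
#'   per-site estimate pooled across individuals, as the differential scan
#'   does); when `NULL` it is MAP-estimated from this unit alone.
#' @return list of class `longage_bb`: `b0`, `b1`, `c`, `loglik`
#'   (MAP-penalized marginal log-likelihood), `pi_phase`, `convergence`.
#' @export
fit_bb_phase_model <- function(y, n, age01, model = c("alt", "null"),
                               pi_phase = 0.5, c_fixed = NULL) {
  model <- match.arg(model)
  stopifnot(length(y) == length(n), length(age01) == length(y))
  if (any(n == 0)) stop("zero-depth observation")
  free_c <- is.null(c_fixed)
  obj <- function(par) {
    b0 <- par[1]
    b1 <- if (model == "alt") par[2] else 0
    c <- if (free_c) exp(par[[length(par)]]) else c_fixed
    lp <- c(log(pi_phase) + bb_ll_phase(y, n, age01, +1, b0, b1, c),
            log(1 - pi_phase) + bb_ll_phase(y, n, age01, -1, b0, b1, c))
    m <- max(lp)
    -(m + log(sum(exp(lp - m))) + if (free_c) log_prior_c(c) else 0)
  }
  lg <- function(p) logit(pmin(pmax(p, 0.02), 0.98))
  p70 <- mean(y[age01 == 0] / n[age01 == 0])
  p80 <- mean(y[age01 == 1] / n[age01 == 1])
  ## the likelihood is multimodal (phase/overdispersion trade-off): start
  ## from the per-age empirical logits, from balance, and from the pooled
  ## mean, keep the best optimum
  starts <- if (model == "alt")
    list(c(lg(p70), lg(p80) - lg(p70), log(50)),
         c(0.1, 0, log(50)),
         c(lg(mean(y / n)), 0, log(500)))
  else list(c(lg(mean(y / n)), log(50)), c(0.1, log(50)),
            c(lg(mean(y / n)), log(500)))
  if (!free_c) starts <- lapply(starts, function(s) s[-length(s)])
  best <- NULL
  for (s in starts) {
    op <- tryCatch(stats::optim(s, obj, method = "BFGS",
                                control = list(maxit = 500,
                                               reltol = 1e-12)),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  op <- best
  structure(list(b0 = op$par[1],
                 b1 = if (model == "alt") op$par[2] else 0,
                 c = if (free_c) exp(op$par[length(op$par)]) else c_fixed,
                 loglik = -op$value,
                 pi_phase = pi_phase, convergence = op$convergence == 0),
            class = "longage_bb")
}

#' @export
print.longage_bb <- function(x, ...) {
  cat(sprintf("BB phase model: b0 = %.3f, b1 = %.3f, c = %.1f, ll = %.3f\n",
              x$b0, x$b1, x$c, x$loglik))
  invisible(x)
}

## Gauss-Hermite machinery for E_{u ~ N(m, s^2)} [ log BB(...) ] terms,
## by fixed-node quadrature u = m + sqrt(2) s x_k, vectorized over all
## observations and nodes at once.
gh_cache <- new.env(parent = emptyenv())
gh_nodes <- function(k = 20) {
  key <- as.character(k)
  if (is.null(gh_cache[[key]])) {
    gh <- pracma::gaussHermite(k)
    gh_cache[[key]] <- list(x = gh$x, w = gh$w / sqrt(pi))
  }
  gh_cache[[key]]
}

## Per-individual expected log-likelihood under both phases.
## y, n, age01: observation vectors; ind: 1-based individual index per
## observation; m, s: variational means/sds per individual.
## Returns an I x 2 matrix (columns: phi = +1, phi = -1).
bb_e_parts <- function(y, n, age01, ind, b0, b1, c, m, s, gh) {
  K <- length(gh$x)
  N <- length(y)
  U <- outer(m[ind], rep(1, K)) +
    sqrt(2) * outer(s[ind], gh$x)           # N x K
  eta <- b0 + b1 * age01                     # N
  lch <- lchoose(n, y)
  out <- matrix(0, max(ind), 2)
  for (col in 1:2) {
    phi <- c(1, -1)[col]
    P <- logistic(phi * eta + U)
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    A <- P * c; B <- (1 - P) * c
    LL <- lch + lbeta(y + A, n - y + B) - lbeta(A, B)   # N x K
    out[, col] <- rowsum(as.numeric(LL %*% gh$w), ind)
  }
  out
}

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Population latent-phase beta-binomial mixed model for one site
#'
#' `y_it ~ BB(n_it, sigma(phi_i beta_t + u_i), c)` with `u_i ~ N(0, v)`.
#' Gaussian variational posteriors per `u_i` and a discrete posterior per
#' phase `phi_i` are alternated with M-steps for `beta_t`, the phase prior
#' `pi`, `v`, and MAP `c`; every update maximizes the same evidence lower
#' bound (ELBO), which is therefore non-decreasing across iterations.  With
#' `random_effect = FALSE` the exact fixed-effect marginal likelihood is
#' maximized instead.
#'
#' @param y,n alt counts and depths (long vectors over individual-age
#'   observations).
#' @param age01 0/1 age per observation.
#' @param individual individual id per observation.
#' @param model `"alt"` (age effect free) or `"null"` (`b1 = 0`).
#' @param random_effect include the per-individual random effect (default
#'   TRUE).
#' @param max_iter,tol EM iteration cap and ELBO convergence tolerance.
#' @param n_gh number of Gauss-Hermite nodes.
#' @return list of class `longage_bb_mixed`: `b0`, `b1`, `pi_phase`, `v`,
#'   `c`, `loglik` (final ELBO, or exact marginal when
#'   `random_effect = FALSE`), `elbo_trace`, `q_phase`, `u_mean`, `u_sd`,
#'   `converged`.
#' @export
fit_bb_phase_mixed <- function(y, n, age01, individual,
                               model = c("alt", "null"),
                               random_effect = TRUE,
                               max_iter = 500, tol = 1e-8, n_gh = 20) {
  model <- match.arg(model)
  individual <- as.character(individual)
  ids <- unique(individual)
  I <- length(ids)
  idx <- split(seq_along(y), factor(individual, levels = ids))

  if (!random_effect) {
    ## exact marginal likelihood: product over individuals of the
    ## phase-summed BB likelihood, with shared b0, b1, pi, c
    ind <- match(individual, ids)
    lch <- lchoose(n, y)
    obj <- function(par) {
      b0 <- par[1]; b1 <- if (model == "alt") par[2] else 0
      pp <- logistic(par[length(par) - 1]); c <- exp(par[length(par)])
      eta <- b0 + b1 * age01
      lli <- matrix(vapply(c(1, -1), function(phi) {
        p <- pmin(pmax(logistic(phi * eta), 1e-12), 1 - 1e-12)
        a <- p * c; b <- (1 - p) * c
        rowsum(lch + lbeta(y + a, n - y + b) - lbeta(a, b), ind)[, 1]
      }, numeric(I)), ncol = 2)
      lp <- cbind(log(pp) + lli[, 1], log(1 - pp) + lli[, 2])
      m <- pmax(lp[, 1], lp[, 2])
      -(sum(m + log(exp(lp[, 1] - m) + exp(lp[, 2] - m))) +
          log_prior_c(c))
    }
    start <- if (model == "alt") c(0.5, 0, 0, log(50)) else c(0.5, 0, log(50))
    op <- stats::optim(start, obj, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-12))
    np <- length(op$par)
    return(structure(list(
      b0 = op$par[1], b1 = if (model == "alt") op$par[2] else 0,
      pi_phase = logistic(op$par[np - 1]), v = 0, c = exp(op$par[np]),
      loglik = -op$value, elbo_trace = -op$value, q_phase = NULL,
      u_mean = NULL, u_sd = NULL, converged = op$convergence == 0),
      class = "longage_bb_mixed"))
  }

  gh <- gh_nodes(n_gh)
  ind <- match(individual, ids)
  ## state; |effect| scale for b0 (the sign is carried by the phase)
  p70 <- stats::weighted.mean(y[age01 == 0] / n[age01 == 0],
                              n[age01 == 0])
  p80 <- stats::weighted.mean(y[age01 == 1] / n[age01 == 1],
                              n[age01 == 1])
  lg <- function(p) logit(pmin(pmax(p, 0.05), 0.95))
  b0 <- abs(lg(p70)) + 0.05
  b1 <- if (model == "alt") abs(lg(p80)) - abs(lg(p70)) else 0
  pp <- 0.5; v <- 0.1; cc <- 50
  q <- rep(0.5, I)
  m_u <- rep(0, I); s_u <- rep(sqrt(v) / 2, I)

  parts <- function(b0., b1., c., m., s.)
    bb_e_parts(y, n, age01, ind, b0., b1., c., m., s., gh)

  ## per-individual variational local objective (the parts of the ELBO
  ## that depend on (m_i, s_i)); separable across individuals
  local_obj <- function(m., s.) {
    g <- parts(b0, b1, cc, m., s.)
    q * g[, 1] + (1 - q) * g[, 2] - (m.^2 + s.^2) / (2 * v) + log(s.)
  }

  elbo_fun <- function() {
    g <- parts(b0, b1, cc, m_u, s_u)
    sum(q * g[, 1] + (1 - q) * g[, 2]) +
      sum(-0.5 * log(2 * pi * v) - (m_u^2 + s_u^2) / (2 * v)) +
      sum(0.5 * log(2 * pi * exp(1) * s_u^2)) +
      sum(q * log(pp) + (1 - q) * log(1 - pp) -
            xlogx(q) - xlogx(1 - q)) +
      log_prior_c(cc)
  }

  elbo <- elbo_fun()
  trace <- elbo
  for (iter in seq_len(max_iter)) {
    ## E-step: phases (exact coordinate update)
    g <- parts(b0, b1, cc, m_u, s_u)
    q <- 1 / (1 + exp((log(1 - pp) + g[, 2]) - (log(pp) + g[, 1])))
    q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
    ## E-step: Gaussian posteriors; joint gradient-ascent sweeps with
    ## per-individual acceptance (the objective is separable, so keeping
    ## only improving coordinates never decreases the ELBO)
    t_u <- log(s_u)
    for (sweep in 1:3) {
      cur <- local_obj(m_u, exp(t_u))
      d <- 1e-5
      gm <- (local_obj(m_u + d, exp(t_u)) -
               local_obj(m_u - d, exp(t_u))) / (2 * d)
      gt <- (local_obj(m_u, exp(t_u + d)) -
               local_obj(m_u, exp(t_u - d))) / (2 * d)
      step <- 0.5
      improved <- rep(FALSE, I)
      for (half in 1:6) {
        mm <- ifelse(improved, m_u, m_u + step * gm / (1 + abs(gm)))
        tt <- ifelse(improved, t_u, t_u + step * gt / (1 + abs(gt)))
        new <- local_obj(mm, exp(tt))
        take <- !improved & new > cur
        m_u[take] <- mm[take]; t_u[take] <- tt[take]
        cur[take] <- new[take]
        improved <- improved | take
        if (all(improved)) break
        step <- step / 2
      }
    }
    s_u <- exp(t_u)
    ## M-step: pi and v (closed-form exact maximizers of the ELBO)
    pp <- min(max(mean(q), 1e-6), 1 - 1e-6)
    v <- max(mean(m_u^2 + s_u^2), 1e-8)
    ## M-step: beta and c (accept-if-improve)
    mob <- function(par) {
      b0. <- par[1]; b1. <- if (model == "alt") par[2] else 0
      c. <- exp(par[length(par)])
      g <- bb_e_parts(y, n, age01, ind, b0., b1., c., m_u, s_u, gh)
      -(sum(q * g[, 1] + (1 - q) * g[, 2]) + log_prior_c(c.))
    }
    start <- if (model == "alt") c(b0, b1, log(cc)) else c(b0, log(cc))
    cur <- mob(start)
    op <- stats::optim(start, mob, method = "BFGS",
                       control = list(maxit = 40))
    if (op$value < cur) {
      b0 <- op$par[1]
      if (model == "alt") b1 <- op$par[2]
      cc <- exp(op$par[length(op$par)])
    }
    new_elbo <- elbo_fun()
    trace <- c(trace, new_elbo)
    if (abs(new_elbo - elbo) < tol) { elbo <- new_elbo; break }
    elbo <- new_elbo
  }
  structure(list(b0 = b0, b1 = b1, pi_phase = pp, v = v, c = cc,
                 loglik = elbo, elbo_trace = trace,
                 q_phase = stats::setNames(q, ids),
                 u_mean = stats::setNames(m_u, ids),
                 u_sd = stats::setNames(s_u, ids),
                 converged = iter < max_iter),
            class = "longage_bb_mixed")
}

#' @export
print.longage_bb_mixed <- function(x, ...) {
  cat(sprintf(
    "BB phase mixed model: b0 = %.3f, b1 = %.3f, pi = %.2f, v = %.4f, c = %.1f, ELBO = %.3f\n",
    x$b0, x$b1, x$pi_phase, x$v, x$c, x$loglik))
  invisible(x)
}

#' Differential-ASE scan
#'
#' Fits the matching latent-phase model per unit (site at the population
#' level; site-individual at the individual level), collects likelihood
#' ratio p-values (chi-square, 1 df) and Storey q-values.
#'
#' @param ase table filtered in the matching mode.
#' @param level `"population"` or `"individual"`.
#' @param fdr significance threshold on q-values (default 0.05).
#' @param random_effect population level only: include the per-individual
#'   random effect via VB-EM (default TRUE).
#' @param adjust `"storey"` or `"BH"`.
#' @param max_iter,tol VB-EM iteration cap and ELBO tolerance used for the
#'   population-level fits (scan-level defaults trade a little convergence
#'   slack for throughput; see [fit_bb_phase_mixed()] for the fitter's own
#'   defaults).
#' @return data.frame: unit ids, `b1` (fitted age effect), `lrt`,
#'   `p_value`, `q_value`, `significant`.
#' @export
differential_ase_scan <- function(ase, level = c("population", "individual"),
                                  fdr = 0.05, random_effect = TRUE,
                                  adjust = c("storey", "BH"),
                                  max_iter = 200, tol = 1e-6) {
  level <- match.arg(level)
  adjust <- match.arg(adjust)
  empty <- data.frame(site_id = character(), p_value = numeric())
  if (nrow(ase) == 0) return(empty)
  if (level == "population") {
    rows <- lapply(split(ase, ase$site_id), function(d) {
      fa <- tryCatch(fit_bb_phase_mixed(d$alt_count, d$n, d$age01,
                                        d$individual_id, "alt",
                                        random_effect = random_effect,
                                        max_iter = max_iter, tol = tol),
                     error = function(e) NULL)
      f0 <- tryCatch(fit_bb_phase_mixed(d$alt_count, d$n, d$age01,
                                        d$individual_id, "null",
                                        random_effect = random_effect,
                                        max_iter = max_iter, tol = tol),
                     error = function(e) NULL)
      if (is.null(fa) || is.null(f0) || !fa$converged || !f0$converged)
        return(NULL)
      lrt <- max(2 * (fa$loglik - f0$loglik), 0)
      data.frame(site_id = d$site_id[1], b1 = fa$b1, lrt = lrt,
                 p_value = stats::pchisq(lrt, 1, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    })
  } else {
    ## the concentration is learned per site by pooling individuals (the
    ## 2-observation per-individual fit cannot identify it); each
    ## individual is tested with c held at the estimate pooled over the
    ## OTHER individuals, so its own (possibly differential) signal does
    ## not inflate the dispersion it is tested against
    pool_c <- function(d) tryCatch(
      fit_bb_phase_mixed(d$alt_count, d$n, d$age01, d$individual_id,
                         "null", random_effect = FALSE)$c,
      error = function(e) NA_real_)
    rows <- lapply(split(ase, ase$site_id), function(ds) {
      c_all <- pool_c(ds)
      lapply(split(ds, ds$individual_id), function(d) {
        if (length(unique(d$age01)) < 2) return(NULL)
        rest <- ds[ds$individual_id != d$individual_id[1], , drop = FALSE]
        cpool <- if (length(unique(rest$individual_id)) >= 2)
          pool_c(rest) else c_all
        if (!is.finite(cpool)) cpool <- c_all
        if (!is.finite(cpool)) return(NULL)
        fa <- tryCatch(fit_bb_phase_model(d$alt_count, d$n, d$age01,
                                          "alt", c_fixed = cpool),
                       error = function(e) NULL)
        f0 <- tryCatch(fit_bb_phase_model(d$alt_count, d$n, d$age01,
                                          "null", c_fixed = cpool),
                       error = function(e) NULL)
        if (is.null(fa) || is.null(f0)) return(NULL)
        lrt <- max(2 * (fa$loglik - f0$loglik), 0)
        data.frame(site_id = d$site_id[1],
                   individual_id = d$individual_id[1],
                   b1 = fa$b1, c = cpool, lrt = lrt,
                   p_value = stats::pchisq(lrt, 1, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
      })
    })
    rows <- unlist(rows, recursive = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res$q_value <- if (adjust == "storey") storey_qvalues(res$p_value)$qvalues
                 else stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value <= fdr
  res
}
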