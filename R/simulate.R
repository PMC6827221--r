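## Synthetic two-timepoint cohort generator.
##
## Emulates the data layers of a paired age-70/age-80 whole-blood RNA-seq
## study: gene-level counts with individual random effects, age effects,
## cis-genetic effects with high cross-age genetic correlation, hidden
## technical factors correlated with age (RIN / RNA-concentration analogues),
## beta-binomially overdispersed allele-specific counts with a latent phase,
## and Dirichlet-multinomial intron-usage counts grouped into clusters.

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by all generators.
#' Defaults reflect the study design the package targets: 65 individuals
#' sampled at ages 70 and 80, cis-heritabilities of 18%/17% with cross-age
#' genetic correlation 0.96, roughly 8% of genes differentially expressed,
#' hidden technical factors moderately (negatively) correlated with age, and a
#' 2.7% global inflation of allelic imbalance at the later age.
#'
#' @param n_individuals number of individuals (each sampled at both ages).
#' @param ages two age labels; the first is coded 0, the second 1.
#' @param n_genes number of genes.
#' @param n_snps_per_gene cis SNPs simulated per gene.
#' @param maf_range interval in (0, 0.5] from which SNP MAFs are drawn.
#' @param h2_by_age length-2 cis-heritability (fraction of latent expression
#'   variance) at each age, each in \[0, 1).
#' @param rho_g cross-age genetic correlation in \[-1, 1\].
#' @param frac_de_genes fraction of genes with a planted age effect.
#' @param de_effect_sd magnitude (log2 units) of planted age effects.
#' @param n_hidden_factors number of hidden technical factors.
#' @param factor_age_corr correlation of the first hidden factor with age
#'   (emulating RIN/concentration confounding).
#' @param ase_sites number of heterozygous exonic ASE sites.
#' @param ase_concentration beta-binomial concentration of allelic counts.
#' @param frac_diff_ase fraction of ASE sites with a planted age effect.
#' @param ase_diff_effect logit-scale age effect at differential-ASE sites.
#' @param ai_ratio multiplicative inflation of |logit effects| at the later
#'   age applied to all ASE sites (global allelic-imbalance drift; 1 = none).
#' @param n_clusters number of intron clusters.
#' @param introns_per_cluster integer range (length 2) of introns per cluster.
#' @param dm_concentration Dirichlet-multinomial concentration of intron
#'   counts around the cluster usage vector.
#' @param frac_ds_clusters fraction of clusters with a planted usage shift.
#' @param ds_effect logit-scale usage shift at differential-splicing clusters.
#' @param seed integer seed; identical configurations give bit-identical
#'   cohorts.
#' @return a validated list of class `longage_config`.
#' @export
sim_config <- function(n_individuals = 65,
                       ages = c(70, 80),
                       n_genes = 200,
                       n_snps_per_gene = 20,
                       maf_range = c(0.05, 0.5),
                       h2_by_age = c(0.18, 0.17),
                       rho_g = 0.96,
                       frac_de_genes = 0.08,
                       de_effect_sd = 0.5,
                       n_hidden_factors = 3,
                       factor_age_corr = -0.46,
                       ase_sites = 1500,
                       ase_concentration = 50,
                       frac_diff_ase = 0.01,
                       ase_diff_effect = 0.5,
                       ai_ratio = 1.027,
                       n_clusters = 100,
                       introns_per_cluster = c(2, 6),
                       dm_concentration = 30,
                       frac_ds_clusters = 0.05,
                       ds_effect = 0.8,
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals), ages = ages,
              n_genes = as.integer(n_genes),
              n_snps_per_gene = as.integer(n_snps_per_gene),
              maf_range = maf_range, h2_by_age = h2_by_age, rho_g = rho_g,
              frac_de_genes = frac_de_genes, de_effect_sd = de_effect_sd,
              n_hidden_factors = as.integer(n_hidden_factors),
              factor_age_corr = factor_age_corr,
              ase_sites = as.integer(ase_sites),
              ase_concentration = ase_concentration,
              frac_diff_ase = frac_diff_ase,
              ase_diff_effect = ase_diff_effect, ai_ratio = ai_ratio,
              n_clusters = as.integer(n_clusters),
              introns_per_cluster = as.integer(introns_per_cluster),
              dm_concentration = dm_concentration,
              frac_ds_clusters = frac_ds_clusters, ds_effect = ds_effect,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "longage_config")
}

validate_config <- function(cfg) {
  if (cfg$n_individuals < 2) stop_invalid("n_individuals must be >= 2")
  if (length(cfg$ages) != 2) stop_invalid("exactly two ages required")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop_invalid("maf_range must lie within (0, 0.5]")
  fr <- c(cfg$frac_de_genes, cfg$frac_diff_ase, cfg$frac_ds_clusters)
  if (any(fr < 0 | fr > 1)) stop_invalid("fractions must lie in [0, 1]")
  if (any(cfg$h2_by_age < 0 | cfg$h2_by_age >= 1))
    stop_invalid("h2_by_age components must lie in [0, 1)")
  if (abs(cfg$rho_g) > 1) stop_invalid("rho_g must lie in [-1, 1]")
  if (cfg$ase_concentration <= 0) stop_invalid("ase_concentration must be > 0")
  if (cfg$dm_concentration <= 0) stop_invalid("dm_concentration must be > 0")
  if (cfg$introns_per_cluster[1] < 2)
    stop_invalid("introns_per_cluster range must be >= 2")
  invisible(cfg)
}

#' @export
print.longage_config <- function(x, ...) {
  cat("longage simulation config:", x$n_individuals, "individuals x 2 ages,",
      x$n_genes, "genes,", x$ase_sites, "ASE sites,", x$n_clusters,
      "intron clusters (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Cohort design table
#'
#' @param config a [sim_config()] object.
#' @return data.frame with sample_id, individual_id, age label, age01 coding
#'   (0 = first age, 1 = second), and RIN / RNA-concentration covariates
#'   correlated with age.
#' @export
simulate_design <- function(config) {
  n <- config$n_individuals
  ind <- sprintf("ind%03d", seq_len(n))
  design <- data.frame(
    sample_id = paste0(rep(ind, each = 2), "_", rep(config$ages, n)),
    individual_id = rep(ind, each = 2),
    age = rep(config$ages, n),
    age01 = rep(c(0, 1), n),
    stringsAsFactors = FALSE)
  ## RIN and concentration drift down with age (observed correlations in
  ## elderly whole-blood cohorts are around -0.3 to -0.5)
  design$rin <- 8 - 0.8 * design$age01 + stats::rnorm(2 * n, sd = 0.8)
  design$rna_conc <- 60 - 10 * design$age01 + stats::rnorm(2 * n, sd = 15)
  design$sex <- rep(sample(c("F", "M"), n, replace = TRUE), each = 2)
  design
}

#' Simulate cis genotypes under Hardy-Weinberg equilibrium
#'
#' Each gene receives `n_snps_per_gene` SNPs with MAF drawn uniformly from
#' `maf_range`; monomorphic draws are re-sampled.  Positions are placed within
#' a 1 Mb window of the gene's TSS.
#'
#' @param config a [sim_config()] object.
#' @return list with `dosage` (SNPs x individuals matrix in 0/1/2), `snps`
#'   (SNP metadata: snp_id, chrom, pos, maf, gene_id), and `genes`
#'   (gene_id, chrom, tss).
#' @export
simulate_genotypes <- function(config) {
  validate_config(config)
  n <- config$n_individuals
  if (n < 2) stop_invalid("n_individuals must be >= 2")
  ng <- config$n_genes
  m <- config$n_snps_per_gene
  genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(ng)),
                      chrom = "chr1",
                      tss = seq(2e6, by = 3e6, length.out = ng))
  total <- ng * m
  maf <- stats::runif(total, config$maf_range[1], config$maf_range[2])
  dosage <- matrix(stats::rbinom(total * n, 2L, rep(maf, n)), nrow = total)
  ## re-sample monomorphic rows (possible at low MAF / small n)
  mono <- apply(dosage, 1, function(x) length(unique(x)) == 1)
  while (any(mono)) {
    idx <- which(mono)
    dosage[idx, ] <- stats::rbinom(length(idx) * n, 2L, rep(maf[idx], n))
    mono[idx] <- apply(dosage[idx, , drop = FALSE], 1,
                       function(x) length(unique(x)) == 1)
  }
  gene_of <- rep(genes$gene_id, each = m)
  pos <- rep(genes$tss, each = m) +
    round(stats::runif(total, -9e5, 9e5))
  snps <- data.frame(snp_id = sprintf("snp%06d", seq_len(total)),
                     chrom = "chr1", pos = pos, maf = maf,
                     gene_id = gene_of, stringsAsFactors = FALSE)
  rownames(dosage) <- snps$snp_id
  colnames(dosage) <- sprintf("ind%03d", seq_len(n))
  list(dosage = dosage, snps = snps, genes = genes)
}

scale_to_var <- function(x, v) {
  s <- stats::sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s * sqrt(v)
}

#' Simulate gene-level RNA-seq counts
#'
#' Latent log2 expression = individual random intercept + age effect (planted
#' differentially expressed genes) + cis-genetic value scaled to the target
#' per-age heritability with cross-age genetic correlation `rho_g` + hidden
#' factor contributions + noise.  Counts are negative-binomial draws around
#' `library_size * 2^latent` with lognormal gene-level dispersions.
#'
#' @param config a [sim_config()] object.
#' @param genotypes output of [simulate_genotypes()].
#' @param design output of [simulate_design()]; generated if `NULL`.
#' @return list with `counts` (genes x samples), `design`, `factors`
#'   (samples x hidden factors), and `truth` (planted DE genes and eQTLs and
#'   factor loadings).
#' @export
simulate_expression_counts <- function(config, genotypes, design = NULL) {
  validate_config(config)
  if (is.null(design)) design <- simulate_design(config)
  n <- config$n_individuals
  ng <- config$n_genes
  ns <- 2 * n
  age01 <- design$age01
  ind_idx <- match(design$individual_id, unique(design$individual_id))

  ## variance budget per gene (latent log2 scale, total 1)
  v_ind <- 0.30
  v_fact_total <- 0.10
  h2 <- config$h2_by_age
  if (any(h2 + v_ind + v_fact_total >= 1))
    stop_invalid("h2 plus individual and factor variance must be < 1")

  ## hidden factors (per sample); the first is correlated with age
  k <- config$n_hidden_factors
  factors <- matrix(stats::rnorm(ns * max(k, 1)), ns, max(k, 1))
  if (k >= 1) {
    r <- config$factor_age_corr
    a <- scale(age01)[, 1]
    factors[, 1] <- r * a + sqrt(1 - r^2) * scale(stats::rnorm(ns))[, 1]
  }
  factors <- factors[, seq_len(k), drop = FALSE]
  colnames(factors) <- if (k > 0) paste0("HF", seq_len(k)) else character()

  ## planted DE genes
  n_de <- round(config$frac_de_genes * ng)
  de_genes <- if (n_de > 0) sample(ng, n_de) else integer()
  delta <- numeric(ng)
  delta[de_genes] <- sample(c(-1, 1), n_de, replace = TRUE) *
    config$de_effect_sd

  ## cis-genetic values: a shared causal SNP (weight sqrt(rho)) plus
  ## age-specific causal SNPs (weight sqrt(1-rho)) give cross-age genetic
  ## correlation rho_g at the gene level
  rho <- max(config$rho_g, 0)
  m <- config$n_snps_per_gene
  geno <- genotypes$dosage
  counts <- matrix(0L, ng, ns,
                   dimnames = list(genotypes$genes$gene_id, design$sample_id))
  lib <- exp(stats::rnorm(ns, log(1), 0.15))  # relative library sizes
  disp <- exp(stats::rnorm(ng, log(0.1), 0.5))
  base <- stats::runif(ng, 4, 9)              # baseline log2 expression
  loadings <- if (k > 0)
    matrix(stats::rnorm(ng * k) * stats::rbinom(ng * k, 1, 0.3), ng, k)
  else matrix(0, ng, 0)

  ## per-gene cis-h2 heterogeneity: real cis-heritability is strongly
  ## right-skewed (most genes weakly heritable, a tail of strong eGenes);
  ## h2_by_age sets the cohort mean, a unit-mean gamma multiplier the shape
  h2_mult <- stats::rgamma(ng, shape = 1.2, rate = 1.2)
  truth_eqtl <- data.frame()
  causal_shared <- integer(ng)
  h2_gene <- matrix(0, ng, 2)
  for (g in seq_len(ng)) {
    rows <- (g - 1) * m + seq_len(m)
    cs <- rows[1]; c70 <- rows[min(2, m)]; c80 <- rows[min(3, m)]
    causal_shared[g] <- cs
    z_sh <- scale(geno[cs, ])[, 1]
    z_70 <- scale(geno[c70, ])[, 1]
    z_80 <- scale(geno[c80, ])[, 1]
    h2g <- pmin(h2 * h2_mult[g], 0.8)
    h2_gene[g, ] <- h2g
    g70 <- sqrt(h2g[1]) * (sqrt(rho) * z_sh + sqrt(1 - rho) * z_70)
    g80 <- sqrt(h2g[2]) * (sqrt(rho) * z_sh + sqrt(1 - rho) * z_80)
    u_i <- stats::rnorm(n, sd = sqrt(v_ind))
    fac <- if (k > 0) scale_to_var(factors %*% loadings[g, ], v_fact_total)
           else numeric(ns)
    v_noise <- 1 - v_ind - v_fact_total - mean(h2g)
    lat <- base[g] + u_i[ind_idx] + delta[g] * age01 + fac +
      ifelse(age01 == 0, g70[ind_idx], g80[ind_idx]) +
      stats::rnorm(ns, sd = sqrt(max(v_noise, 0.05)))
    mu <- lib * 2^lat / 2^mean(base) * 50   # scale to realistic depth
    counts[g, ] <- stats::rnbinom(ns, mu = mu, size = 1 / disp[g])
  }
  truth_de <- data.frame(gene_id = genotypes$genes$gene_id[de_genes],
                         effect_log2 = delta[de_genes],
                         stringsAsFactors = FALSE)
  truth_eqtl <- data.frame(
    gene_id = genotypes$genes$gene_id,
    snp_id = genotypes$snps$snp_id[causal_shared],
    h2_70 = h2_gene[, 1], h2_80 = h2_gene[, 2], rho_g = config$rho_g,
    stringsAsFactors = FALSE)
  list(counts = counts, design = design, factors = factors,
       truth = list(de = truth_de, eqtl = truth_eqtl, loadings = loadings))
}

#' Simulate allele-specific read counts with a latent phase
#'
#' For each heterozygous site/individual, a phase `phi_i` in {-1, +1} is drawn
#' with prior `pi = 0.5`; total depth is lognormal; the alternative-allele
#' count is beta-binomial with mean `logistic(phi_i * beta_t)` and
#' concentration `ase_concentration`.  Differential sites receive
#' `beta_80 = beta_70 + ase_diff_effect`; all sites' effect magnitudes at the
#' later age are additionally inflated by `ai_ratio` (global AI drift).
#'
#' @param config a [sim_config()] object.
#' @param design optional design table (for individual ids).
#' @return list with `ase` (long table: site_id, contig, position, ref, alt,
#'   individual_id, age, age01, ref_count, alt_count) and `truth`
#'   (differential sites with their effects).
#' @export
simulate_ase_counts <- function(config, design = NULL) {
  validate_config(config)
  if (config$ase_sites <= 0) stop_invalid("ase_sites must be > 0")
  if (is.null(design)) design <- simulate_design(config)
  n <- config$n_individuals
  inds <- unique(design$individual_id)
  ns <- config$ase_sites
  n_diff <- round(config$frac_diff_ase * ns)
  diff_sites <- if (n_diff > 0) sample(ns, n_diff) else integer()
  beta0 <- stats::rnorm(ns, 0, 0.5)           # baseline site effect (slab)
  d_eff <- numeric(ns)
  d_eff[diff_sites] <- sample(c(-1, 1), n_diff, replace = TRUE) *
    config$ase_diff_effect
  maf <- stats::runif(ns, 0.15, 0.5)
  het_p <- 2 * maf * (1 - maf)

  rows <- vector("list", ns)
  bases <- c("A", "C", "G", "T")
  for (s in seq_len(ns)) {
    het <- which(stats::runif(n) < pmax(het_p[s], 0.25))
    if (length(het) == 0) het <- sample(n, 1)
    phi <- sample(c(-1, 1), length(het), replace = TRUE)  # pi_phase = 0.5
    b70 <- beta0[s]
    b80 <- (beta0[s] + d_eff[s]) * config$ai_ratio
    ## depths: lognormal, truncated upward so filter rules have work to do
    n70 <- pmax(round(stats::rlnorm(length(het), log(120), 0.6)), 5)
    n80 <- pmax(round(stats::rlnorm(length(het), log(120), 0.6)), 5)
    c_bb <- config$ase_concentration
    y70 <- rbetabinom(length(het), n70, logistic(phi * b70), c_bb)
    y80 <- rbetabinom(length(het), n80, logistic(phi * b80), c_bb)
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    rows[[s]] <- data.frame(
      site_id = sprintf("site%05d", s), contig = "chr1", position = s * 1000L,
      ref = ref, alt = alt,
      individual_id = rep(inds[het], 2),
      age = rep(config$ages, each = length(het)),
      age01 = rep(c(0, 1), each = length(het)),
      ref_count = c(n70 - y70, n80 - y80),
      alt_count = c(y70, y80),
      stringsAsFactors = FALSE)
  }
  ase <- do.call(rbind, rows)
  truth <- data.frame(site_id = sprintf("site%05d", diff_sites),
                      effect_logit = d_eff[diff_sites],
                      stringsAsFactors = FALSE)
  list(ase = ase, truth = truth)
}

#' Simulate intron-junction counts grouped into clusters
#'
#' Per cluster and sample, intron counts are Dirichlet-multinomial around the
#' cluster usage vector with concentration `dm_concentration`; planted
#' differential-splicing clusters shift the first intron's usage on the logit
#' scale by `ds_effect` at the later age.  Cluster totals vary per sample.
#'
#' @param config a [sim_config()] object.
#' @param design optional design table.
#' @return list with `junctions` (introns x samples counts, rownames
#'   "chrom:start:end:cluster"), `introns` metadata (incl. gene_id), and
#'   `truth` (planted DS clusters).
#' @export
simulate_splicing_counts <- function(config, design = NULL) {
  validate_config(config)
  if (is.null(design)) design <- simulate_design(config)
  ns <- nrow(design)
  nc <- config$n_clusters
  n_ds <- round(config$frac_ds_clusters * nc)
  ds_cl <- if (n_ds > 0) sample(nc, n_ds) else integer()
  rng <- config$introns_per_cluster
  sizes <- rng[1] + floor(stats::runif(nc) * (rng[2] - rng[1] + 1))
  out <- vector("list", nc)
  meta <- vector("list", nc)
  for (cl in seq_len(nc)) {
    I <- sizes[cl]
    eta <- stats::rnorm(I, 0, 1)
    shift <- if (cl %in% ds_cl) config$ds_effect else 0
    counts <- matrix(0L, I, ns)
    tot <- pmax(round(stats::rlnorm(ns, log(150), 0.5)), 10)
    for (s in seq_len(ns)) {
      e <- eta
      e[1] <- e[1] + shift * design$age01[s]
      p <- exp(e) / sum(exp(e))
      pr <- rdirichlet(1, config$dm_concentration * p)[1, ]
      counts[, s] <- stats::rmultinom(1, tot[s], pr)[, 1]
    }
    start <- cl * 50000L + cumsum(rep(1000L, I))
    rn <- sprintf("chr1:%d:%d:clu_%d", start, start + 500L, cl)
    rownames(counts) <- rn
    out[[cl]] <- counts
    meta[[cl]] <- data.frame(intron_id = rn, chrom = "chr1", start = start,
                             end = start + 500L,
                             cluster_id = paste0("clu_", cl),
                             gene_id = sprintf("sgene%04d", cl),
                             stringsAsFactors = FALSE)
  }
  junctions <- do.call(rbind, out)
  colnames(junctions) <- design$sample_id
  truth <- data.frame(cluster_id = sprintf("clu_%d", ds_cl),
                      effect_logit = rep(config$ds_effect, length(ds_cl)),
                      stringsAsFactors = FALSE)
  list(junctions = junctions, introns = do.call(rbind, meta), truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Composes the genotype, expression, ASE, and splicing generators under a
#' single seed and optionally writes all standard-format files (counts.tsv,
#' genotypes.vcf, dosage.tsv, ase_counts.tsv, junctions.tsv, annotation.bed,
#' design.tsv, truth tables).
#'
#' @param config a [sim_config()] object.
#' @param out_dir optional directory to write files into.
#' @return a `longage_cohort` list: design, counts, genotypes, ase, junctions,
#'   truth.
#' @export
simulate_cohort <- function(config = sim_config(), out_dir = NULL) {
  validate_config(config)
  set.seed(config$seed)
  design <- simulate_design(config)
  geno <- simulate_genotypes(config)
  expr <- simulate_expression_counts(config, geno, design)
  ase <- simulate_ase_counts(config, design)
  spl <- simulate_splicing_counts(config, design)
  cohort <- structure(list(
    config = config, design = design,
    counts = expr$counts, factors_true = expr$factors,
    genotypes = geno, ase = ase$ase, junctions = spl$junctions,
    introns = spl$introns,
    truth = list(de = expr$truth$de, eqtl = expr$truth$eqtl,
                 loadings = expr$truth$loadings,
                 diff_ase = ase$truth, ds = spl$truth)),
    class = "longage_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.longage_cohort <- function(x, ...) {
  cat("longage synthetic cohort:", nrow(x$design), "samples (",
      x$config$n_individuals, "individuals x 2 ages ),",
      nrow(x$counts), "genes,", nrow(x$genotypes$dosage), "SNPs,",
      length(unique(x$ase$site_id)), "ASE sites,",
      length(unique(x$introns$cluster_id)), "intron clusters\n")
  invisible(x)
}

#' Write a synthetic cohort to standard-format text files
#'
#' @param cohort a [simulate_cohort()] object.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  wt <- function(x, f, rn = FALSE)
    utils::write.table(x, p(f), sep = "\t", quote = FALSE, row.names = rn,
                       col.names = if (rn) NA else TRUE)
  wt(cohort$counts, "counts.tsv", rn = TRUE)
  wt(cohort$design, "design.tsv")
  wt(cohort$genotypes$dosage, "dosage.tsv", rn = TRUE)
  wt(cohort$ase, "ase_counts.tsv")
  wt(cohort$junctions, "junctions.tsv", rn = TRUE)
  bed <- data.frame(chrom = cohort$genotypes$genes$chrom,
                    start = cohort$genotypes$genes$tss,
                    end = cohort$genotypes$genes$tss + 1L,
                    name = cohort$genotypes$genes$gene_id)
  utils::write.table(bed, p("annotation.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_minimal_vcf(cohort$genotypes, p("genotypes.vcf"))
  for (nm in c("de", "eqtl", "diff_ase", "ds"))
    wt(cohort$truth[[nm]], paste0("truth_", nm, ".tsv"))
  invisible(list.files(out_dir, full.names = TRUE))
}

## Minimal VCF 4.2 with GT only, dosage coded 0/0, 0/1, 1/1.
write_minimal_vcf <- function(genotypes, path) {
  d <- genotypes$dosage
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d), ncol(d))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  body <- paste(genotypes$snps$chrom, genotypes$snps$pos,
                genotypes$snps$snp_id, "A", "G", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
}
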