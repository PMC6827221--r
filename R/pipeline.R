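## End-to-end orchestration: simulate -> preprocess -> DE/outliers -> QTL ->
## heritability -> ASE -> splicing, with a reproducible manifest.

#' Run the full longitudinal analysis pipeline on a synthetic cohort
#'
#' Executes the requested stages in dependency order.  Each stochastic
#' stage re-seeds from the master seed by a fixed counter scheme
#' (`child = (seed * 101 + stage index) mod 2^31 - 1`), so a re-run with the
#' same configuration reproduces every stage bit-identically.
#'
#' @param config a [sim_config()] object, or a path to a YAML file whose
#'   keys are `sim_config()` arguments.
#' @param out_dir optional output directory for stage TSVs and the manifest.
#' @param stages subset of `c("preprocess", "de", "outliers", "qtl", "h2",
#'   "ase", "splicing")` (simulation always runs).
#' @param n_factors hidden-factor count, or `"auto"` for permutation
#'   parallel analysis.
#' @param h2_genes number of genes carried into the (per-gene) bivariate
#'   heritability stage.
#' @param ase_scan_sites number of sites carried into the population-level
#'   differential ASE scan.
#' @param ase_scan_units number of site-individual units for the
#'   individual-level scan.
#' @return a `longage_manifest` list: config, seeds, stage results, summary
#'   metrics, file checksums.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         stages = c("preprocess", "de", "outliers", "qtl",
                                    "h2", "ase", "splicing"),
                         n_factors = "auto", h2_genes = 100,
                         ase_scan_sites = 25, ase_scan_units = 150) {
  if (is.character(config) && length(config) == 1)
    config <- do.call(sim_config, yaml::read_yaml(config))
  stopifnot(inherits(config, "longage_config"))
  known <- c("preprocess", "de", "outliers", "qtl", "h2", "ase", "splicing")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stages: ", paste(bad, collapse = ", "))
  ## downstream stages need preprocessing
  if (length(intersect(stages, c("de", "outliers", "qtl"))) > 0)
    stages <- union(stages, "preprocess")
  res <- list(); seeds <- list(); summary <- list(); status <- list()
  t_stage <- function(nm, idx, expr) {
    seeds[[nm]] <<- child_seed(config$seed, idx)
    set.seed(seeds[[nm]])
    out <- tryCatch(expr, error = function(e) e)
    status[[nm]] <<- if (inherits(out, "error"))
      paste("failed:", conditionMessage(out)) else "ok"
    if (inherits(out, "error")) stop("stage '", nm, "' failed: ",
                                     conditionMessage(out))
    out
  }

  cohort <- t_stage("simulate", 0, simulate_cohort(config))
  res$cohort <- cohort
  design <- cohort$design

  if ("preprocess" %in% stages) {
    pp <- t_stage("preprocess", 1, {
      kept <- filter_expressed_genes(cohort$counts, design)
      nm <- normalize_counts(cohort$counts, kept)
      k <- if (identical(n_factors, "auto"))
        estimate_num_hidden_factors(nm$normalized, design,
                                    covariates = c("rin", "rna_conc"))
      else as.integer(n_factors)
      hf <- extract_hidden_factors(nm$normalized, design, k)
      cc <- clustering_concordance(nm$normalized, design)
      list(norm = nm, factors = hf, concordance = cc, n_factors = k)
    })
    res$preprocess <- pp
    summary$n_kept_genes <- length(pp$norm$kept_genes)
    summary$n_hidden_factors <- pp$n_factors
    summary$clustering_concordance <- pp$concordance$fraction
  }

  if ("de" %in% stages) {
    de <- t_stage("de", 2,
                  de_scan(res$preprocess$norm$normalized, design,
                          res$preprocess$factors))
    res$de <- de
    summary$n_de_genes <- sum(de$significant)
    summary$mean_var_explained_by_age_sig <-
      if (any(de$significant))
        mean(de$var_explained_by_age[de$significant]) else NA_real_
  }

  if ("outliers" %in% stages) {
    out <- t_stage("outliers", 3, {
      inds <- res$preprocess$concordance$concordant_individuals
      ## with few concordant individuals the fences are unstable; fall
      ## back to the full cohort
      if (length(inds) < 10) inds <- unique(design$individual_id)
      detect_trajectory_outliers(res$preprocess$norm$normalized, design,
                                 individuals = inds)
    })
    res$outliers <- out
    summary$n_outlier_pairs <- nrow(out)
  }

  if ("qtl" %in% stages) {
    qtl <- t_stage("qtl", 4, {
      geno_ids <- colnames(cohort$genotypes$dosage)
      pheno_pos <- data.frame(
        phenotype_id = res$preprocess$norm$kept_genes, chrom = "chr1",
        pos = cohort$genotypes$genes$tss[
          match(res$preprocess$norm$kept_genes,
                cohort$genotypes$genes$gene_id)])
      ## per age, correct for the number of hidden factors that maximizes
      ## discovery (grid over 0..k_max), as in per-age eQTL optimization
      scans <- lapply(c(0, 1), function(a) {
        cols <- design$age01 == a
        samp_ind <- design$individual_id[cols]
        Y <- res$preprocess$norm$normalized[, cols, drop = FALSE]
        ord <- match(geno_ids, samp_ind)
        fac <- res$preprocess$factors$factors[cols, , drop = FALSE]
        k_max <- ncol(fac)
        grid <- unique(pmin(c(0, 5, 10, 15), k_max))
        best <- NULL; best_n <- -1
        for (k in grid) {
          cov <- if (k > 0) fac[ord, seq_len(k), drop = FALSE] else NULL
          sc <- map_cis_qtl(Y[, ord, drop = FALSE],
                            cohort$genotypes$dosage, pheno_pos,
                            cohort$genotypes$snps, covariates = cov,
                            window = 1e6)
          n_eg <- hierarchical_fdr(sc, 0.01, 0.01)$R
          if (n_eg > best_n) { best <- sc; best_n <- n_eg
            best$n_factors_used <- k }
        }
        best
      })
      h70 <- hierarchical_fdr(scans[[1]], 0.01, 0.01)
      h80 <- hierarchical_fdr(scans[[2]], 0.01, 0.01)
      rep70 <- replicate_two_step(scans[[1]], scans[[2]], 0.01, 0.10)
      rep80 <- replicate_two_step(scans[[2]], scans[[1]], 0.01, 0.10)
      ids <- scans[[1]]$phenotypes$phenotype_id
      mc <- mcnemar_exact(ids %in% h70$selected, ids %in% h80$selected)
      ec <- tryCatch(effect_correlation(scans[[1]], scans[[2]],
                                        "either_significant"),
                     error = function(e) list(rho = NA_real_))
      list(scans = scans, egenes_70 = h70, egenes_80 = h80,
           replication_70 = rep70, replication_80 = rep80,
           mcnemar = mc, effect_corr = ec)
    })
    res$qtl <- qtl
    summary$qtl_factors_70 <- qtl$scans[[1]]$n_factors_used
    summary$qtl_factors_80 <- qtl$scans[[2]]$n_factors_used
    summary$n_egenes_70 <- qtl$egenes_70$R
    summary$n_egenes_80 <- qtl$egenes_80$R
    summary$replication_70_in_80 <- qtl$replication_70$proportion
    summary$replication_80_in_70 <- qtl$replication_80$proportion
    summary$mcnemar_or <- qtl$mcnemar$or
    summary$mcnemar_p <- qtl$mcnemar$p_value
    summary$effect_spearman_rho <- qtl$effect_corr$rho
  }

  if ("h2" %in% stages) {
    h2r <- t_stage("h2", 5, {
      geno_ids <- colnames(cohort$genotypes$dosage)
      genes <- cohort$genotypes$genes$gene_id
      genes <- genes[seq_len(min(h2_genes, length(genes)))]
      y70m <- cohort$counts[, design$age01 == 0, drop = FALSE]
      y80m <- cohort$counts[, design$age01 == 1, drop = FALSE]
      ind70 <- design$individual_id[design$age01 == 0]
      ind80 <- design$individual_id[design$age01 == 1]
      fits <- lapply(genes, function(g) {
        snps <- cohort$genotypes$snps$snp_id[
          cohort$genotypes$snps$gene_id == g]
        grm <- compute_grm(cohort$genotypes$dosage[snps, , drop = FALSE])
        y70 <- log2(y70m[g, match(geno_ids, ind70)] + 1)
        y80 <- log2(y80m[g, match(geno_ids, ind80)] + 1)
        fit <- tryCatch(reml_bivariate(y70, y80, grm, n_restarts = 1),
                        error = function(e) NULL)
        if (is.null(fit) || !isTRUE(fit$convergence)) return(NULL)
        data.frame(gene = g, h2_70 = fit$h2_70, h2_80 = fit$h2_80,
                   se_70 = fit$se_70, se_80 = fit$se_80,
                   rho_g = fit$rho_g, stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, fits)
      wil <- paired_wilcoxon(tab$h2_80, tab$h2_70)
      ## SE floor keeps boundary estimates (tiny SEs) from dominating;
      ## fits without a usable SE get the median weight
      w <- 1 / pmax(c(tab$se_70, tab$se_80), 0.05)^2
      w[!is.finite(w)] <- stats::median(w[is.finite(w)])
      trend <- beta_regression_h2(c(tab$h2_70, tab$h2_80),
                                  rep(c(0, 1), each = nrow(tab)),
                                  weights = w)
      list(table = tab, wilcoxon = wil, trend = trend)
    })
    res$h2 <- h2r
    summary$median_rho_g <- stats::median(h2r$table$rho_g)
    summary$median_h2_70 <- stats::median(h2r$table$h2_70)
    summary$median_h2_80 <- stats::median(h2r$table$h2_80)
    summary$median_h2_change <- stats::median(h2r$table$h2_80 -
                                                h2r$table$h2_70)
    summary$h2_wilcoxon_p <- h2r$wilcoxon$p_value
    if (!isTRUE(h2r$trend$degenerate)) {
      summary$trend_h2_70 <- h2r$trend$fitted_h2_70
      summary$trend_h2_80 <- h2r$trend$fitted_h2_80
    }
  }

  if ("ase" %in% stages) {
    aser <- t_stage("ase", 6, {
      glob <- filter_ase_sites(cohort$ase, "global")
      stats_g <- global_ai_stats(glob)
      test_g <- global_ai_test(stats_g)
      pop <- filter_ase_sites(cohort$ase, "population")
      pop_sites <- unique(pop$site_id)
      truth_sites <- intersect(cohort$truth$diff_ase$site_id, pop_sites)
      keep <- union(truth_sites,
                    utils::head(pop_sites, ase_scan_sites))
      pop_scan <- differential_ase_scan(pop[pop$site_id %in% keep, ],
                                        "population")
      indiv <- filter_ase_sites(cohort$ase, "individual")
      key <- unique(paste(indiv$site_id, indiv$individual_id, sep = "||"))
      keep_u <- utils::head(key, ase_scan_units)
      ind_scan <- differential_ase_scan(
        indiv[paste(indiv$site_id, indiv$individual_id,
                    sep = "||") %in% keep_u, ], "individual")
      list(global_stats = stats_g, global_test = test_g,
           population = pop_scan, individual = ind_scan)
    })
    res$ase <- aser
    summary$ai_ratio_median <- aser$global_stats$mu
    summary$ai_increase_p <- aser$global_test$p_value
    summary$spearman_pi <- aser$global_stats$spearman_pi
    summary$n_diff_ase_sites <- sum(aser$population$significant)
    summary$n_diff_ase_individual <- sum(aser$individual$significant)
  }

  if ("splicing" %in% stages) {
    spl <- t_stage("splicing", 7, {
      ics <- intron_cluster_set(cohort$junctions,
                                unique(cohort$introns[, c("cluster_id",
                                                          "gene_id")]))
      cf <- cluster_filter(ics, design)
      covs <- as.matrix(design[, c("rin", "rna_conc")])
      scan <- ds_scan(cf$filtered, design, covariates = covs)
      list(qc = cf$qc, scan = scan)
    })
    res$splicing <- spl
    summary$n_clusters_pass <- sum(spl$qc$pass)
    summary$n_ds_clusters <- sum(spl$scan$clusters$significant)
    summary$n_ds_genes <- sum(spl$scan$genes$significant)
  }

  manifest <- structure(list(config = unclass(config), seeds = seeds,
                             status = status, summary = summary,
                             files = character()),
                        class = "longage_manifest")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_cohort(cohort, file.path(out_dir, "cohort"))
    wr <- function(x, f) {
      fp <- file.path(out_dir, f)
      utils::write.table(x, fp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      fp
    }
    if (!is.null(res$preprocess)) {
      fp <- file.path(out_dir, "normalized.tsv")
      utils::write.table(res$preprocess$norm$normalized, fp, sep = "\t",
                         quote = FALSE, col.names = NA)
      paths <- c(paths, fp)
      if (res$preprocess$factors$n_factors > 0)
        paths <- c(paths, wr(res$preprocess$factors$factors,
                             "factors.tsv"))
    }
    if (!is.null(res$de)) paths <- c(paths, wr(res$de, "de_results.tsv"))
    if (!is.null(res$outliers))
      paths <- c(paths, wr(res$outliers, "outliers.tsv"))
    if (!is.null(res$h2)) paths <- c(paths, wr(res$h2$table, "h2.tsv"))
    if (!is.null(res$splicing))
      paths <- c(paths, wr(res$splicing$scan$clusters, "ds_clusters.tsv"))
    manifest$files <- tools::md5sum(unlist(paths))
    jsonlite::write_json(
      list(config = manifest$config, seeds = manifest$seeds,
           status = manifest$status, summary = manifest$summary,
           files = as.list(manifest$files)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest$results <- res
  manifest
}

#' @export
print.longage_manifest <- function(x, ...) {
  cat("longage pipeline manifest (seed", x$config$seed, ")\n")
  for (nm in names(x$status)) cat(" ", nm, ":", x$status[[nm]], "\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-32s %s\n", nm, format(x$summary[[nm]], digits = 4)))
  invisible(x)
}

#' Calibration / power / recovery report against planted truth
#'
#' Compares each executed stage's discoveries with the cohort's truth
#' tables, reporting false discovery proportion, power, and parameter
#' recovery where applicable.
#'
#' @param manifest a [run_pipeline()] result.
#' @return data.frame: stage, metric, value.
#' @export
acceptance_report <- function(manifest) {
  res <- manifest$results
  truth <- res$cohort$truth
  rows <- list()
  add <- function(stage, metric, value)
    rows[[length(rows) + 1]] <<- data.frame(stage = stage, metric = metric,
                                            value = value)
  if (!is.null(res$de) && nrow(res$de) > 0) {
    sig <- res$de$gene[res$de$significant]
    if (length(sig) > 0)
      add("de", "fdp", mean(!sig %in% truth$de$gene_id))
    tested_true <- intersect(truth$de$gene_id, res$de$gene)
    if (length(tested_true) > 0)
      add("de", "power", mean(tested_true %in% sig))
    m <- match(tested_true, res$de$gene)
    if (length(m) > 0)
      add("de", "effect_bias",
          mean(res$de$beta_age[m] -
                 truth$de$effect_log2[match(tested_true,
                                            truth$de$gene_id)]))
  }
  if (!is.null(res$qtl)) {
    add("qtl", "egene_power_70",
        length(res$qtl$egenes_70$selected) / res$qtl$egenes_70$M)
    add("qtl", "replication_70_in_80", res$qtl$replication_70$proportion)
  }
  if (!is.null(res$h2)) {
    add("h2", "h2_70_bias",
        mean(res$h2$table$h2_70) - manifest$config$h2_by_age[1])
    add("h2", "rho_g_median_error",
        stats::median(res$h2$table$rho_g) - manifest$config$rho_g)
  }
  if (!is.null(res$ase)) {
    sig <- res$ase$population$site_id[res$ase$population$significant]
    tested_true <- intersect(truth$diff_ase$site_id,
                             res$ase$population$site_id)
    if (length(sig) > 0)
      add("ase", "fdp", mean(!sig %in% truth$diff_ase$site_id))
    if (length(tested_true) > 0)
      add("ase", "power", mean(tested_true %in% sig))
  }
  if (!is.null(res$splicing)) {
    sig <- res$splicing$scan$clusters$cluster_id[
      res$splicing$scan$clusters$significant]
    tested_true <- intersect(truth$ds$cluster_id,
                             res$splicing$scan$clusters$cluster_id)
    if (length(sig) > 0)
      add("splicing", "fdp", mean(!sig %in% truth$ds$cluster_id))
    if (length(tested_true) > 0)
      add("splicing", "power", mean(tested_true %in% sig))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
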