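## Expression filtering, normalization, hidden-factor estimation, and the
## sample-clustering concordance metric.

#' Filter genes by expression level
#'
#' A gene is kept if, within each age separately, (a) its mean count is at
#' least `min_mean` and (b) it has zero counts in no more than `max_zero_frac`
#' of individuals.
#'
#' @param raw_counts genes x samples non-negative integer matrix.
#' @param design cohort design table (needs `sample_id`, `age01`).
#' @param min_mean minimum within-age mean count (default 5).
#' @param max_zero_frac maximum within-age fraction of individuals with a
#'   zero count (default 0.2).
#' @return character vector of kept gene ids.
#' @export
filter_expressed_genes <- function(raw_counts, design, min_mean = 5,
                                   max_zero_frac = 0.2) {
  if (nrow(raw_counts) == 0 || ncol(raw_counts) == 0)
    stop("empty count matrix")
  stopifnot(identical(colnames(raw_counts), design$sample_id))
  keep <- rep(TRUE, nrow(raw_counts))
  for (a in unique(design$age01)) {
    cols <- design$age01 == a
    sub <- raw_counts[, cols, drop = FALSE]
    keep <- keep & rowMeans(sub) >= min_mean &
      rowMeans(sub == 0) <= max_zero_frac
  }
  rownames(raw_counts)[keep]
}

#' Library-size normalization (median-of-ratios) and log2 transform
#'
#' Size factors are median-of-ratios (median over genes of count / per-gene
#' geometric mean, computed by `DESeq2::estimateSizeFactorsForMatrix`);
#' normalized values are `log2(count / size_factor + 1)`.
#'
#' @param raw_counts genes x samples counts.
#' @param kept_genes gene ids to normalize (default: all rows).
#' @param transform optional replacement for the default
#'   `function(x) log2(x + 1)` applied to size-factor-corrected counts.
#' @return list with `normalized` (log2 scale), `size_factors`, `kept_genes`.
#' @export
normalize_counts <- function(raw_counts, kept_genes = rownames(raw_counts),
                             transform = function(x) log2(x + 1)) {
  if (length(kept_genes) == 0) stop("kept_genes is empty")
  m <- raw_counts[kept_genes, , drop = FALSE]
  sf <- DESeq2::estimateSizeFactorsForMatrix(m)
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factors undefined: a sample shares no gene with positive ",
         "geometric mean")
  norm <- transform(sweep(m, 2, sf, "/"))
  list(normalized = norm, size_factors = sf, kept_genes = kept_genes)
}

#' Estimate the number of hidden factors by permutation parallel analysis
#'
#' The normalized matrix is residualized on the primary model (age plus
#' measured covariates), rows standardized, and its singular-value variance
#' shares compared with those of `B` matrices in which each row is
#' independently permuted.  The returned count is the number of leading
#' components whose observed share exceeds the permutation `1 - alpha`
#' quantile (stopping at the first failure).
#'
#' @param normalized genes x samples matrix.
#' @param design design table (`age01` plus any columns named in
#'   `covariates`).
#' @param covariates character vector of design columns to residualize on
#'   (besides age); default none.
#' @param B number of permutations (default 20).
#' @param alpha significance level (default 0.05).
#' @return integer count of significant factors.
#' @export
estimate_num_hidden_factors <- function(normalized, design,
                                        covariates = character(),
                                        B = 20, alpha = 0.05) {
  if (B < 1) stop("B must be >= 1")
  if (ncol(normalized) < 3) stop("need at least 3 samples")
  X <- stats::model.matrix(
    ~., data = cbind(data.frame(age01 = design$age01),
                     design[, covariates, drop = FALSE]))
  R <- t(stats::lm.fit(X, t(normalized))$residuals)
  sds <- apply(R, 1, stats::sd)
  R <- R[sds > 0, , drop = FALSE]
  R <- R / apply(R, 1, stats::sd)
  share <- function(m) { d <- svd(m, nu = 0, nv = 0)$d^2; d / sum(d) }
  obs <- share(R)
  perm <- matrix(0, B, length(obs))
  for (b in seq_len(B)) {
    Rp <- t(apply(R, 1, sample))
    perm[b, ] <- share(Rp)
  }
  thr <- apply(perm, 2, stats::quantile, probs = 1 - alpha)
  sig <- obs > thr
  if (!sig[1]) return(0L)
  as.integer(which.min(c(sig, FALSE)) - 1L)
}

#' Extract hidden factors (surrogate variables)
#'
#' Iterative surrogate-variable estimation via `sva::sva`, with age as the
#' variable of interest and measured covariates in the model.  By default
#' (`protect_age = FALSE`) factors are allowed to correlate with age; with
#' `protect_age = TRUE` the returned factors are residualized on age.
#'
#' @param normalized genes x samples matrix.
#' @param design design table.
#' @param n_factors number of factors to extract; 0 returns an empty set.
#' @param covariates character vector of design columns used as measured
#'   covariates.
#' @param protect_age logical; force factors orthogonal to age.
#' @return list of class `longage_factors`: `factors` (samples x n_factors,
#'   columns centered), `n_factors`, `measured_covariates_used`.
#' @export
extract_hidden_factors <- function(normalized, design, n_factors,
                                   covariates = c("rin", "rna_conc"),
                                   protect_age = FALSE) {
  covariates <- intersect(covariates, colnames(design))
  empty <- structure(list(
    factors = matrix(0, ncol(normalized), 0), n_factors = 0L,
    measured_covariates_used = covariates), class = "longage_factors")
  if (n_factors <= 0) return(empty)
  if (n_factors > ncol(normalized) - 2)
    stop("n_factors must be <= samples - 2")
  df <- cbind(data.frame(age01 = design$age01),
              design[, covariates, drop = FALSE])
  mod <- stats::model.matrix(~., data = df)
  mod0 <- if (length(covariates) > 0)
    stats::model.matrix(~., data = df[, -1, drop = FALSE])
  else stats::model.matrix(~1, data = df)
  ## rows with zero variance carry no information and break the re-weighting
  keep <- apply(normalized, 1, stats::sd) > 0
  utils::capture.output(svobj <- suppressMessages(suppressWarnings(
    sva::sva(normalized[keep, , drop = FALSE], mod, mod0,
             n.sv = as.integer(n_factors)))))
  fac <- as.matrix(svobj$sv)
  if (protect_age)
    fac <- stats::lm.fit(cbind(1, design$age01), fac)$residuals
  fac <- scale(fac, scale = FALSE)
  colnames(fac) <- paste0("SV", seq_len(ncol(fac)))
  rownames(fac) <- design$sample_id
  structure(list(factors = fac, n_factors = ncol(fac),
                 measured_covariates_used = covariates),
            class = "longage_factors")
}

#' @export
print.longage_factors <- function(x, ...) {
  cat("longage hidden factors:", x$n_factors, "surrogate variables;",
      "measured covariates:", paste(x$measured_covariates_used,
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Sample-clustering concordance between ages
#'
#' Hierarchical clustering (Euclidean distance, complete linkage) of samples;
#' a sample "clusters with its own individual" if the sibling branch at its
#' first merge in the dendrogram contains its same-individual other-age
#' sample.  Returns the fraction of samples for which this holds.
#'
#' @param normalized genes x samples matrix.
#' @param design design table (`sample_id`, `individual_id`).
#' @return list: `fraction`, `concordant` (named logical per sample),
#'   `concordant_individuals` (ids for which both samples are concordant).
#' @export
clustering_concordance <- function(normalized, design) {
  tab <- table(design$individual_id)
  unpaired <- names(tab)[tab != 2]
  if (length(unpaired) > 0) {
    warning("excluding unpaired individuals: ",
            paste(unpaired, collapse = ", "))
    keep <- !design$individual_id %in% unpaired
    design <- design[keep, , drop = FALSE]
    normalized <- normalized[, keep, drop = FALSE]
  }
  hc <- stats::hclust(stats::dist(t(normalized)), method = "complete")
  ns <- ncol(normalized)
  ## leaves of each merge node
  leaves <- vector("list", nrow(hc$merge))
  sibling <- vector("list", ns)   # sibling leaf set at each sample's 1st merge
  for (k in seq_len(nrow(hc$merge))) {
    m <- hc$merge[k, ]
    side <- lapply(m, function(j) if (j < 0) -j else leaves[[j]])
    leaves[[k]] <- c(side[[1]], side[[2]])
    for (s in 1:2) {
      singles <- if (m[s] < 0) -m[s] else integer()
      for (leaf in singles) sibling[[leaf]] <- side[[3 - s]]
    }
  }
  pair_of <- vapply(seq_len(ns), function(i) {
    which(design$individual_id == design$individual_id[i] &
            seq_len(ns) != i)[1]
  }, integer(1))
  conc <- vapply(seq_len(ns), function(i) pair_of[i] %in% sibling[[i]],
                 logical(1))
  names(conc) <- design$sample_id
  ok_ind <- tapply(conc, design$individual_id, all)
  list(fraction = mean(conc), concordant = conc,
       concordant_individuals = names(ok_ind)[ok_ind])
}
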