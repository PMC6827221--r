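## Readers for the standard-format files the package writes and consumes.

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing counts.tsv, design.tsv, dosage.tsv,
#'   ase_counts.tsv, junctions.tsv, annotation.bed (any subset).
#' @return list with the components found: `counts`, `design`, `dosage`,
#'   `ase`, `junctions`, `annotation`.
#' @export
read_cohort_dir <- function(dir) {
  p <- function(f) file.path(dir, f)
  rd_mat <- function(f)
    as.matrix(utils::read.table(p(f), header = TRUE, sep = "\t",
                                row.names = 1, check.names = FALSE))
  out <- list()
  if (file.exists(p("counts.tsv"))) out$counts <- rd_mat("counts.tsv")
  if (file.exists(p("design.tsv")))
    out$design <- utils::read.table(p("design.tsv"), header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
  if (file.exists(p("dosage.tsv"))) out$dosage <- rd_mat("dosage.tsv")
  if (file.exists(p("ase_counts.tsv")))
    out$ase <- utils::read.table(p("ase_counts.tsv"), header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
  if (file.exists(p("junctions.tsv")))
    out$junctions <- rd_mat("junctions.tsv")
  if (file.exists(p("annotation.bed")))
    out$annotation <- utils::read.table(
      p("annotation.bed"), header = FALSE, sep = "\t",
      col.names = c("chrom", "start", "end", "name"),
      stringsAsFactors = FALSE)
  out
}

#' Read genotype dosages from a VCF or a dosage TSV
#'
#' VCF input (GT field, unphased or phased diploid calls) is parsed with
#' `vcfR`; a `.tsv` is read as a SNPs x individuals dosage matrix with SNP
#' ids in the first column.
#'
#' @param path path to a `.vcf`/`.vcf.gz` or `.tsv` file.
#' @return list: `dosage` (SNPs x individuals, 0/1/2), `snps` (snp_id,
#'   chrom, pos).
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dosage <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    dosage[] <- vapply(strsplit(gt, "[/|]"),
                       function(a) sum(as.integer(a)), integer(1))
    fix <- vcfR::getFIX(v)
    snps <- data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       stringsAsFactors = FALSE)
    list(dosage = dosage, snps = snps)
  } else {
    m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     row.names = 1, check.names = FALSE))
    list(dosage = m, snps = data.frame(snp_id = rownames(m),
                                       chrom = NA_character_,
                                       pos = NA_integer_,
                                       stringsAsFactors = FALSE))
  }
}

#' Hypergeometric gene-set over-representation test
#'
#' One-sided test of whether `hits` are enriched in each user-supplied set,
#' relative to the `universe` of tested genes.
#'
#' @param hits character vector of significant gene ids.
#' @param universe character vector of all tested gene ids.
#' @param sets named list of gene-id vectors.
#' @return data.frame: set, n_set, n_overlap, expected, p_value, q_value
#'   (BH).
#' @export
gene_set_enrichment <- function(hits, universe, sets) {
  hits <- intersect(hits, universe)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(hits, s))
    data.frame(set = nm, n_set = length(s), n_overlap = k,
               expected = length(hits) * length(s) / length(universe),
               p_value = stats::phyper(k - 1, length(s),
                                       length(universe) - length(s),
                                       length(hits), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}
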