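#' Pairwise LD between two SNPs as squared dosage correlation
#'
#' The composite LD estimate: the squared Pearson correlation of additive
#' dosages, computed on pairwise-complete observations. Needs no phasing
#' and is invariant to allele relabeling of either SNP (`d -> 2 - d`).
#'
#' @param d1,d2 dosage vectors in `{0, 1, 2, NA}`.
#' @return r-squared in `[0, 1]`, or `NA` when fewer than 3 complete pairs
#'   remain or either vector is constant on the complete set.
#' @export
genotype_r2 <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("dosage vectors differ in length")
  ok <- !is.na(d1) & !is.na(d2)
  if (sum(ok) < 3) return(NA_real_)
  x <- d1[ok]; y <- d2[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Minor allele frequency from dosages
#'
#' Folded allele-b frequency computed from non-missing dosages.
#'
#' @param geno a [genotype_matrix] or a dosage matrix/vector.
#' @return Named vector of per-SNP MAF in `[0, 0.5]`.
#' @export
snp_maf <- function(geno) {
  d <- if (inherits(geno, "genotype_matrix")) geno$dosage else as.matrix(geno)
  f <- colMeans(d, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Coverage rate of a gene region
#'
#' Genotyped-plus-tagged SNPs divided by the common SNPs in the region.
#' Can exceed 1 because genotyped SNPs are not required to be common.
#'
#' @param n_typed SNPs genotyped on the array.
#' @param n_tagged common, untyped SNPs tagged at the r-squared threshold.
#' @param n_common reference SNPs with MAF above the floor.
#' @return `(n_typed + n_tagged) / n_common`, or `NA` when `n_common` is 0
#'   (rendered "-" in reports).
#' @export
coverage_rate <- function(n_typed, n_tagged, n_common) {
  if (any(c(n_typed, n_tagged, n_common) < 0)) stop("counts must be >= 0")
  ifelse(n_common > 0, (n_typed + n_tagged) / n_common, NA_real_)
}

#' Tagging-based array coverage of one gene region
#'
#' Given a reference panel restricted to a gene region and the ids of SNPs
#' genotyped on the array, counts: all reference SNPs; common SNPs
#' (MAF strictly above `maf_floor`); typed SNPs; and tagged SNPs — common,
#' untyped SNPs whose pairwise r-squared with at least one typed SNP in the
#' same region reaches `r2_min`. SNPs with undefined r-squared (constant
#' dosage) are treated as untagged.
#'
#' @param ref_geno a [genotype_matrix] restricted to the gene region
#'   (reference panel).
#' @param typed_ids character vector of SNP ids genotyped on the array;
#'   must be a subset of the reference SNP ids.
#' @param maf_floor common means MAF strictly greater than this (default 0.05).
#' @param r2_min tagging threshold on pairwise r-squared (default 0.8).
#' @param gene_id id carried into the record.
#' @return One-row data.frame (a coverage record): `gene_id`, `n_total`,
#'   `n_common`, `n_typed`, `n_tagged`, `coverage_rate`.
#' @export
compute_tagging <- function(ref_geno, typed_ids, maf_floor = 0.05,
                            r2_min = 0.8, gene_id = NA_character_) {
  ids <- ref_geno$snps$snp_id
  if (length(setdiff(typed_ids, ids)))
    stop("typed_ids not in reference panel: ",
         paste(utils::head(setdiff(typed_ids, ids), 5), collapse = ", "))
  n_total <- length(ids)
  if (n_total == 0)
    return(data.frame(gene_id = gene_id, n_total = 0L, n_common = 0L,
                      n_typed = 0L, n_tagged = 0L,
                      coverage_rate = NA_real_, stringsAsFactors = FALSE))
  maf <- snp_maf(ref_geno)
  common <- maf > maf_floor
  typed <- ids %in% typed_ids
  candidates <- which(common & !typed)
  tagged <- logical(n_total)
  for (j in candidates) {
    for (k in which(typed)) {
      r2 <- genotype_r2(ref_geno$dosage[, j], ref_geno$dosage[, k])
      if (!is.na(r2) && r2 >= r2_min) { tagged[j] <- TRUE; break }
    }
  }
  data.frame(gene_id = gene_id, n_total = n_total,
             n_common = sum(common), n_typed = sum(typed),
             n_tagged = sum(tagged),
             coverage_rate = coverage_rate(sum(typed), sum(tagged),
                                           sum(common)),
             stringsAsFactors = FALSE)
}

#' Per-gene coverage report over an annotated reference panel
#'
#' Runs [compute_tagging()] for every gene, restricting the reference panel
#' to the SNPs assigned to that gene's extended region.
#'
#' @param ref_geno reference-panel [genotype_matrix].
#' @param genes gene data.frame (see [read_gene_table()]).
#' @param typed_ids SNP ids genotyped on the array.
#' @param upstream_bp,downstream_bp region extension, as in
#'   [extend_gene_region()].
#' @param maf_floor,r2_min see [compute_tagging()].
#' @return data.frame with one coverage record per gene.
#' @export
coverage_report <- function(ref_geno, genes, typed_ids, upstream_bp = 2000,
                            downstream_bp = 500, maf_floor = 0.05,
                            r2_min = 0.8) {
  asg <- map_snps_to_genes(ref_geno$snps, genes, upstream_bp, downstream_bp)
  rows <- lapply(genes$gene_id, function(g) {
    ids <- asg$snp_id[asg$gene_id == g]
    col <- match(ids, ref_geno$snps$snp_id)
    sub <- genotype_matrix(ref_geno$snps[col, , drop = FALSE],
                           ref_geno$individuals,
                           ref_geno$dosage[, col, drop = FALSE])
    compute_tagging(sub, intersect(typed_ids, ids), maf_floor, r2_min,
                    gene_id = g)
  })
  do.call(rbind, rows)
}
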