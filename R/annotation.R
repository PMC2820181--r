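#' Extend gene regions by asymmetric upstream/downstream windows
#'
#' Each gene interval is widened by `upstream_bp` beyond its 5' end and
#' `downstream_bp` beyond its 3' end, interpreted relative to strand: for a
#' `+` strand gene the 5' end is `start`, for a `-` strand gene it is `end`.
#' Genes with unknown strand are treated as `+`. The defaults (2 kb
#' upstream, 500 bp downstream) capture proximal promoter elements and 3'
#' processing signals. Lower bounds are clipped at 1.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive).
#' @param upstream_bp bases added beyond the 5' end.
#' @param downstream_bp bases added beyond the 3' end.
#' @return The input data.frame with extra columns `ext_start`, `ext_end`.
#' @export
extend_gene_region <- function(genes, upstream_bp = 2000, downstream_bp = 500) {
  if (any(genes$start > genes$end)) stop("gene with start > end")
  plus <- genes$strand != "-"
  ext_start <- ifelse(plus, genes$start - upstream_bp,
                      genes$start - downstream_bp)
  ext_end <- ifelse(plus, genes$end + downstream_bp,
                    genes$end + upstream_bp)
  genes$ext_start <- pmax(1L, as.integer(ext_start))
  genes$ext_end <- as.integer(ext_end)
  genes
}

#' Map SNPs to genes via extended gene regions
#'
#' A SNP is assigned to a gene when its position falls inside the gene's
#' extended region, boundaries inclusive. SNPs inside several extended
#' regions are assigned to each of those genes; SNPs on chromosomes absent
#' from the annotation are left unassigned.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (e.g.
#'   `geno$snps`).
#' @param genes gene data.frame; extended via [extend_gene_region()] using
#'   `upstream_bp`/`downstream_bp` unless it already has `ext_start`/`ext_end`.
#' @param upstream_bp,downstream_bp window sizes passed to
#'   [extend_gene_region()].
#' @return data.frame with columns `snp_id`, `gene_id`, one row per
#'   (SNP, gene) assignment.
#' @export
map_snps_to_genes <- function(snps, genes, upstream_bp = 2000,
                              downstream_bp = 500) {
  if (!all(c("ext_start", "ext_end") %in% names(genes)))
    genes <- extend_gene_region(genes, upstream_bp, downstream_bp)
  if (nrow(snps) == 0 || nrow(genes) == 0)
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  sg <- GenomicRanges::GRanges(snps$chrom,
                               IRanges::IRanges(snps$pos, snps$pos))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$ext_start,
                                                genes$ext_end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(sg, gg))
  out <- data.frame(
    snp_id = snps$snp_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  unique(out)
}

#' Build per-group SNP indexes
#'
#' For each gene group, collects the union of SNPs assigned to its member
#' genes. A SNP assigned to two member genes contributes once; its p-value
#' will enter the group statistic once. `n_genes_covered` counts member
#' genes carrying at least one SNP — genes without array SNPs drop out of
#' the counts but are reported.
#'
#' @param assignments data.frame from [map_snps_to_genes()].
#' @param groups named list of gene-id vectors (see [read_gene_groups()]).
#' @param warn_empty warn about groups with zero covered genes.
#' @return Named list of `group_snp_index` objects, each a list with
#'   `group_name`, `snp_ids` (deduplicated, in assignment order),
#'   `n_genes_covered`, `n_genes_in_group`, and `genes_uncovered`.
#' @export
build_group_index <- function(assignments, groups, warn_empty = TRUE) {
  out <- vector("list", length(groups))
  names(out) <- names(groups)
  for (g in names(groups)) {
    members <- unique(as.character(groups[[g]]))
    sel <- assignments$gene_id %in% members
    snp_ids <- unique(assignments$snp_id[sel])
    covered <- unique(assignments$gene_id[sel])
    if (warn_empty && length(covered) == 0)
      warning("group '", g, "' has no covered genes", call. = FALSE)
    out[[g]] <- structure(list(group_name = g, snp_ids = snp_ids,
                               n_genes_covered = length(covered),
                               n_genes_in_group = length(members),
                               genes_uncovered = setdiff(members, covered)),
                          class = "group_snp_index")
  }
  out
}

#' @export
print.group_snp_index <- function(x, ...) {
  cat("group_snp_index '", x$group_name, "': ", length(x$snp_ids),
      " SNPs over ", x$n_genes_covered, "/", x$n_genes_in_group,
      " genes\n", sep = "")
  invisible(x)
}
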