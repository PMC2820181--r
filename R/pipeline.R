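#' Run the full functional gene group analysis pipeline
#'
#' Stages, in order: match individuals across genotype and phenotype
#' inputs; optionally standardize the trait within collection sites; map
#' SNPs to extended gene regions and index them per group; per-SNP
#' regression scan; genomic-control lambda estimation (and, optionally,
#' GC-adjusted per-SNP p-values for reporting); group permutation test;
#' Bonferroni threshold over the groups tested. Group permutation runs on
#' the raw (non-GC) p-values — the permutation null is itself blind to
#' stratification — with lambda and GC-adjusted per-SNP p-values reported
#' alongside; set `gc_permute = TRUE` to permute GC-adjusted statistics
#' instead.
#'
#' @param geno a [genotype_matrix] or a path prefix (with `dialect`).
#' @param pheno phenotype data.frame or file path ([read_phenotypes()]).
#' @param genes gene data.frame or file path ([read_gene_table()]).
#' @param groups named list of gene-id vectors or a GMT path
#'   ([read_gene_groups()]).
#' @param dialect genotype dialect when `geno` is a path.
#' @param n_perm,seed,escalate permutation settings, see
#'   [permutation_plan()].
#' @param alpha family-wise significance level for the Bonferroni
#'   threshold.
#' @param upstream_bp,downstream_bp gene-region extension windows.
#' @param site_z standardize the trait within sites before analysis.
#' @param gc_permute apply genomic control to per-SNP p-values before the
#'   group permutation statistic (default uses raw p-values).
#' @param ... further arguments to [permutation_plan()].
#' @return list of class `fgg_run`: `group_results`, `snp_results`,
#'   `lambda`, `qq`, `bonferroni`, `manifest`.
#' @export
run_pipeline <- function(geno, pheno, genes, groups,
                         dialect = c("ped_map", "traw"),
                         n_perm = 10000, seed = 1, escalate = TRUE,
                         alpha = 0.05, upstream_bp = 2000,
                         downstream_bp = 500, site_z = FALSE,
                         gc_permute = FALSE, ...) {
  dialect <- match.arg(dialect)
  digests <- character(0)
  digest_of <- function(x) {
    f <- if (file.exists(x)) x else paste0(x, ".ped")
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }
  if (is.character(geno)) { digests["geno"] <- digest_of(geno)
    geno <- read_genotypes(geno, dialect) }
  if (is.character(pheno)) { digests["pheno"] <- digest_of(pheno)
    pheno <- read_phenotypes(pheno) }
  if (is.character(genes)) { digests["genes"] <- digest_of(genes)
    genes <- read_gene_table(genes) }
  if (is.character(groups)) { digests["groups"] <- digest_of(groups)
    groups <- read_gene_groups(groups) }

  n_snps_read <- nrow(geno$snps)
  matched <- match_individuals(geno, pheno)
  geno <- matched$geno
  trait <- matched$pheno$trait
  if (site_z) trait <- site_zscores(trait, matched$pheno$site)

  assignments <- map_snps_to_genes(geno$snps, genes, upstream_bp,
                                   downstream_bp)
  indexes <- build_group_index(assignments, groups)

  scan <- assoc_scan(geno, trait)
  lam <- estimate_lambda(scan$p[scan$valid])
  scan$p_gc <- genomic_control_adjust(scan$p, lam)
  qq <- qq_data(scan$p[scan$valid])

  plan <- permutation_plan(n_perm = n_perm, seed = seed,
                           escalate = escalate, ...)
  res <- permutation_test(geno, trait, indexes, plan,
                          gc_lambda = if (gc_permute) lam else 1)
  thr <- bonferroni_threshold(alpha, nrow(res))
  res$significant_after_bonferroni <- res$emp_p < thr

  manifest <- list(
    version = as.character(utils::packageVersion("fggtest")),
    input_digests = as.list(digests),
    seed = plan$seed, n_perm = plan$n_perm,
    flags = list(site_z = site_z, gc_permute = gc_permute,
                 escalate = plan$escalate),
    alpha = alpha, bonferroni_threshold = as.numeric(thr),
    upstream_bp = upstream_bp, downstream_bp = downstream_bp,
    counts = list(
      n_individuals_genotyped = length(matched$geno$individuals) +
        matched$n_geno_only,
      n_individuals_phenotyped = matched$n_matched + matched$n_pheno_only,
      n_individuals_matched = matched$n_matched,
      n_individuals_trait_missing = sum(is.na(trait)),
      n_snps_read = n_snps_read,
      n_snps_mapped = length(unique(assignments$snp_id)),
      n_snps_analyzed = sum(scan$valid),
      n_snps_invalid = sum(!scan$valid),
      n_groups = nrow(res)))

  structure(list(group_results = res, snp_results = scan, lambda = lam,
                 qq = qq, bonferroni = thr, manifest = manifest),
            class = "fgg_run")
}

#' @export
print.fgg_run <- function(x, ...) {
  m <- x$manifest
  cat("functional gene group analysis run\n")
  cat("  individuals:", m$counts$n_individuals_matched, "matched;",
      "SNPs:", m$counts$n_snps_analyzed, "analyzed of",
      m$counts$n_snps_read, "read\n")
  cat(sprintf("  lambda = %.5f; Bonferroni threshold = %.4f (%d groups)\n",
              x$lambda$lam, m$bonferroni_threshold, m$counts$n_groups))
  ord <- order(x$group_results$emp_p)
  print(x$group_results[ord, c("group_name", "n_genes", "n_snps",
                               "sum_stat", "emp_p")], row.names = FALSE)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits the Table-1-shaped group results TSV, the per-SNP results TSV
#' (SNP, CHR, POS, N, BETA, SE, T, P, P_GC), QQ data TSV, and the run
#' manifest as JSON.
#'
#' @param run an `fgg_run` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_group_results(run$group_results, file.path(dir, "group_results.tsv"),
                      alpha = run$manifest$alpha)
  snp <- run$snp_results
  out <- data.frame(SNP = snp$snp_id, CHR = snp$chrom, POS = snp$pos,
                    N = snp$n_used, BETA = snp$beta, SE = snp$se,
                    T = snp$t_stat, P = snp$p, P_GC = snp$p_gc,
                    stringsAsFactors = FALSE)
  utils::write.table(out, file.path(dir, "snp_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$qq, file.path(dir, "qq_data.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
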