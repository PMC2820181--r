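# Shared fixture builders; everything is generated in code at test time.

# quick genotype_matrix from a dosage matrix, one SNP per column
make_geno <- function(dosage, pos = NULL, chrom = "1") {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  snps <- data.frame(snp_id = sprintf("s%03d", seq_len(m)),
                     chrom = rep_len(chrom, m), pos = pos,
                     allele_a = rep_len("A", m), allele_b = rep_len("G", m),
                     stringsAsFactors = FALSE)
  genotype_matrix(snps, sprintf("i%03d", seq_len(nrow(dosage))), dosage)
}

# 3 individuals x 3 SNPs; snp2 genotypes AA / AG / GG
write_tiny_ped <- function(dir) {
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200", "1\tsnp3\t0\t300"),
             file.path(dir, "tiny.map"))
  writeLines(c("F1 id1 0 0 1 -9 A A A A C C",
               "F1 id2 0 0 1 -9 A A A G C T",
               "F1 id3 0 0 2 -9 A A G G T T"),
             file.path(dir, "tiny.ped"))
  file.path(dir, "tiny")
}

write_tiny_traw <- function(dir) {
  path <- file.path(dir, "tiny.traw")
  writeLines(c("CHR\tSNP\t(C)M\tPOS\tCOUNTED\tALT\tid1\tid2\tid3",
               "1\tsnp1\t0\t100\tG\tA\t0\t1\t2",
               "1\tsnp2\t0\t200\tT\tC\t2\tNA\t0"),
             path)
  path
}

write_tiny_pheno <- function(dir, site = FALSE) {
  path <- file.path(dir, "pheno.tsv")
  lines <- if (site)
    c("ID\tTRAIT\tSITE", "id1\t95.5\tA", "id2\tNA\tA", "id3\t110\tB")
  else
    c("ID\tTRAIT", "id1\t95.5", "id2\tNA", "id3\t110")
  writeLines(lines, path)
  path
}

# gene table used across annotation tests
tiny_genes <- function() {
  data.frame(gene_id = c("geneP", "geneM", "geneC"),
             chrom = c("1", "1", "2"),
             start = c(10000L, 10000L, 1000L),
             end = c(12000L, 12000L, 1200L),
             strand = c("+", "-", "+"), stringsAsFactors = FALSE)
}

gmt_path <- function() {
  system.file("extdata", "gprotein_relay.gmt", package = "fggtest")
}

# small-but-real study used by several modules
small_study <- function(seed = 11, n = 500) {
  simulate_study(sim_config(
    n_individuals = n, n_blocks = 10, snps_per_block = 5,
    group_spec = list(planted = list(n_genes = 5, r2 = 0.08)),
    seed = seed))
}
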