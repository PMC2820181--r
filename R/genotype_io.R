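#' Construct a genotype matrix object
#'
#' Bundles additive allele dosages with SNP metadata and individual ids.
#' Dosage is the count (0/1/2, `NA` = missing) of `allele_b`, the effect
#' allele, per individual and SNP.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`. Positions are 1-based. Alleles are single characters in
#'   `A`, `C`, `G`, `T` or `0` (unknown).
#' @param individuals character vector of individual ids.
#' @param dosage numeric matrix, individuals x SNPs, values in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(snps, individuals, dosage) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(req %in% names(snps)))
    stop("snps must have columns: ", paste(req, collapse = ", "))
  individuals <- as.character(individuals)
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(individuals) || ncol(dosage) != nrow(snps))
    stop("dosage dimensions (", nrow(dosage), " x ", ncol(dosage),
         ") do not match ", length(individuals), " individuals x ",
         nrow(snps), " SNPs")
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  if (anyDuplicated(individuals))
    stop("duplicate individual id")
  if (any(snps$pos < 1))
    stop("SNP positions must be >= 1")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or NA")
  ok <- c("A", "C", "G", "T", "0")
  if (!all(snps$allele_a %in% ok) || !all(snps$allele_b %in% ok))
    stop("alleles must be one of A, C, G, T or 0 (unknown)")
  dimnames(dosage) <- list(individuals, snps$snp_id)
  structure(list(snps = snps, individuals = individuals, dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individuals), "individuals x",
      nrow(x$snps), "SNPs\n")
  cat("  chromosomes:", paste(unique(x$snps$chrom), collapse = ", "), "\n")
  nm <- sum(is.na(x$dosage))
  cat("  missing dosages:", nm,
      sprintf("(%.2f%%)\n", 100 * nm / length(x$dosage)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read genotypes from PLINK-style text files
#'
#' Two dialects are supported: `ped_map` (a `.ped`/`.map` pair with two
#' allele columns per SNP) and `traw` (a transposed additive dosage table
#' with header `CHR SNP (C)M POS COUNTED ALT` followed by one column per
#' individual, as produced by `plink --recode A-transpose`).
#'
#' For the `ped_map` dialect the effect allele (`allele_b`, whose copies the
#' dosage counts) is the minor allele at each SNP; frequency ties are broken
#' toward the alphabetically later allele. Missing genotypes are `0 0` in
#' `.ped` and `NA` in `.traw`.
#'
#' @param path_prefix path without extension for `ped_map` (reads
#'   `<prefix>.ped` and `<prefix>.map`); full file path for `traw`.
#' @param dialect `"ped_map"` or `"traw"`.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path_prefix, dialect = c("ped_map", "traw")) {
  dialect <- match.arg(dialect)
  if (dialect == "ped_map") read_ped_map(path_prefix) else read_traw(path_prefix)
}

read_ped_map <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (f in c(ped_path, map_path))
    if (!file.exists(f)) stop("file not found: ", f)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  if (!length(map_lines)) stop("empty .map file: ", map_path)
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_tok)
  if (any(nf < 4))
    stop("malformed .map line ", which(nf < 4)[1], " in ", map_path,
         ": expected 4 fields")
  map <- data.frame(chrom = vapply(map_tok, `[`, "", 1),
                    snp_id = vapply(map_tok, `[`, "", 2),
                    pos = as.integer(vapply(map_tok, `[`, "", 4)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp_id in ", map_path, ": ",
         paste(unique(map$snp_id[duplicated(map$snp_id)]), collapse = ", "))
  m <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  if (!length(ped_lines)) stop("empty .ped file: ", ped_path)
  n <- length(ped_lines)
  a1 <- matrix("", n, m)
  a2 <- matrix("", n, m)
  ids <- character(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m)
      stop("malformed .ped line ", i, " in ", ped_path, ": expected ",
           6 + 2 * m, " columns, found ", length(tok))
    ids[i] <- tok[2]
    g <- tok[-(1:6)]
    a1[i, ] <- g[seq(1, 2 * m, by = 2)]
    a2[i, ] <- g[seq(2, 2 * m, by = 2)]
  }

  dosage <- matrix(NA_real_, n, m)
  allele_a <- character(m)
  allele_b <- character(m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    if (!all(obs %in% c("A", "C", "G", "T")))
      stop("invalid allele code at SNP ", map$snp_id[j], " in ", ped_path)
    u <- sort(unique(obs))
    if (length(u) > 2)
      stop("more than two alleles at SNP ", map$snp_id[j], " in ", ped_path)
    if (length(u) == 0) {
      allele_a[j] <- "0"; allele_b[j] <- "0"
      next
    }
    if (length(u) == 1) {
      # monomorphic: the single observed allele is the reference, dosage 0
      allele_a[j] <- u; allele_b[j] <- "0"
      miss <- a1[, j] == "0" | a2[, j] == "0"
      dosage[!miss, j] <- 0
      next
    }
    freq <- c(mean(obs == u[1]), mean(obs == u[2]))
    # minor allele is counted; tie -> alphabetically later allele
    b <- if (freq[2] <= freq[1]) u[2] else u[1]
    a <- setdiff(u, b)
    allele_a[j] <- a; allele_b[j] <- b
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dosage[, j] <- (a1[, j] == b) + (a2[, j] == b)
    dosage[miss, j] <- NA_real_
  }
  snps <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                     allele_a = allele_a, allele_b = allele_b,
                     stringsAsFactors = FALSE)
  genotype_matrix(snps, ids, dosage)
}

read_traw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("empty traw file: ", path)
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(header) < 7 || toupper(header[2]) != "SNP")
    stop("malformed traw header in ", path,
         ": expected CHR SNP (C)M POS COUNTED ALT <ids...>")
  ids <- header[-(1:6)]
  m <- length(lines) - 1
  if (m < 1) stop("traw file has no SNP rows: ", path)
  n <- length(ids)
  dosage <- matrix(NA_real_, n, m)
  snps <- data.frame(snp_id = character(m), chrom = character(m),
                     pos = integer(m), allele_a = character(m),
                     allele_b = character(m), stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    tok <- strsplit(trimws(lines[j + 1]), "[ \t]+")[[1]]
    if (length(tok) != 6 + n)
      stop("malformed traw line ", j + 1, " in ", path, ": expected ",
           6 + n, " columns, found ", length(tok))
    snps$chrom[j] <- tok[1]
    snps$snp_id[j] <- tok[2]
    snps$pos[j] <- as.integer(tok[4])
    snps$allele_b[j] <- tok[5]  # COUNTED allele
    snps$allele_a[j] <- tok[6]
    v <- tok[-(1:6)]
    d <- suppressWarnings(as.numeric(v))
    d[v %in% c("NA", "-9")] <- NA_real_
    if (any(is.na(d) & !(v %in% c("NA", "-9"))))
      stop("non-numeric dosage token on traw line ", j + 1, " in ", path)
    dosage[, j] <- d
  }
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id in ", path, ": ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  genotype_matrix(snps, ids, dosage)
}

#' Write genotypes to PLINK-style text files
#'
#' Inverse of [read_genotypes()]; used for fixtures and round-trip checks.
#'
#' @param geno a [genotype_matrix].
#' @param path_prefix output prefix (`ped_map`) or file path (`traw`).
#' @param dialect `"ped_map"` or `"traw"`.
#' @return Invisibly, the path(s) written.
#' @export
write_genotypes <- function(geno, path_prefix, dialect = c("ped_map", "traw")) {
  dialect <- match.arg(dialect)
  if (dialect == "traw") {
    rows <- c(paste(c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT",
                      geno$individuals), collapse = "\t"))
    for (j in seq_len(nrow(geno$snps))) {
      d <- geno$dosage[, j]
      rows <- c(rows, paste(c(geno$snps$chrom[j], geno$snps$snp_id[j], 0,
                              geno$snps$pos[j], geno$snps$allele_b[j],
                              geno$snps$allele_a[j],
                              ifelse(is.na(d), "NA", format(d))),
                            collapse = "\t"))
    }
    writeLines(rows, path_prefix)
    return(invisible(path_prefix))
  }
  map <- with(geno$snps, paste(chrom, snp_id, 0, pos, sep = "\t"))
  writeLines(map, paste0(path_prefix, ".map"))
  n <- length(geno$individuals)
  ped <- character(n)
  for (i in seq_len(n)) {
    g <- character(0)
    for (j in seq_len(nrow(geno$snps))) {
      d <- geno$dosage[i, j]
      a <- geno$snps$allele_a[j]; b <- geno$snps$allele_b[j]
      g <- c(g, if (is.na(d)) c("0", "0")
             else if (d == 0) c(a, a)
             else if (d == 1) c(a, b)
             else c(b, b))
    }
    ped[i] <- paste(c("FAM", geno$individuals[i], 0, 0, 0, -9, g),
                    collapse = " ")
  }
  writeLines(ped, paste0(path_prefix, ".ped"))
  invisible(paste0(path_prefix, c(".ped", ".map")))
}

#' Read a phenotype table
#'
#' Whitespace- or tab-delimited with a header. The first column is the
#' individual id, the second the quantitative trait, and an optional third
#' column the collection-site label. Missing traits may be coded `NA` or
#' `-9` (PLINK convention).
#'
#' @param path file path.
#' @param missing_codes tokens treated as missing trait values.
#' @return data.frame with columns `individual_id`, `trait`, `site`.
#'   When no site column is present every individual gets site `"site1"`.
#' @export
read_phenotypes <- function(path, missing_codes = c("NA", "-9")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("empty phenotype file: ", path)
  tok <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(tok)
  if (any(nf < 2))
    stop("malformed phenotype line ", which(nf < 2)[1], " in ", path)
  body <- tok[-1]
  ids <- vapply(body, `[`, "", 1)
  raw <- vapply(body, `[`, "", 2)
  trait <- suppressWarnings(as.numeric(raw))
  bad <- is.na(trait) & !(raw %in% missing_codes)
  if (any(bad))
    stop("non-numeric trait token '", raw[which(bad)[1]],
         "' on phenotype line ", which(bad)[1] + 1, " in ", path)
  trait[raw %in% missing_codes] <- NA_real_
  has_site <- all(nf[-1] >= 3)
  site <- if (has_site) vapply(body, `[`, "", 3) else rep("site1", length(ids))
  if (anyDuplicated(ids))
    stop("duplicate individual id in ", path)
  data.frame(individual_id = ids, trait = trait, site = site,
             stringsAsFactors = FALSE)
}

#' Read a gene annotation table
#'
#' Tab/whitespace-delimited with header and columns GENE, CHR, START, END,
#' STRAND. Coordinates are 1-based and inclusive; strand is `+`, `-` or
#' anything else (treated as unknown, handled as `+` during extension).
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 5) stop("gene table needs 5 columns (GENE CHR START END STRAND): ", path)
  genes <- data.frame(gene_id = tab[[1]], chrom = tab[[2]],
                      start = as.integer(tab[[3]]), end = as.integer(tab[[4]]),
                      strand = tab[[5]], stringsAsFactors = FALSE)
  if (any(genes$start > genes$end))
    stop("gene with start > end in ", path, ": ",
         genes$gene_id[which(genes$start > genes$end)[1]])
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in ", path)
  genes$strand[!(genes$strand %in% c("+", "-"))] <- "+"
  genes
}

#' Read gene groups from a GMT file
#'
#' One gene set per line: set name, description, then member gene ids, all
#' tab-separated. Duplicate gene ids within a line are collapsed.
#'
#' @param path GMT file path.
#' @return Named list; each element is a character vector of unique gene
#'   ids with a `description` attribute.
#' @export
read_gene_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  groups <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) < 3)
      stop("malformed GMT line ", i, " in ", path,
           ": expected name, description and at least one gene id")
    genes <- unique(tok[-(1:2)])
    g <- structure(genes, description = tok[2])
    groups[[tok[1]]] <- g
  }
  groups
}

#' Write group association results to a TSV file
#'
#' Rows are ordered by empirical p-value (ascending). Columns: group,
#' n_genes, n_snps, sum_neglog10, emp_p, n_perm, significant_after_bonferroni.
#'
#' @param results data.frame as returned by [permutation_test()].
#' @param path output path.
#' @param alpha family-wise significance level for the Bonferroni column.
#' @return Invisibly, the written data.frame.
#' @export
write_group_results <- function(results, path, alpha = 0.05) {
  cols <- c("group", "n_genes", "n_snps", "sum_neglog10", "emp_p", "n_perm",
            "significant_after_bonferroni")
  if (nrow(results) == 0) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(results))
  }
  thr <- bonferroni_threshold(alpha, nrow(results))
  out <- data.frame(group = results$group_name, n_genes = results$n_genes,
                    n_snps = results$n_snps,
                    sum_neglog10 = results$sum_stat, emp_p = results$emp_p,
                    n_perm = results$n_perm,
                    significant_after_bonferroni = results$emp_p < thr,
                    stringsAsFactors = FALSE)
  out <- out[order(out$emp_p, -out$sum_neglog10), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Match genotype and phenotype individuals
#'
#' Intersects the two id sets, preserving genotype order, and reports how
#' many individuals were dropped from each side.
#'
#' @param geno a [genotype_matrix].
#' @param pheno a phenotype data.frame from [read_phenotypes()].
#' @return list with the subset `geno`, aligned `pheno`, and counts
#'   `n_matched`, `n_geno_only`, `n_pheno_only`.
#' @export
match_individuals <- function(geno, pheno) {
  keep <- geno$individuals %in% pheno$individual_id
  ids <- geno$individuals[keep]
  g <- genotype_matrix(geno$snps, ids, geno$dosage[keep, , drop = FALSE])
  p <- pheno[match(ids, pheno$individual_id), , drop = FALSE]
  rownames(p) <- NULL
  list(geno = g, pheno = p, n_matched = length(ids),
       n_geno_only = sum(!keep),
       n_pheno_only = sum(!(pheno$individual_id %in% ids)))
}
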