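test_that("ped/map parsing codes dosage as minor-allele counts", {
  dir <- withr::local_tempdir()
  geno <- read_genotypes(write_tiny_ped(dir), "ped_map")
  expect_s3_class(geno, "genotype_matrix")
  expect_equal(dim(geno), c(3L, 3L))
  expect_equal(geno$individuals, c("id1", "id2", "id3"))
  # AA/AG/GG with allele_b = G -> 0/1/2
  expect_equal(geno$snps$allele_b[2], "G")
  expect_equal(unname(geno$dosage[, "snp2"]), c(0, 1, 2))
  expect_equal(unname(geno$dosage[, "snp3"]), c(0, 1, 2))
  # monomorphic SNP: observed allele is reference, dosage 0
  expect_equal(unname(geno$dosage[, "snp1"]), c(0, 0, 0))
  expect_identical(geno$snps$snp_id, c("snp1", "snp2", "snp3"))
})

test_that("traw parsing keeps COUNTED as effect allele and NA as missing", {
  dir <- withr::local_tempdir()
  geno <- read_genotypes(write_tiny_traw(dir), "traw")
  expect_equal(geno$snps$allele_b, c("G", "T"))
  expect_equal(geno$snps$allele_a, c("A", "C"))
  expect_equal(unname(geno$dosage[, "snp1"]), c(0, 1, 2))
  expect_true(is.na(geno$dosage["id2", "snp2"]))
})

test_that("malformed genotype files raise errors naming the line", {
  dir <- withr::local_tempdir()
  prefix <- write_tiny_ped(dir)
  # wrong column count (2N + 6 mismatch)
  lines <- readLines(paste0(prefix, ".ped"))
  lines[2] <- paste(lines[2], "A")
  writeLines(lines, file.path(dir, "bad.ped"))
  file.copy(paste0(prefix, ".map"), file.path(dir, "bad.map"))
  expect_error(read_genotypes(file.path(dir, "bad"), "ped_map"), "line 2")
  # duplicate snp_id
  map <- readLines(paste0(prefix, ".map"))
  map[2] <- map[1]
  writeLines(map, file.path(dir, "dup.map"))
  file.copy(paste0(prefix, ".ped"), file.path(dir, "dup.ped"))
  expect_error(read_genotypes(file.path(dir, "dup"), "ped_map"),
               "duplicate snp_id")
  expect_error(read_genotypes(file.path(dir, "nothere"), "ped_map"),
               "not found")
})

test_that("genotype round-trip reproduces dosages exactly in both dialects", {
  st <- small_study(seed = 3, n = 40)
  geno <- st$geno
  geno$dosage[2, 5] <- NA  # include a missing cell
  # .ped carries no counted-allele designation: reading recodes to the
  # minor allele, so write the fixture in that coding first (ties keep G,
  # the alphabetically later allele)
  flip <- colMeans(geno$dosage, na.rm = TRUE) / 2 > 0.5
  geno$dosage[, flip] <- 2 - geno$dosage[, flip]
  geno$snps[flip, c("allele_a", "allele_b")] <-
    geno$snps[flip, c("allele_b", "allele_a")]
  dir <- withr::local_tempdir()
  write_genotypes(geno, file.path(dir, "rt"), "ped_map")
  back <- read_genotypes(file.path(dir, "rt"), "ped_map")
  expect_identical(back$dosage, geno$dosage)
  write_genotypes(geno, file.path(dir, "rt.traw"), "traw")
  back2 <- read_genotypes(file.path(dir, "rt.traw"), "traw")
  expect_identical(back2$dosage, geno$dosage)
  expect_identical(back2$snps, geno$snps)
})

test_that("allele swap is involutive on dosage: d -> 2 - d, missing fixed", {
  dir <- withr::local_tempdir()
  geno <- read_genotypes(write_tiny_traw(dir), "traw")
  swapped <- geno
  swapped$snps[, c("allele_a", "allele_b")] <-
    swapped$snps[, c("allele_b", "allele_a")]
  swapped$dosage <- 2 - swapped$dosage
  # writing the swapped coding and reading back must invert it
  write_genotypes(swapped, file.path(dir, "sw.traw"), "traw")
  back <- read_genotypes(file.path(dir, "sw.traw"), "traw")
  expect_equal(unname(2 - back$dosage), unname(geno$dosage))
  expect_true(is.na(back$dosage["id2", "snp2"]))
})

test_that("phenotype reading handles missing codes, sites and errors", {
  dir <- withr::local_tempdir()
  ph <- read_phenotypes(write_tiny_pheno(dir))
  expect_equal(ph$trait, c(95.5, NA, 110))
  expect_equal(unique(ph$site), "site1")
  ph2 <- read_phenotypes(write_tiny_pheno(dir, site = TRUE))
  expect_equal(ph2$site, c("A", "A", "B"))
  writeLines(c("ID TRAIT", "id1 ninety"), file.path(dir, "bad.tsv"))
  expect_error(read_phenotypes(file.path(dir, "bad.tsv")), "non-numeric")
  writeLines(character(0), file.path(dir, "empty.tsv"))
  expect_error(read_phenotypes(file.path(dir, "empty.tsv")), "empty")
})

test_that("phenotype file round-trips the simulated trait moments", {
  cfg <- sim_config(n_individuals = 627, n_blocks = 4, snps_per_block = 2,
                    group_spec = list(g = list(n_genes = 1, r2 = 0.02)),
                    n_genes = 4, seed = 9)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(nrow(ph), 627)
  expect_equal(mean(ph$trait), 100.7, tolerance = 1e-6)
  expect_equal(sd(ph$trait), 15.7, tolerance = 1e-6)
})

test_that("GMT parsing dedupes genes and rejects short lines", {
  dir <- withr::local_tempdir()
  writeLines("Gprotein\tdesc\tGNAQ\tGNB3\tGNAQ", file.path(dir, "one.gmt"))
  g <- read_gene_groups(file.path(dir, "one.gmt"))
  expect_equal(sort(as.character(g$Gprotein)), c("GNAQ", "GNB3"))
  expect_equal(attr(g$Gprotein, "description"), "desc")
  gp <- read_gene_groups(gmt_path())
  expect_length(gp$Gprotein_relay, 27)
  writeLines("name_only\tdesc", file.path(dir, "bad.gmt"))
  expect_error(read_gene_groups(file.path(dir, "bad.gmt")), "line 1")
})

test_that("group results table is emp_p-ordered with a Bonferroni flag", {
  res <- data.frame(
    group_name = c("other", "G_protein_relay"),
    n_genes = c(26L, 25L), n_snps = c(405L, 359L),
    sum_stat = c(210, 227), emp_p = c(0.031, 0.00019),
    n_perm = c(10000L, 100000L), perm_exceed = c(240L, 19L),
    stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  out <- write_group_results(res, file.path(dir, "groups.tsv"), alpha = 0.05)
  tab <- read.delim(file.path(dir, "groups.tsv"))
  expect_equal(tab$group, c("G_protein_relay", "other"))
  expect_equal(tab$sum_neglog10, c(227, 210))
  expect_equal(tab$emp_p, c(0.00019, 0.031))
  expect_equal(tab$significant_after_bonferroni, c(TRUE, FALSE))
  # empty input -> header-only file
  write_group_results(res[0, ], file.path(dir, "empty.tsv"))
  expect_equal(length(readLines(file.path(dir, "empty.tsv"))), 1L)
})

test_that("individual matching drops and counts unmatched ids", {
  st <- small_study(seed = 5, n = 20)
  pheno <- st$pheno[c(3:20, 1), ]  # drop id 2, scramble order
  pheno <- rbind(pheno, data.frame(individual_id = "ghost", trait = 100,
                                   site = "site1"))
  m <- match_individuals(st$geno, pheno)
  expect_equal(m$n_matched, 19)
  expect_equal(m$n_geno_only, 1)
  expect_equal(m$n_pheno_only, 1)
  expect_identical(m$geno$individuals, m$pheno$individual_id)
})
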