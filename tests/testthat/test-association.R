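test_that("per-SNP regression matches the correlation-test closed form", {
  set.seed(101)
  n <- 200
  for (rep in 1:20) {
    x <- rbinom(n, 2, runif(1, 0.1, 0.5))
    y <- rnorm(n)
    fit <- fit_snp_regression(x, y)
    r <- cor(x, y)
    t_or <- r * sqrt((n - 2) / (1 - r^2))
    p_or <- 2 * pt(-abs(t_or), n - 2)
    expect_equal(fit$p, p_or, tolerance = 1e-10)
    expect_equal(fit$t_stat, t_or, tolerance = 1e-10)
    expect_equal(fit$df, n - 2L)
  }
  # independent oracle: lm()
  x <- rbinom(n, 2, 0.3); y <- 0.2 * x + rnorm(n)
  fit <- fit_snp_regression(x, y)
  co <- summary(lm(y ~ x))$coefficients["x", ]
  expect_equal(fit$beta, unname(co["Estimate"]), tolerance = 1e-12)
  expect_equal(fit$se, unname(co["Std. Error"]), tolerance = 1e-12)
  expect_equal(fit$p, unname(co["Pr(>|t|)"]), tolerance = 1e-12)
})

test_that("regression flags degenerate SNPs and floors perfect fits", {
  # perfect fit: trait equals dosage
  x <- rep(c(0, 1, 2), length.out = 10)
  fit <- fit_snp_regression(x, x)
  expect_true(fit$valid)
  expect_equal(fit$beta, 1)
  expect_equal(fit$p, 1e-300)
  # monomorphic
  expect_false(fit_snp_regression(rep(1, 10), rnorm(10))$valid)
  # too few complete observations
  expect_false(fit_snp_regression(c(0, 1, NA, NA), c(1, 2, 3, NA))$valid)
  # casewise deletion: NAs in either vector are dropped for that SNP
  set.seed(5)
  x <- rbinom(50, 2, 0.4); y <- rnorm(50)
  x[c(3, 7)] <- NA; y[10] <- NA
  ok <- !is.na(x) & !is.na(y)
  fit <- fit_snp_regression(x, y)
  expect_equal(fit$n_used, sum(ok))
  expect_equal(fit$p, fit_snp_regression(x[ok], y[ok])$p)
})

test_that("assoc_scan equals per-SNP fits, is alignment-invariant and calibrated", {
  st <- small_study(seed = 31, n = 300)
  geno <- st$geno
  geno$dosage[cbind(sample(300, 20), sample(50, 20, replace = TRUE))] <- NA
  trait <- st$pheno$trait
  scan <- assoc_scan(geno, trait)
  expect_equal(nrow(scan), 50)
  for (j in c(1, 17, 50)) {
    fit <- fit_snp_regression(geno$dosage[, j], trait)
    expect_equal(scan$p[j], fit$p, tolerance = 1e-12)
    expect_equal(scan$beta[j], fit$beta, tolerance = 1e-12)
    expect_equal(scan$n_used[j], fit$n_used)
  }
  # permuting individuals in both inputs leaves results identical
  ord <- sample(300)
  geno2 <- genotype_matrix(geno$snps, geno$individuals[ord],
                           geno$dosage[ord, ])
  scan2 <- assoc_scan(geno2, trait[ord])
  expect_equal(scan2$p, scan$p, tolerance = 1e-12)
  # scale invariance: multiplying the trait leaves every p unchanged
  scan3 <- assoc_scan(geno, trait * 3.7)
  expect_equal(scan3$p, scan$p, tolerance = 1e-9)
  # null calibration: fraction p < 0.05 within binomial 99% CI
  cfg <- sim_config(n_individuals = 400, n_blocks = 400, snps_per_block = 5,
                    ld_rho = 0, group_spec = list(g = list(n_genes = 1,
                                                           r2 = 0)),
                    seed = 77)
  stn <- simulate_study(cfg)
  scan_null <- assoc_scan(stn$geno, stn$pheno$trait)
  frac <- mean(scan_null$p[scan_null$valid] < 0.05)
  m <- sum(scan_null$valid)
  half <- 2.576 * sqrt(0.05 * 0.95 / m)
  expect_lt(abs(frac - 0.05), half)
  # all-monomorphic input errors
  mono <- make_geno(matrix(1, 10, 2))
  expect_error(assoc_scan(mono, rnorm(10)), "no analyzable")
})

test_that("p/chi-square conversion hits the reference quantiles", {
  expect_equal(p_to_chisq(1), 0)
  expect_equal(p_to_chisq(0.05), 3.8415, tolerance = 1e-4)
  expect_equal(p_to_chisq(0.3173), 1.0, tolerance = 1e-3)
  expect_error(p_to_chisq(0), "\\(0, 1\\]")
  expect_error(p_to_chisq(1.1), "\\(0, 1\\]")
  # round trip through the survival function
  p <- c(0.9, 0.5, 0.01, 1e-6)
  expect_equal(pchisq(p_to_chisq(p), 1, lower.tail = FALSE), p)
})

test_that("lambda estimation is calibrated and scales with inflation", {
  expect_equal(estimate_lambda(rep(0.5, 10))$lam, 1.0, tolerance = 1e-10)
  set.seed(202)
  p <- runif(1e5)
  lam <- estimate_lambda(p)
  expect_equal(lam$lam, 1.0, tolerance = 0.02)
  expect_equal(lam$n_snps, 1e5)
  # doubling every chi-square doubles lambda
  p2 <- pchisq(2 * p_to_chisq(p), 1, lower.tail = FALSE)
  expect_equal(estimate_lambda(p2)$lam, 2 * lam$lam, tolerance = 1e-8)
  expect_error(estimate_lambda(numeric(0)), "no valid")
})

test_that("genomic control deflates chi-squares, never p-values", {
  p <- c(0.5, 0.05, 0.001)
  expect_identical(genomic_control_adjust(p, 1), p)
  adj <- genomic_control_adjust(0.05, 1.05672)
  expect_equal(adj, 0.0566, tolerance = 1e-3)
  set.seed(7)
  p <- runif(500)
  adj <- genomic_control_adjust(p, 1.3)
  expect_true(all(adj >= p))                      # monotone: p_adj >= p
  expect_identical(order(adj), order(p))          # order-preserving
  expect_identical(genomic_control_adjust(p, 0.8), p)  # lam < 1 not applied
  # GC idempotence at null: re-estimated lambda after adjustment ~ 1
  p_infl <- pchisq(1.4 * p_to_chisq(p), 1, lower.tail = FALSE)
  lam <- estimate_lambda(p_infl)
  expect_equal(estimate_lambda(genomic_control_adjust(p_infl, lam))$lam,
               1.0, tolerance = 0.01)
})

test_that("site z-scores standardize within site and equalize means", {
  set.seed(9)
  x <- rnorm(40, 50, 5)
  z <- site_zscores(x, rep("only", 40))
  expect_equal(z, as.numeric(scale(x)))
  site <- rep(c("a", "b"), each = 30)
  x <- c(rnorm(30, 100, 15), rnorm(30, 112, 10))
  z <- site_zscores(x, site)
  for (s in c("a", "b")) {
    expect_equal(mean(z[site == s]), 0, tolerance = 1e-12)
    expect_equal(sd(z[site == s]), 1, tolerance = 1e-12)
  }
  expect_error(site_zscores(c(1, 2, 3), c("a", "a", "b")), "'b'")
  expect_error(site_zscores(c(1, 1, 1), rep("c", 3)), "'c'")
})

test_that("QQ data uses rank-midpoint expected quantiles", {
  one <- qq_data(0.1)
  expect_equal(one$expected, -log10(0.5))
  expect_equal(one$observed, 1)
  same <- qq_data(rep(0.2, 5))
  expect_equal(same$observed, rep(-log10(0.2), 5))
  set.seed(33)
  q <- qq_data(runif(5000))
  # hugs the diagonal away from the noisy extreme tail
  expect_lt(max(abs(q$observed - q$expected)[-(1:20)]), 0.2)
  expect_lt(mean(abs(q$observed - q$expected)), 0.02)
  expect_false(is.unsorted(rev(q$observed)))
})
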