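#' Per-SNP additive linear regression
#'
#' Ordinary least squares of the trait on the allele dosage with an
#' intercept. Individuals missing either value are dropped for that SNP
#' (casewise deletion); the two-sided p-value comes from the t distribution
#' with `n_used - 2` degrees of freedom. SNPs with fewer than 3 complete
#' observations or a constant dosage among them are flagged invalid.
#'
#' @param dosage numeric vector in `{0, 1, 2, NA}`.
#' @param trait numeric trait vector, same length.
#' @param snp_id optional id carried into the result.
#' @return list with `snp_id`, `n_used`, `beta`, `se`, `t_stat`, `df`, `p`,
#'   `chisq` (the 1-df chi-square equivalent of `p`) and `valid`.
#' @export
fit_snp_regression <- function(dosage, trait, snp_id = NA_character_) {
  if (length(dosage) != length(trait))
    stop("dosage and trait lengths differ")
  ok <- !is.na(dosage) & !is.na(trait)
  x <- dosage[ok]; y <- trait[ok]
  n <- length(x)
  res <- list(snp_id = snp_id, n_used = n, beta = NA_real_, se = NA_real_,
              t_stat = NA_real_, df = n - 2L, p = NA_real_,
              chisq = NA_real_, valid = FALSE)
  if (n < 3) return(res)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) return(res)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  rss <- syy - beta * sxy
  dfree <- n - 2L
  if (rss <= 0) {
    # perfect fit: p at the numeric floor
    res$beta <- beta; res$se <- 0; res$t_stat <- Inf
    res$p <- P_FLOOR; res$chisq <- p_to_chisq(P_FLOOR); res$valid <- TRUE
    return(res)
  }
  se <- sqrt(rss / dfree / sxx)
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), dfree)
  p <- max(p, P_FLOOR)
  res$beta <- beta; res$se <- se; res$t_stat <- t
  res$p <- p; res$chisq <- p_to_chisq(p); res$valid <- TRUE
  res
}

# Numeric floor applied to p-values before -log10 to avoid infinities.
P_FLOOR <- 1e-300

# Vectorized per-SNP regression p-values for one or more trait vectors.
#
# G: n x m dosage matrix (NA = missing); Y: n x k matrix of complete trait
# vectors (one column per permutation). Casewise deletion per SNP is exact:
# the sums entering each SNP's OLS use only that SNP's non-missing rows.
# Returns an m x k matrix of two-sided p-values (NA for invalid SNPs).
scan_pvalues <- function(G, Y) {
  n <- nrow(G); m <- ncol(G)
  Y <- as.matrix(Y)
  if (nrow(Y) != n) stop("trait length does not match genotypes")
  if (anyNA(Y)) stop("trait matrix must be complete (drop missing first)")
  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0
  storage.mode(M) <- "double"
  nj <- .colSums(M, n, m)
  sx <- .colSums(G0, n, m)
  sxx <- .colSums(G0 * G0, n, m)
  sy <- crossprod(M, Y)        # m x k
  syy <- crossprod(M, Y * Y)
  sxy <- crossprod(G0, Y)
  sxx_c <- sxx - sx^2 / nj
  syy_c <- syy - sy^2 / nj
  sxy_c <- sxy - (sx / nj) * sy
  dfree <- nj - 2
  valid <- nj >= 3 & sxx_c > 1e-12
  denom <- sxx_c * syy_c
  r2 <- sxy_c^2 / denom
  r2[!valid | denom <= 0] <- NA
  r2 <- pmin(r2, 1)
  tt <- sqrt(r2 * dfree / pmax(1 - r2, 1e-16))
  p <- 2 * stats::pt(-tt, dfree)
  p <- pmax(p, P_FLOOR)
  p[syy_c <= 0 & valid] <- 1  # constant trait: no association signal
  p[!valid] <- NA
  p
}

#' Genome scan: per-SNP regression over a genotype matrix
#'
#' Runs [fit_snp_regression()] for every SNP against one trait vector,
#' with individuals aligned positionally between `geno` and `trait`.
#' Individuals with missing trait are dropped for all SNPs; missing
#' dosages are dropped per SNP.
#'
#' @param geno a [genotype_matrix].
#' @param trait numeric vector, one value per individual in `geno`.
#' @return data.frame of class `snp_assoc` with one row per SNP:
#'   `snp_id`, `chrom`, `pos`, `n_used`, `beta`, `se`, `t_stat`, `df`,
#'   `p`, `chisq`, `valid`. Order follows `geno$snps`.
#' @export
assoc_scan <- function(geno, trait) {
  if (length(trait) != length(geno$individuals))
    stop("trait length (", length(trait), ") does not match individuals (",
         length(geno$individuals), ")")
  keep <- !is.na(trait)
  G <- geno$dosage[keep, , drop = FALSE]
  y <- trait[keep]
  n <- nrow(G); m <- ncol(G)
  M <- !is.na(G)
  storage.mode(M) <- "double"
  G0 <- G; G0[is.na(G)] <- 0
  nj <- .colSums(M, n, m)
  sx <- .colSums(G0, n, m)
  sxx <- .colSums(G0 * G0, n, m)
  sy <- drop(crossprod(M, y))
  syy <- drop(crossprod(M, y * y))
  sxy <- drop(crossprod(G0, y))
  sxx_c <- sxx - sx^2 / nj
  syy_c <- syy - sy^2 / nj
  sxy_c <- sxy - sx * sy / nj
  dfree <- nj - 2
  valid <- nj >= 3 & sxx_c > 1e-12
  beta <- ifelse(valid, sxy_c / sxx_c, NA_real_)
  rss <- syy_c - beta * sxy_c
  perfect <- valid & rss <= 0
  se <- ifelse(valid & rss > 0, sqrt(rss / dfree / sxx_c), NA_real_)
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), dfree)
  p <- pmax(p, P_FLOOR)
  p[perfect] <- P_FLOOR
  se[perfect] <- 0
  t[perfect] <- Inf
  p[!valid] <- NA
  if (!any(valid)) stop("no analyzable SNPs (all monomorphic or n < 3)")
  out <- data.frame(snp_id = geno$snps$snp_id, chrom = geno$snps$chrom,
                    pos = geno$snps$pos, n_used = as.integer(nj),
                    beta = beta, se = se, t_stat = t,
                    df = as.integer(dfree), p = p,
                    chisq = ifelse(is.na(p), NA_real_, p_to_chisq(pmax(p, P_FLOOR))),
                    valid = valid, stringsAsFactors = FALSE)
  class(out) <- c("snp_assoc", "data.frame")
  out
}

#' Convert a two-sided p-value to its 1-df chi-square equivalent
#'
#' @param p p-value(s) in `(0, 1]`.
#' @return Quantile of the central chi-square distribution (1 df) at `1 - p`.
#' @export
p_to_chisq <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::qchisq(p, df = 1, lower.tail = FALSE)
}

# Median of the central 1-df chi-square distribution.
CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1)  # 0.4549364

#' Estimate the genomic inflation factor lambda
#'
#' Median of the per-SNP 1-df chi-square statistics divided by the null
#' median of the central chi-square(1) distribution (0.45494). Values
#' above 1 indicate inflation, e.g. from population stratification.
#'
#' @param pvals vector of p-values in `(0, 1]`; `NA`s are dropped.
#' @return list of class `lambda_estimate` with `lam` and `n_snps`.
#' @export
estimate_lambda <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) stop("no valid p-values for lambda estimation")
  lam <- stats::median(p_to_chisq(pvals)) / CHISQ1_MEDIAN
  structure(list(lam = lam, n_snps = length(pvals)),
            class = "lambda_estimate")
}

#' @export
print.lambda_estimate <- function(x, ...) {
  cat(sprintf("genomic inflation factor lambda = %.5f (%d SNPs)\n",
              x$lam, x$n_snps))
  invisible(x)
}

#' Genomic-control adjustment of p-values
#'
#' Divides each SNP's 1-df chi-square by lambda and converts back to a
#' p-value. Following the standard convention, lambda below 1 is not
#' applied (no deflation), so the adjustment never makes p-values smaller.
#'
#' @param pvals vector of p-values in `(0, 1]` (`NA` passed through).
#' @param lam a `lambda_estimate` or a single number.
#' @return Adjusted p-values, same length and order.
#' @export
genomic_control_adjust <- function(pvals, lam) {
  if (inherits(lam, "lambda_estimate")) lam <- lam$lam
  if (!is.numeric(lam) || length(lam) != 1 || lam <= 0)
    stop("lam must be a positive scalar")
  if (lam <= 1) return(pvals)
  ok <- !is.na(pvals)
  out <- pvals
  out[ok] <- stats::pchisq(p_to_chisq(pvals[ok]) / lam, df = 1,
                           lower.tail = FALSE)
  out
}

#' Standardize a trait within collection sites
#'
#' Within each site the trait is centered and scaled to mean 0, SD 1
#' (sample SD, n-1 denominator), removing between-site mean and scale
#' differences before association analysis.
#'
#' @param trait numeric vector (`NA` allowed, passed through).
#' @param site site labels, same length.
#' @return Standardized trait vector.
#' @export
site_zscores <- function(trait, site) {
  if (length(trait) != length(site)) stop("trait and site lengths differ")
  out <- rep(NA_real_, length(trait))
  for (s in unique(site)) {
    idx <- which(site == s)
    v <- trait[idx]
    obs <- v[!is.na(v)]
    if (length(obs) < 2)
      stop("site '", s, "' has fewer than 2 non-missing trait values")
    sdv <- stats::sd(obs)
    if (sdv == 0) stop("site '", s, "' has zero trait variance")
    out[idx] <- (v - mean(obs)) / sdv
  }
  out
}

#' Expected vs observed quantiles for a QQ plot
#'
#' @param pvals vector of p-values; `NA`s dropped.
#' @return data.frame with columns `expected` and `observed`, both on the
#'   -log10 scale, largest observed first. `expected[i] = -log10((i - 0.5)/m)`
#'   for rank i of m.
#' @export
qq_data <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) stop("no p-values for QQ data")
  m <- length(pvals)
  obs <- sort(-log10(pmax(pvals, P_FLOOR)), decreasing = TRUE)
  expd <- -log10((seq_len(m) - 0.5) / m)
  data.frame(expected = expd, observed = obs)
}
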