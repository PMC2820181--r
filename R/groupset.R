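#' Sum of -log10 p-values
#'
#' The group test statistic: the sum over a set of SNPs of -log10 of the
#' per-SNP association p-value (the observed value is conventionally called
#' X, its permutation replicates Y). Deterministic and order-independent.
#'
#' @param pvals p-values in `(0, 1]`; invalid SNPs must already be excluded.
#' @param floor numeric floor applied before the log to avoid infinities.
#' @return Sum of `-log10(p)`.
#' @export
sum_neglog10 <- function(pvals, floor = P_FLOOR) {
  if (!length(pvals)) stop("empty p-value list")
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1] with no NA")
  sum(-log10(pmax(pvals, floor)))
}

#' Empirical p-value from permutation replicates
#'
#' The fraction of permutation statistics strictly exceeding the observed
#' statistic; ties count as non-exceedance, so the estimate can be 0. The
#' add-one smoothed estimator `(b + 1)/(N + 1)` is available via `smooth`.
#'
#' @param x_obs observed statistic X.
#' @param y_perm vector of permutation statistics Y.
#' @param smooth use the add-one estimator instead of the plain fraction.
#' @return Empirical p-value.
#' @export
empirical_p <- function(x_obs, y_perm, smooth = FALSE) {
  if (!length(y_perm)) stop("no permutation statistics")
  b <- sum(y_perm > x_obs)
  if (smooth) (b + 1) / (length(y_perm) + 1) else b / length(y_perm)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise significance level in `(0, 1)`.
#' @param n_groups number of groups tested.
#' @return `alpha / n_groups` at full precision, with a `display`
#'   attribute rounded to 4 decimals.
#' @export
bonferroni_threshold <- function(alpha, n_groups) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_groups < 1) stop("n_groups must be >= 1")
  thr <- alpha / n_groups
  attr(thr, "display") <- round(thr, 4)
  thr
}

#' Define a permutation plan
#'
#' @param n_perm number of phenotype permutations (default 10,000).
#' @param seed master seed; the shuffle for permutation i is derived
#'   deterministically from `(seed, i)`, so runs are reproducible and
#'   individual permutations re-derivable.
#' @param escalate re-run groups with very small empirical p at
#'   `n_perm_max` permutations.
#' @param escalate_if_below escalation trigger on the initial empirical p;
#'   the default `20 / n_perm` ensures a reported small p is never
#'   supported by fewer than 20 exceedances unless already at maximum.
#' @param n_perm_max permutation count after escalation (default 100,000).
#' @param smooth use the add-one empirical p estimator (off by default;
#'   the plain fraction of strict exceedances is the reference behavior).
#' @return list of class `permutation_plan`.
#' @export
permutation_plan <- function(n_perm = 10000, seed = 1, escalate = TRUE,
                             escalate_if_below = 20 / n_perm,
                             n_perm_max = 100000, smooth = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 escalate = escalate,
                 escalate_if_below = escalate_if_below,
                 n_perm_max = as.integer(n_perm_max), smooth = smooth),
            class = "permutation_plan")
}

# Deterministic 32-bit seed for permutation i under master seed s.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 69621) %% 2147483647L)
}

# Shuffled index vector for permutation i.
derive_perm <- function(seed, i, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(derive_seed(seed, i))
  sample.int(n)
}

#' Group association test by phenotype permutation
#'
#' Computes the observed sum of -log10 per-SNP regression p-values (X) for
#' each gene-group SNP index, then permutes the phenotype vector over
#' individuals `n_perm` times. Each permutation re-runs the full per-SNP
#' scan over the union of indexed SNPs and yields one replicate statistic Y
#' per group; a single shared shuffle serves all groups within a
#' permutation. The genotype matrix is never touched, so the LD structure
#' — every pairwise dosage correlation — is identical in every replicate,
#' and each group keeps its exact SNP count, gene count and sample size
#' under the null. The empirical p-value is the fraction of permutations
#' with Y strictly greater than X.
#'
#' SNPs flagged invalid in the observed scan (monomorphic, n < 3) are
#' excluded from their groups in the observed statistic and in every
#' permutation, keeping X and Y on identical SNP sets.
#'
#' @param geno a [genotype_matrix].
#' @param trait numeric trait vector aligned with `geno$individuals`;
#'   individuals with missing trait are dropped before permutation.
#' @param indexes list of group SNP indexes from [build_group_index()];
#'   empty groups are skipped with a warning.
#' @param plan a [permutation_plan()].
#' @param chunk permutations evaluated per matrix-multiplication batch
#'   (memory/speed trade-off; does not affect results).
#' @param gc_lambda optional genomic-control inflation factor applied (when
#'   above 1) to every per-SNP p-value entering the statistic, observed and
#'   permuted alike — a monotone transform shared across replicates.
#' @return data.frame of class `group_result` with one row per group:
#'   `group_name`, `n_genes`, `n_snps`, `sum_stat` (X), `emp_p`, `n_perm`,
#'   `perm_exceed`, `n_snps_excluded`. Attribute `perm_stats` holds the
#'   matrix of Y draws from the initial (pre-escalation) pass.
#' @export
permutation_test <- function(geno, trait, indexes, plan = permutation_plan(),
                             chunk = 100L, gc_lambda = 1) {
  if (inherits(gc_lambda, "lambda_estimate")) gc_lambda <- gc_lambda$lam
  if (!inherits(plan, "permutation_plan")) stop("plan must be a permutation_plan")
  if (length(trait) != length(geno$individuals))
    stop("trait length does not match genotype individuals")
  if (!length(indexes)) stop("no group indexes supplied")
  if (inherits(indexes, "group_snp_index")) indexes <- list(indexes)

  empty <- vapply(indexes, function(ix) length(ix$snp_ids) == 0, logical(1))
  if (any(empty)) {
    warning("skipping group(s) with empty SNP index: ",
            paste(vapply(indexes[empty], `[[`, "", "group_name"),
                  collapse = ", "), call. = FALSE)
    indexes <- indexes[!empty]
    if (!length(indexes)) stop("all group indexes are empty")
  }
  unknown <- unique(unlist(lapply(indexes, function(ix)
    setdiff(ix$snp_ids, geno$snps$snp_id))))
  if (length(unknown))
    stop("group index references unknown SNPs: ",
         paste(utils::head(unknown, 5), collapse = ", "))

  keep <- !is.na(trait)
  y <- trait[keep]
  union_ids <- unique(unlist(lapply(indexes, `[[`, "snp_ids")))
  col <- match(union_ids, geno$snps$snp_id)
  G <- geno$dosage[keep, col, drop = FALSE]
  n <- nrow(G)

  # observed scan on the union of indexed SNPs
  p_obs <- drop(scan_pvalues(G, matrix(y, ncol = 1)))
  invalid <- is.na(p_obs)
  if (gc_lambda > 1) p_obs <- genomic_control_adjust(p_obs, gc_lambda)

  # group membership matrix over valid union SNPs (m x g)
  A <- vapply(indexes, function(ix) union_ids %in% ix$snp_ids,
              logical(length(union_ids)))
  A <- matrix(A, nrow = length(union_ids))
  n_excl <- as.integer(colSums(A & invalid))
  A[invalid, ] <- FALSE
  if (any(colSums(A) == 0))
    stop("group(s) left with no valid SNPs after exclusions: ",
         paste(names(indexes)[colSums(A) == 0], collapse = ", "))
  storage.mode(A) <- "double"

  nl_obs <- -log10(pmax(p_obs, P_FLOOR))
  nl_obs[invalid] <- 0
  X <- drop(crossprod(A, nl_obs))

  run_perms <- function(n_perm, collect = FALSE) {
    exceed <- numeric(ncol(A))
    Ystats <- if (collect) matrix(NA_real_, ncol(A), n_perm) else NULL
    i <- 0L
    while (i < n_perm) {
      k <- min(chunk, n_perm - i)
      Yp <- vapply(seq_len(k) + i, function(j) y[derive_perm(plan$seed, j, n)],
                   numeric(n))
      P <- scan_pvalues(G, Yp)
      if (gc_lambda > 1) P <- genomic_control_adjust(P, gc_lambda)
      NL <- -log10(pmax(P, P_FLOOR))
      NL[is.na(P)] <- 0
      Ysum <- crossprod(A, NL)            # g x k
      exceed <- exceed + rowSums(Ysum > X)
      if (collect) Ystats[, seq_len(k) + i] <- Ysum
      i <- i + k
    }
    list(exceed = exceed, stats = Ystats)
  }

  first <- run_perms(plan$n_perm, collect = TRUE)
  emp_p <- if (plan$smooth) (first$exceed + 1) / (plan$n_perm + 1)
           else first$exceed / plan$n_perm
  n_perm_used <- rep(plan$n_perm, ncol(A))
  exceed <- first$exceed

  if (plan$escalate && plan$n_perm_max > plan$n_perm) {
    esc <- which(emp_p < plan$escalate_if_below)
    if (length(esc)) {
      # re-run from scratch at the larger size; shuffles reuse the same
      # derivation so draws 1..n_perm are shared, the rest are new
      full <- run_perms(plan$n_perm_max)
      emp_p[esc] <- if (plan$smooth)
        (full$exceed[esc] + 1) / (plan$n_perm_max + 1)
      else full$exceed[esc] / plan$n_perm_max
      exceed[esc] <- full$exceed[esc]
      n_perm_used[esc] <- plan$n_perm_max
    }
  }

  out <- data.frame(
    group_name = names(indexes),
    n_genes = vapply(indexes, `[[`, 0L, "n_genes_covered"),
    n_snps = as.integer(colSums(A)),
    sum_stat = X,
    emp_p = emp_p,
    n_perm = as.integer(n_perm_used),
    perm_exceed = as.integer(exceed),
    n_snps_excluded = n_excl,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "perm_stats") <- first$stats
  class(out) <- c("group_result", "data.frame")
  out
}
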