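#' Random-mating next-generation genotype distribution
#'
#' Given the current genotype frequencies `P = [p0, p1, p2]` of the
#' classes AA / Aa / aa at a bi-allelic site, returns the genotype
#' distribution expected among offspring under random mating:
#' with allele frequencies `a = p0 + p1/2` (major) and `b = p2 + p1/2`
#' (minor), the next generation is `[a^2, 2ab, b^2]` — the
#' Hardy-Weinberg proportions, reached in a single generation.
#'
#' @param p Numeric vector of length 3 on the probability simplex.
#' @param tol Tolerance for the simplex-sum check.
#' @return Numeric vector of length 3 summing to 1 (up to floating error).
#' @export
#' @examples
#' next_gen_distribution(c(0.5, 0, 0.5))  # heterozygote frequency 0.5
next_gen_distribution <- function(p, tol = 1e-8) {
  if (length(p) != 3L || anyNA(p))
    stop("p must be a numeric vector of 3 genotype frequencies")
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > tol)
    stop("p must lie on the probability simplex (components in [0,1], sum 1)")
  a <- p[1L] + p[2L] / 2
  b <- p[3L] + p[2L] / 2
  c(a * a, 2 * a * b, b * b)
}

#' Log-probability that a genotype class is never observed
#'
#' The count of a genotype class with frequency `p_star` among `n`
#' sampled individuals is binomial(n, p_star); the probability of
#' observing zero is `(1 - p_star)^n`. Returned on the natural-log scale
#' as `n * log1p(-p_star)`, which stays accurate for small `p_star` where
#' `log(1 - p_star)` would lose precision.
#'
#' @param p_star Expected class frequency in `[0, 1]`.
#' @param n Non-negative integer sample size.
#' @return The log-probability (`0` when `n == 0` or `p_star == 0`;
#'   `-Inf` when `p_star == 1` with `n >= 1`).
#' @export
log_prob_zero_observed <- function(p_star, n) {
  if (length(p_star) != 1L || is.na(p_star) || p_star < 0 || p_star > 1)
    stop("p_star must be a single frequency in [0, 1]")
  if (length(n) != 1L || is.na(n) || n < 0 || n != round(n))
    stop("n must be a single non-negative integer")
  if (n == 0 || p_star == 0) return(0)
  if (p_star == 1) return(-Inf)
  n * log1p(-p_star)
}

#' Combine per-population zero-observation probabilities
#'
#' The event that a genotype class is unseen in every population is the
#' intersection of the independent per-population events, so its
#' probability is the product of the per-population probabilities —
#' computed here as a sum of log-probabilities to avoid underflow (a
#' combined probability below double precision is reported as 0 with the
#' exact log retained).
#'
#' @param log_probs Numeric vector of per-population log-probabilities
#'   (each `<= 0`; tiny positive rounding residue is clamped to 0).
#' @return List with `log_p_value` and `p_value`.
#' @export
combine_populations <- function(log_probs) {
  if (length(log_probs) == 0L) stop("log_probs must be non-empty")
  if (anyNA(log_probs)) stop("log_probs contains NA")
  if (any(log_probs > 1e-12))
    stop("log-probabilities must be <= 0; got ", max(log_probs))
  log_probs <- pmin(log_probs, 0)
  lp <- sum(log_probs)
  list(log_p_value = lp, p_value = exp(lp))
}

#' Bonferroni-corrected significance threshold
#'
#' For `k` SNPs, each of the three genotype classes is a separate
#' hypothesis, giving `3k` tests; the family-wise threshold at level
#' `alpha` is `alpha / (3k)`.
#'
#' @param k Number of SNPs tested (>= 1).
#' @param alpha Significance level in (0, 1).
#' @return The per-test threshold `alpha / (3 * k)`.
#' @export
bonferroni_threshold <- function(k, alpha = 0.05) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != round(k))
    stop("k must be a positive integer")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  alpha / (3 * k)
}

#' Test whether an unobserved genotype class is improbably absent
#'
#' Applies the screen's statistic to one harmonized SNP and one genotype
#' class `i` (0 = major homozygote, 1 = heterozygote, 2 = minor
#' homozygote). The test is defined only when the class has a zero count
#' in *every* population; otherwise `NULL` is returned. For each
#' population the current genotype distribution `P` is estimated from its
#' called genotypes, propagated one generation of random mating to `P*`,
#' and the probability that a sample of size `n_j` contains no individual
#' of class `i` is computed; the per-population probabilities are then
#' multiplied across populations.
#'
#' @param counts A `multipop_counts` object from [harmonize_snps()].
#' @param i Genotype class index, 0, 1 or 2.
#' @param n_source `"called"` (default) uses the per-SNP called-genotype
#'   count as the binomial sample size; `"panel"` uses the full panel
#'   size, treating missing calls as potential observations.
#' @return A `lethal_test` object, or `NULL` when the class was observed
#'   somewhere. Fields `k_tested`, `threshold`, `flagged` are `NA` until
#'   filled by the screening driver.
#' @export
test_genotype_class <- function(counts, i, n_source = c("called", "panel")) {
  n_source <- match.arg(n_source)
  if (!i %in% c(0, 1, 2)) stop("genotype class i must be 0, 1 or 2")
  cdf <- counts$counts
  obs <- cdf[[c("n0", "n1", "n2")[i + 1L]]]
  if (any(obs > 0)) return(NULL)
  if (any(cdf$n_called < 1))
    stop("population with no called genotypes reached the test: ",
         cdf$population[cdf$n_called < 1][1L])

  npop <- nrow(cdf)
  p_star <- numeric(npop); expectation <- numeric(npop)
  log_prob <- numeric(npop)
  n_used <- if (n_source == "called") cdf$n_called else cdf$panel_size
  for (j in seq_len(npop)) {
    P <- c(cdf$n0[j], cdf$n1[j], cdf$n2[j]) / cdf$n_called[j]
    Pstar <- next_gen_distribution(P)
    p_star[j] <- Pstar[i + 1L]
    expectation[j] <- n_used[j] * p_star[j]
    log_prob[j] <- log_prob_zero_observed(p_star[j], n_used[j])
  }
  comb <- combine_populations(log_prob)

  geno <- c(paste0(counts$major, counts$major),
            paste0(counts$major, counts$minor),
            paste0(counts$minor, counts$minor))[i + 1L]
  structure(
    list(snp = counts[c("rsid", "chrom", "pos", "major", "minor", "strand")],
         genotype_class = i, genotype_label = geno,
         populations = cdf$population,
         n_source = n_source, n_used = n_used,
         per_pop_pstar = p_star,
         per_pop_expectation = expectation,
         per_pop_log_prob = log_prob,
         log_p_value = comb$log_p_value, p_value = comb$p_value,
         k_tested = NA_integer_, threshold = NA_real_, flagged = NA),
    class = "lethal_test")
}

#' @export
print.lethal_test <- function(x, ...) {
  cat("<lethal_test> ", x$snp$rsid, " chr", x$snp$chrom, ":", x$snp$pos,
      "  missing genotype ", x$genotype_label,
      " (class g", x$genotype_class, ")\n", sep = "")
  cat("  expected carriers: ",
      paste(sprintf("%s=%.1f", x$populations, x$per_pop_expectation),
            collapse = " "), "\n", sep = "")
  cat(sprintf("  total expectation %.1f; p-value %s (log10 %.2f)\n",
              sum(x$per_pop_expectation), format_pvalue(x$p_value),
              x$log_p_value / log(10)))
  if (!is.na(x$flagged))
    cat("  flagged:", x$flagged, "at threshold",
        format_pvalue(x$threshold), "over", x$k_tested, "SNPs\n")
  invisible(x)
}
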