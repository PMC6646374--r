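#' Screen one chromosome for improbably absent genotype classes
#'
#' Harmonizes the per-population tables, tests every retained SNP and
#' every genotype class that is unobserved in all populations, and flags
#' results whose combined p-value falls below the Bonferroni threshold
#' `alpha / (3k)`, where `k` is the number of retained SNPs. Flagged
#' results are sorted by ascending p-value with ties broken by
#' (chrom, pos, rsid), so output is deterministic and independent of the
#' order in which SNPs or population files were supplied.
#'
#' @param tables List of [genotype_table()] objects, one per population,
#'   all from the same autosome.
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_source Binomial sample size: per-SNP `"called"` genotypes
#'   (default) or full `"panel"` size; see [test_genotype_class()].
#' @param min_call_rate,min_maf Harmonization filters, see
#'   [harmonize_snps()].
#' @return A `scan_summary` list: `chrom`, `n_input_snps` (distinct rsids
#'   across the input tables), `n_tested_snps` (`k`), `n_hypotheses`
#'   (`3k`), `threshold` (`NaN` when `k == 0`), `n_flagged` (distinct
#'   flagged rsids), `n_flagged_tests` (flagged SNP/class pairs),
#'   `results` (flagged tests), `tested` (all computed tests) and a `qc`
#'   drop-reason table.
#' @export
scan_chromosome <- function(tables, alpha = 0.05,
                            n_source = c("called", "panel"),
                            min_call_rate = 0, min_maf = 0) {
  n_source <- match.arg(n_source)
  chroms <- unique(unlist(lapply(tables, function(t) t$snps$chrom)))
  if (length(chroms) > 1L)
    stop("tables span several chromosomes: ", paste(chroms, collapse = ", "))
  if (length(chroms) == 1L && !chroms %in% autosome_labels())
    stop("not an autosome: ", chroms)

  harmonized <- harmonize_snps(tables, min_call_rate = min_call_rate,
                               min_maf = min_maf)
  k <- length(harmonized)
  n_input <- length(unique(unlist(lapply(tables, function(t) t$snps$rsid))))

  threshold <- if (k >= 1L) bonferroni_threshold(k, alpha) else NaN

  tested <- list()
  for (mpc in harmonized) {
    zero0 <- all(mpc$counts$n0 == 0)
    zero1 <- all(mpc$counts$n1 == 0)
    zero2 <- all(mpc$counts$n2 == 0)
    for (i in which(c(zero0, zero1, zero2)) - 1L) {
      res <- test_genotype_class(mpc, i, n_source = n_source)
      if (is.null(res)) next
      res$k_tested <- k
      res$threshold <- threshold
      res$flagged <- is.finite(threshold) && res$p_value < threshold
      tested[[length(tested) + 1L]] <- res
    }
  }

  flagged <- Filter(function(r) isTRUE(r$flagged), tested)
  if (length(flagged) > 0) {
    ord <- order(vapply(flagged, `[[`, numeric(1), "p_value"),
                 vapply(flagged, function(r) r$snp$chrom, character(1)),
                 vapply(flagged, function(r) r$snp$pos, numeric(1)),
                 vapply(flagged, function(r) r$snp$rsid, character(1)))
    flagged <- flagged[ord]
  }

  structure(
    list(chrom = if (length(chroms) == 1L) chroms else NA_character_,
         alpha = alpha, n_source = n_source,
         n_input_snps = n_input, n_tested_snps = k,
         n_hypotheses = 3L * k, threshold = threshold,
         n_flagged = length(unique(vapply(flagged, function(r) r$snp$rsid,
                                          character(1)))),
         n_flagged_tests = length(flagged),
         results = flagged, tested = tested,
         qc = attr(harmonized, "qc")),
    class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat("<scan_summary> chromosome ", x$chrom, ": ", x$n_tested_snps,
      " SNPs tested (", x$n_hypotheses, " hypotheses), threshold ",
      format_pvalue(x$threshold), ", ", x$n_flagged, " SNP(s) flagged\n",
      sep = "")
  for (r in x$results)
    cat(sprintf("  %s chr%s:%d  %s absent  p = %s\n", r$snp$rsid,
                r$snp$chrom, r$snp$pos, r$genotype_label,
                format_pvalue(r$p_value)))
  invisible(x)
}

#' Screen several chromosomes
#'
#' Runs [scan_chromosome()] independently on each element of
#' `tables_by_chrom`. With the default `"per-chromosome"` correction each
#' chromosome uses its own Bonferroni threshold `alpha / (3 k_c)`;
#' `"genome-wide"` instead re-flags every test against
#' `alpha / (3 * sum(k_c))`, which is never more permissive.
#'
#' @param tables_by_chrom Named list: autosome label -> list of
#'   population [genotype_table()]s for that chromosome.
#' @param alpha Family-wise significance level.
#' @param n_source See [test_genotype_class()].
#' @param correction `"per-chromosome"` (default) or `"genome-wide"`.
#' @param min_call_rate,min_maf Passed to [harmonize_snps()].
#' @return A `genome_scan` list with per-chromosome `summaries`, the
#'   correction mode, total SNP and flag counts.
#' @export
scan_genome <- function(tables_by_chrom, alpha = 0.05,
                        n_source = c("called", "panel"),
                        correction = c("per-chromosome", "genome-wide"),
                        min_call_rate = 0, min_maf = 0) {
  n_source <- match.arg(n_source)
  correction <- match.arg(correction)
  chroms <- names(tables_by_chrom)
  if (length(tables_by_chrom) > 0 &&
      (is.null(chroms) || !all(normalize_chrom(chroms) %in% autosome_labels())))
    stop("tables_by_chrom must be named by autosome (\"1\"..\"22\")")
  names(tables_by_chrom) <- normalize_chrom(chroms)

  summaries <- lapply(tables_by_chrom, scan_chromosome, alpha = alpha,
                      n_source = n_source, min_call_rate = min_call_rate,
                      min_maf = min_maf)

  k_total <- sum(vapply(summaries, `[[`, integer(1), "n_tested_snps"))
  if (correction == "genome-wide") {
    threshold <- if (k_total >= 1L) bonferroni_threshold(k_total, alpha)
                 else NaN
    summaries <- lapply(summaries, function(s) {
      s$threshold <- threshold
      s$tested <- lapply(s$tested, function(r) {
        r$k_tested <- k_total
        r$threshold <- threshold
        r$flagged <- is.finite(threshold) && r$p_value < threshold
        r
      })
      flagged <- Filter(function(r) isTRUE(r$flagged), s$tested)
      if (length(flagged) > 0) {
        ord <- order(vapply(flagged, `[[`, numeric(1), "p_value"),
                     vapply(flagged, function(r) r$snp$chrom, character(1)),
                     vapply(flagged, function(r) r$snp$pos, numeric(1)),
                     vapply(flagged, function(r) r$snp$rsid, character(1)))
        flagged <- flagged[ord]
      }
      s$results <- flagged
      s$n_flagged <- length(unique(vapply(flagged, function(r) r$snp$rsid,
                                          character(1))))
      s$n_flagged_tests <- length(flagged)
      s
    })
  }

  structure(
    list(summaries = summaries, alpha = alpha, n_source = n_source,
         correction = correction, k_total = k_total,
         n_flagged = sum(vapply(summaries, `[[`, integer(1), "n_flagged")),
         n_flagged_tests = sum(vapply(summaries, `[[`, integer(1),
                                      "n_flagged_tests"))),
    class = "genome_scan")
}

#' @export
print.genome_scan <- function(x, ...) {
  cat("<genome_scan> ", length(x$summaries), " chromosome(s), ",
      x$k_total, " SNPs tested, ", x$n_flagged, " flagged (",
      x$correction, " Bonferroni at alpha = ", x$alpha, ")\n", sep = "")
  for (s in x$summaries) print(s)
  invisible(x)
}

#' Collect flagged results of a genome scan
#'
#' @param scan A `genome_scan` object.
#' @return A single list of flagged `lethal_test` results across
#'   chromosomes, ordered by (chrom, p-value).
#' @export
flagged_results <- function(scan) {
  unlist(lapply(scan$summaries, `[[`, "results"), recursive = FALSE,
         use.names = FALSE)
}
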