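#' Worked-example expectation tables
#'
#' Per-population expected carrier counts of the missing genotype class
#' for two suspicious HapMap SNPs (rs2145402, the 'AA' class near LYST,
#' and rs4915931, the 'AA' class near ROR1), shipped with the package as
#' a desk-checkable worked example. Combined with the panel sizes of
#' [hapmap_populations()], these reproduce the screen's headline p-values
#' via [pvalue_from_expected_counts()].
#'
#' @return Data frame with columns `rsid`, `population`, `expected_count`.
#' @export
worked_example_expectations <- function() {
  path <- system.file("extdata", "worked_example_expected_counts.tsv",
                      package = "lethalscan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Recompute a combined p-value from expected carrier counts
#'
#' Inverts the expectation `E_j = n_j * p*_j` to recover the
#' per-population expected class frequency, evaluates the
#' zero-observation probability `(1 - p*_j)^{n_j}` for each population,
#' and multiplies across populations. This is the desk route for checking
#' a reported screen hit from its published per-population expectation
#' row and the panel sizes alone.
#'
#' @param expected_counts Numeric vector of per-population expected
#'   counts of the missing class.
#' @param sample_sizes Integer vector of matching population sample
#'   sizes.
#' @return List with `log_p_value` and `p_value`, as
#'   [combine_populations()].
#' @export
pvalue_from_expected_counts <- function(expected_counts, sample_sizes) {
  if (length(expected_counts) != length(sample_sizes))
    stop("expected_counts and sample_sizes must have equal length")
  if (any(expected_counts < 0) || any(expected_counts > sample_sizes))
    stop("expected counts must lie in [0, sample size]")
  lp <- mapply(log_prob_zero_observed,
               p_star = expected_counts / sample_sizes, n = sample_sizes)
  combine_populations(lp)
}
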