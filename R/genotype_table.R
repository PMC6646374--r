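#' Construct a per-population genotype table
#'
#' A `genotype_table` holds the diploid genotype calls of one population
#' sample at a set of SNPs: a SNP metadata table, an ordered vector of
#' individual IDs, and a character matrix of two-letter genotype strings
#' (rows = SNPs, columns = individuals). `"NN"` marks a missing call; any
#' call containing `N` is treated as fully missing downstream.
#'
#' @param population Population label, e.g. `"CEU"`.
#' @param individuals Character vector of sample IDs (column order of
#'   `calls`).
#' @param snps Data frame with columns `rsid`, `chrom` (autosome label
#'   `"1"`..`"22"`), `pos` (1-based integer), `allele1`, `allele2` (single
#'   characters in A/C/G/T), `strand` (`"+"` or `"-"`).
#' @param calls Character matrix, `nrow(snps)` rows by
#'   `length(individuals)` columns, each entry matching `[ACGTN]{2}`.
#' @param validate Check all invariants (set `FALSE` only for trusted
#'   internally generated data).
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(population, individuals, snps, calls,
                           validate = TRUE) {
  if (is.null(dim(calls))) {
    calls <- matrix(calls, nrow = nrow(snps), ncol = length(individuals),
                    byrow = TRUE)
  }
  storage.mode(calls) <- "character"
  rownames(calls) <- snps$rsid
  tab <- structure(
    list(population = as.character(population),
         individuals = as.character(individuals),
         snps = snps,
         calls = calls),
    class = "genotype_table")
  if (validate) validate_genotype_table(tab)
  tab
}

validate_genotype_table <- function(tab) {
  snps <- tab$snps
  needed <- c("rsid", "chrom", "pos", "allele1", "allele2", "strand")
  missing_cols <- setdiff(needed, names(snps))
  if (length(missing_cols) > 0L)
    stop("snps table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(snps$rsid))
    stop("duplicate rsid in genotype table: ",
         snps$rsid[duplicated(snps$rsid)][1L])
  if (nrow(snps) > 0 && any(snps$pos < 1L))
    stop("SNP positions must be >= 1 (1-based coordinates)")
  bad_allele <- !(snps$allele1 %in% c("A", "C", "G", "T")) |
    !(snps$allele2 %in% c("A", "C", "G", "T"))
  if (any(bad_allele))
    stop("non-ACGT allele for rsid ", snps$rsid[which(bad_allele)[1L]])
  if (nrow(tab$calls) != nrow(snps))
    stop("calls matrix has ", nrow(tab$calls), " rows for ", nrow(snps), " SNPs")
  if (ncol(tab$calls) != length(tab$individuals))
    stop("calls matrix has ", ncol(tab$calls), " columns for ",
         length(tab$individuals), " individuals")
  if (length(tab$calls) > 0) {
    ok <- grepl("^[ACGTN]{2}$", tab$calls)
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      stop("invalid genotype call '", tab$calls[bad], "' at SNP ",
           snps$rsid[(bad - 1L) %% nrow(snps) + 1L])
    }
  }
  invisible(tab)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> population ", x$population, ": ",
      nrow(x$snps), " SNPs x ", length(x$individuals), " individuals\n",
      sep = "")
  if (nrow(x$snps) > 0) {
    chroms <- unique(x$snps$chrom)
    cat("  chromosome(s): ", paste(chroms, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of SNPs / individuals in a genotype table
#' @param tab A `genotype_table`.
#' @return Integer count.
#' @export
n_snps <- function(tab) nrow(tab$snps)

#' @rdname n_snps
#' @export
n_individuals <- function(tab) length(tab$individuals)

# Complement calls (both characters) for minus-strand reconciliation.
# chartr maps N -> N so missing calls pass through unchanged.
complement_calls <- function(calls) chartr("ACGTN", "TGCAN", calls)

complement_alleles <- function(a) chartr("ACGT", "TGCA", a)

autosome_labels <- function() as.character(1:22)

normalize_chrom <- function(x) sub("^chr", "", x, ignore.case = TRUE)
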