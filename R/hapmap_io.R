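#' Read a HapMap phase-3-style genotype file
#'
#' Parses one whitespace-delimited genotype text file for one population.
#' The header line carries `rs# alleles chrom pos strand`, then
#' `n_meta_cols - 5` further metadata columns (assembly, center, LSIDs,
#' QC code in the phase-3 dialect), then one column per individual. Each
#' subsequent line is one SNP; genotype tokens are two-letter strings over
#' A/C/G/T/N with `"NN"` meaning missing.
#'
#' Rows on X, Y or mitochondrial chromosomes are dropped with a warning:
#' the random-mating genotype expectation used downstream only applies to
#' autosomes. A leading `"chr"` on chromosome labels is stripped.
#'
#' @param path Path to the genotype file.
#' @param population Population label; defaults to the file name stem.
#' @param n_meta_cols Number of non-individual leading columns (11 in
#'   HapMap phase 3: rs#, alleles, chrom, pos, strand, assembly#, center,
#'   protLSID, assayLSID, panelLSID, QCcode). Must be >= 5.
#'
#' @return A [genotype_table()].
#' @export
read_hapmap_genotypes <- function(path, population = NULL, n_meta_cols = 11L) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (n_meta_cols < 5L) stop("n_meta_cols must be >= 5")
  if (is.null(population))
    population <- sub("\\.[^.]*$", "", basename(path))

  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("file is empty (no header line): ", path)

  header <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  if (length(header) < n_meta_cols)
    stop("header has ", length(header), " columns; expected at least ",
         n_meta_cols, " metadata columns")
  individuals <- if (length(header) > n_meta_cols)
    header[(n_meta_cols + 1L):length(header)] else character(0)
  n_fields <- length(header)

  body <- lines[-1L]
  rsid <- character(length(body)); chrom <- character(length(body))
  pos <- integer(length(body)); strand <- character(length(body))
  a1 <- character(length(body)); a2 <- character(length(body))
  calls <- matrix(character(0), nrow = length(body), ncol = length(individuals))

  if (length(body) > 0L) {
    toks <- strsplit(trimws(body), "[ \t]+")
    lens <- lengths(toks)
    if (any(lens != n_fields)) {
      bad <- which(lens != n_fields)[1L]
      stop("malformed line ", bad + 1L, " in ", basename(path), ": ",
           lens[bad], " fields, expected ", n_fields)
    }
    tok <- matrix(unlist(toks), nrow = length(body), byrow = TRUE)
    rsid <- tok[, 1L]
    pair <- parse_allele_pair(tok[, 2L], rsid)
    a1 <- pair$a1; a2 <- pair$a2
    chrom <- normalize_chrom(tok[, 3L])
    pos_num <- suppressWarnings(as.integer(tok[, 4L]))
    if (anyNA(pos_num)) {
      bad <- which(is.na(pos_num))[1L]
      stop("non-integer position '", tok[bad, 4L], "' at line ", bad + 1L)
    }
    pos <- pos_num
    strand <- tok[, 5L]
    if (length(individuals) > 0L) {
      calls <- toupper(tok[, (n_meta_cols + 1L):n_fields, drop = FALSE])
      bad_call <- !grepl("^[ACGTN]{2}$", calls)
      if (any(bad_call)) {
        idx <- which(bad_call)[1L]
        row <- (idx - 1L) %% nrow(calls) + 1L
        stop("invalid genotype token '", calls[idx], "' at line ", row + 1L,
             " (", rsid[row], ")")
      }
    }
  }

  if (anyDuplicated(rsid))
    stop("duplicate rsid in ", basename(path), ": ",
         rsid[duplicated(rsid)][1L])

  snps <- data.frame(rsid = rsid, chrom = chrom, pos = pos,
                     allele1 = a1, allele2 = a2, strand = strand,
                     stringsAsFactors = FALSE)

  sex_mt <- snps$chrom %in% c("X", "Y", "XY", "MT", "M")
  if (any(sex_mt)) {
    warning(sum(sex_mt), " SNP(s) on X/Y/MT dropped from ", basename(path),
            " (screen is autosome-only)")
    snps <- snps[!sex_mt, , drop = FALSE]
    calls <- calls[!sex_mt, , drop = FALSE]
  }
  if (nrow(snps) > 0 && !all(snps$chrom %in% autosome_labels()))
    stop("unrecognized chromosome label: ",
         snps$chrom[!snps$chrom %in% autosome_labels()][1L])

  rownames(snps) <- NULL
  genotype_table(population, individuals, snps, calls)
}

parse_allele_pair <- function(x, rsid) {
  parts <- strsplit(toupper(x), "/", fixed = TRUE)
  ok <- lengths(parts) == 2L
  if (!all(ok))
    stop("malformed allele field '", x[!ok][1L], "' for ", rsid[!ok][1L])
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  bad <- !(m[, 1L] %in% c("A", "C", "G", "T")) |
    !(m[, 2L] %in% c("A", "C", "G", "T"))
  if (any(bad))
    stop("non-ACGT allele pair '", x[bad][1L], "' for ", rsid[bad][1L])
  list(a1 = m[, 1L], a2 = m[, 2L])
}

#' Write a genotype table in HapMap phase-3 layout
#'
#' Emits the 11 standard metadata columns (placeholder `"-"` for the
#' assembly/center/LSID/QC fields) followed by one column per individual,
#' space-delimited, readable back with [read_hapmap_genotypes()].
#'
#' @param tab A [genotype_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hapmap_genotypes <- function(tab, path) {
  header <- paste(c("rs#", "alleles", "chrom", "pos", "strand",
                    "assembly#", "center", "protLSID", "assayLSID",
                    "panelLSID", "QCcode", tab$individuals),
                  collapse = " ")
  if (nrow(tab$snps) > 0) {
    meta <- paste(tab$snps$rsid,
                  paste0(tab$snps$allele1, "/", tab$snps$allele2),
                  tab$snps$chrom, tab$snps$pos, tab$snps$strand,
                  "-", "-", "-", "-", "-", "-")
    geno <- apply(tab$calls, 1L, paste, collapse = " ")
    rows <- if (length(tab$individuals) > 0) paste(meta, geno) else meta
  } else {
    rows <- character(0)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read / write a simple TSV genotype matrix
#'
#' A lighter interchange format: tab-separated with columns `rsid`,
#' `chrom`, `pos`, `alleles` (e.g. `"A/C"`), `strand`, then one column per
#' individual holding the two-letter genotype call. An empty cell is
#' treated as missing (`"NN"`). The `strand` column is optional on read
#' (defaults to `"+"`) and always written, so `read(write(x))` returns an
#' identical table.
#'
#' @param path File path.
#' @param population Population label; defaults to the file name stem.
#' @return A [genotype_table()].
#' @export
read_matrix_tsv <- function(path, population = NULL) {
  if (!file.exists(path)) stop("genotype matrix not found: ", path)
  if (is.null(population))
    population <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  fixed <- c("rsid", "chrom", "pos", "alleles")
  if (!all(fixed %in% names(df)[seq_along(fixed)]))
    stop("matrix TSV must start with columns: ",
         paste(fixed, collapse = ", "))
  has_strand <- ncol(df) >= 5L && names(df)[5L] == "strand"
  first_ind <- if (has_strand) 6L else 5L
  individuals <- if (ncol(df) >= first_ind)
    names(df)[first_ind:ncol(df)] else character(0)

  pair <- if (nrow(df) > 0) parse_allele_pair(df$alleles, df$rsid)
          else list(a1 = character(0), a2 = character(0))
  pos <- suppressWarnings(as.integer(df$pos))
  if (nrow(df) > 0 && anyNA(pos))
    stop("non-integer position '", df$pos[is.na(pos)][1L], "'")
  snps <- data.frame(
    rsid = df$rsid, chrom = normalize_chrom(df$chrom), pos = pos,
    allele1 = pair$a1, allele2 = pair$a2,
    strand = if (has_strand) df$strand else rep("+", nrow(df)),
    stringsAsFactors = FALSE)

  calls <- as.matrix(df[, seq.int(first_ind, length.out = length(individuals)),
                        drop = FALSE])
  calls <- toupper(calls)
  calls[calls == ""] <- "NN"
  if (length(calls) > 0) {
    bad <- !grepl("^[ACGTN]{2}$", calls)
    if (any(bad)) {
      idx <- which(bad)[1L]
      stop("invalid genotype token '", calls[idx], "' for rsid ",
           snps$rsid[(idx - 1L) %% nrow(snps) + 1L])
    }
  }
  dimnames(calls) <- NULL

  sex_mt <- snps$chrom %in% c("X", "Y", "XY", "MT", "M")
  if (any(sex_mt)) {
    warning(sum(sex_mt), " SNP(s) on X/Y/MT dropped (screen is autosome-only)")
    snps <- snps[!sex_mt, , drop = FALSE]
    calls <- calls[!sex_mt, , drop = FALSE]
    rownames(snps) <- NULL
  }
  genotype_table(population, individuals, snps, calls)
}

#' @rdname read_matrix_tsv
#' @param tab A [genotype_table()] to write.
#' @export
write_matrix_tsv <- function(tab, path) {
  df <- data.frame(rsid = tab$snps$rsid, chrom = tab$snps$chrom,
                   pos = tab$snps$pos,
                   alleles = paste0(tab$snps$allele1, "/", tab$snps$allele2),
                   strand = tab$snps$strand,
                   stringsAsFactors = FALSE, check.names = FALSE)
  calls <- tab$calls
  if (length(calls) > 0 || length(tab$individuals) > 0) {
    m <- as.data.frame(calls, stringsAsFactors = FALSE)
    names(m) <- tab$individuals
    df <- cbind(df, m)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Table-1 style scientific notation: 3.051e-16 -> "3.05E-16"
format_pvalue <- function(p) {
  out <- toupper(formatC(p, format = "e", digits = 2))
  sub("E([+-])0(\\d\\d)$", "E\\1\\2", out)
}

#' Write screen results as a TSV
#'
#' One row per flagged (or otherwise reported) SNP/genotype-class test.
#' Columns: `chrom`, `rsid`, `pos`, `alleles`, `tested_genotype`, one
#' `expected_<POP>` column per population with the random-mating expected
#' count of the missing class, `log10_p_value`, `p_value`, `k_tested`,
#' `threshold`, `flagged`. P-values and thresholds are rendered in
#' scientific notation with 3 significant digits (e.g. `3.05E-16`).
#'
#' @param results A list of test results as produced by
#'   [test_genotype_class()] / [scan_chromosome()] (the `results` field of
#'   a scan summary), possibly empty.
#' @param path Output file path.
#' @param populations Population labels for the expectation columns;
#'   taken from the first result when `NULL`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, populations = NULL) {
  if (is.null(populations) && length(results) > 0)
    populations <- results[[1L]]$populations
  exp_cols <- if (length(populations) > 0)
    paste0("expected_", populations) else character(0)
  header <- c("chrom", "rsid", "pos", "alleles", "tested_genotype",
              exp_cols, "log10_p_value", "p_value", "k_tested",
              "threshold", "flagged")
  rows <- vapply(results, function(r) {
    stopifnot(identical(r$populations, populations))
    paste(c(r$snp$chrom, r$snp$rsid, r$snp$pos,
            paste0(r$snp$major, "/", r$snp$minor), r$genotype_label,
            sprintf("%.1f", r$per_pop_expectation),
            sprintf("%.4f", r$log_p_value / log(10)),
            format_pvalue(r$p_value), r$k_tested,
            format_pvalue(r$threshold), r$flagged),
          collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"), rows), con)
  invisible(path)
}
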