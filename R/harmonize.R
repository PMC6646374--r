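#' Assign major/minor roles from pooled allele counts
#'
#' The major allele is the one with the larger allele count pooled across
#' all populations (homozygotes contribute two copies, heterozygotes one).
#' A tie is broken toward the lexicographically smaller character so that
#' role assignment is deterministic.
#'
#' @param pooled_counts Named numeric vector of length 2: allele -> pooled
#'   copy count.
#' @return Named character vector `c(major = ..., minor = ...)`.
#' @export
assign_allele_roles <- function(pooled_counts) {
  if (length(pooled_counts) != 2L || is.null(names(pooled_counts)) ||
      anyDuplicated(names(pooled_counts)))
    stop("pooled_counts must name exactly 2 distinct alleles")
  al <- names(pooled_counts)
  major <- if (pooled_counts[1L] > pooled_counts[2L]) al[1L]
           else if (pooled_counts[2L] > pooled_counts[1L]) al[2L]
           else sort(al)[1L]
  c(major = major, minor = setdiff(al, major))
}

#' Count genotype classes in a vector of calls
#'
#' Classifies each two-letter call as major homozygote (`n0`),
#' heterozygote (`n1`, either character order), minor homozygote (`n2`)
#' or missing (any call containing `N`). A call carrying an allele outside
#' `{major, minor}` is an error: such SNPs must be filtered as
#' multi-allelic before counting.
#'
#' @param calls Character vector of two-letter genotype strings.
#' @param major,minor Single allele characters.
#' @return A list with `population` (NA here), `n0`, `n1`, `n2`,
#'   `n_missing`, `n_called`.
#' @export
count_genotypes <- function(calls, major, minor) {
  miss <- grepl("N", calls, fixed = TRUE)
  hom0 <- calls == paste0(major, major)
  het <- calls == paste0(major, minor) | calls == paste0(minor, major)
  hom2 <- calls == paste0(minor, minor)
  leak <- !(miss | hom0 | het | hom2)
  if (any(leak))
    stop("call '", calls[leak][1L], "' carries an allele outside {",
         major, ",", minor, "}")
  n0 <- sum(hom0); n1 <- sum(het); n2 <- sum(hom2)
  list(n0 = n0, n1 = n1, n2 = n2, n_missing = sum(miss),
       n_called = n0 + n1 + n2)
}

# Reasons a SNP can be excluded during harmonization; logged to the QC table.
drop_reasons <- c("absent-in-population", "multi-allelic",
                  "strand-ambiguous", "allele-mismatch", "no-calls",
                  "low-call-rate", "low-maf")

#' Harmonize SNPs across population genotype tables
#'
#' Intersects SNPs by rsid across all populations and produces, for each
#' SNP kept, aligned per-population genotype counts with a single global
#' major/minor assignment (so the three genotype classes mean the same
#' thing in every population). A SNP is kept only if it
#' is present in every population, resolves to a single bi-allelic allele
#' set after strand reconciliation, shows at most two distinct alleles in
#' the pooled calls, and has at least one called genotype (and call rate
#' >= `min_call_rate`) in every population. Monomorphic SNPs are kept:
#' downstream they yield p-value 1 and are never flagged.
#'
#' Strand handling: the consensus allele set is the unordered pair
#' reported by the majority of populations (ties broken toward the
#' alphabetically first set). A population whose pair is the reverse
#' complement of the consensus has its calls complemented; A/T and C/G
#' pairs are strand-ambiguous, so a SNP whose populations disagree on such
#' a pair is dropped rather than guessed.
#'
#' @param tables List of [genotype_table()] objects, all from the same
#'   chromosome. A single population is allowed (the cross-population
#'   intersection and evidence product are then trivial).
#' @param min_call_rate Minimum per-population call rate in `[0, 1]`
#'   (default 0; a population with zero called genotypes always drops the
#'   SNP).
#' @param min_maf Optional pooled minor-allele-frequency floor (default 0,
#'   i.e. presence-only filtering).
#' @return A list of `multipop_counts` objects ordered by (pos, rsid),
#'   with a `qc` attribute: a data frame of dropped rsids and reasons.
#' @export
harmonize_snps <- function(tables, min_call_rate = 0, min_maf = 0) {
  if (length(tables) < 1L)
    stop("harmonization needs at least 1 population table")
  if (min_call_rate < 0 || min_call_rate > 1)
    stop("min_call_rate must be in [0, 1]")
  tables <- unname(tables)
  pops <- vapply(tables, function(t) t$population, character(1))
  if (anyDuplicated(pops))
    stop("duplicate population label: ", pops[duplicated(pops)][1L])
  for (t in tables)
    if (anyDuplicated(t$snps$rsid))
      stop("duplicate rsid within population ", t$population)

  qc_rsid <- character(0); qc_reason <- character(0)
  drop <- function(rsid, reason) {
    qc_rsid <<- c(qc_rsid, rsid); qc_reason <<- c(qc_reason, reason)
  }

  rsid_sets <- lapply(tables, function(t) t$snps$rsid)
  shared <- Reduce(intersect, rsid_sets)
  absent <- setdiff(unique(unlist(rsid_sets)), shared)
  if (length(absent) > 0)
    drop(absent, "absent-in-population")

  # Pre-index per table: row lookup and sorted allele-pair strings, so the
  # per-SNP loop only does cheap vector indexing.
  idx <- lapply(tables, function(t) match(shared, t$snps$rsid))
  panel_sizes <- vapply(tables, n_individuals, integer(1))
  pair_str <- lapply(tables, function(t)
    paste(pmin(t$snps$allele1, t$snps$allele2),
          pmax(t$snps$allele1, t$snps$allele2), sep = "/"))
  npop <- length(tables)
  meta1 <- tables[[1L]]$snps

  out <- vector("list", length(shared))
  kept <- 0L
  for (s in seq_along(shared)) {
    rs <- shared[s]
    rows <- vapply(idx, `[`, integer(1), s)
    pairs <- character(npop)
    for (j in seq_len(npop)) pairs[j] <- pair_str[[j]][rows[j]]

    # consensus allele set by majority vote over populations
    upair <- unique(pairs)
    votes <- tabulate(match(pairs, upair), nbins = length(upair))
    top <- upair[votes == max(votes)]
    consensus <- sort(top)[1L]
    cons <- strsplit(consensus, "/", fixed = TRUE)[[1L]]
    ambiguous <- identical(sort(cons),
                           sort(complement_alleles(cons)))

    flip <- rep(FALSE, npop)
    ok <- TRUE
    for (j in seq_len(npop)) {
      if (pairs[j] == consensus) next
      rc <- paste(sort(complement_alleles(
        strsplit(pairs[j], "/", fixed = TRUE)[[1L]])), collapse = "/")
      if (!ambiguous && rc == consensus) {
        flip[j] <- TRUE
      } else {
        drop(rs, if (ambiguous || rc == consensus) "strand-ambiguous"
                 else "allele-mismatch")
        ok <- FALSE; break
      }
    }
    if (!ok) next

    calls <- vector("list", npop)
    for (j in seq_len(npop)) {
      cl <- tables[[j]]$calls[rows[j], ]
      calls[[j]] <- if (flip[j]) complement_calls(cl) else cl
    }

    # pooled observed alleles must fit inside the consensus pair
    pooled <- unlist(calls, use.names = FALSE)
    pooled <- pooled[!grepl("N", pooled, fixed = TRUE)]
    chars <- c(substr(pooled, 1L, 1L), substr(pooled, 2L, 2L))
    allele_chars <- unique(chars)
    if (length(allele_chars) > 2L) {
      drop(rs, "multi-allelic"); next
    }
    if (!all(allele_chars %in% cons)) {
      drop(rs, "allele-mismatch"); next
    }

    # pooled copy counts over the consensus pair (unobserved allele -> 0)
    copies <- c(sum(chars == cons[1L]), sum(chars == cons[2L]))
    names(copies) <- cons
    roles <- assign_allele_roles(copies)

    counts <- vector("list", npop)
    bad <- NULL
    for (j in seq_len(npop)) {
      cnt <- count_genotypes(calls[[j]], roles[["major"]], roles[["minor"]])
      if (cnt$n_called == 0L) { bad <- "no-calls"; break }
      if (cnt$n_called / panel_sizes[j] < min_call_rate) {
        bad <- "low-call-rate"; break
      }
      counts[[j]] <- cnt
    }
    if (!is.null(bad)) { drop(rs, bad); next }

    if (min_maf > 0) {
      tot <- sum(copies)
      maf <- if (tot > 0) min(copies) / tot else 0
      if (maf < min_maf) { drop(rs, "low-maf"); next }
    }

    cdf <- structure(
      list(population = pops,
           n0 = vapply(counts, `[[`, integer(1), "n0"),
           n1 = vapply(counts, `[[`, integer(1), "n1"),
           n2 = vapply(counts, `[[`, integer(1), "n2"),
           n_missing = vapply(counts, `[[`, integer(1), "n_missing"),
           n_called = vapply(counts, `[[`, integer(1), "n_called"),
           panel_size = panel_sizes),
      class = "data.frame", row.names = seq_len(npop))

    r1 <- rows[1L]
    kept <- kept + 1L
    out[[kept]] <- structure(
      list(rsid = rs, chrom = meta1$chrom[r1], pos = meta1$pos[r1],
           major = roles[["major"]], minor = roles[["minor"]],
           strand = meta1$strand[r1], counts = cdf),
      class = "multipop_counts")
  }
  out <- out[seq_len(kept)]

  if (kept > 0) {
    ord <- order(vapply(out, `[[`, numeric(1), "pos"),
                 vapply(out, `[[`, character(1), "rsid"))
    out <- out[ord]
  }
  attr(out, "qc") <- data.frame(rsid = qc_rsid, reason = qc_reason,
                                stringsAsFactors = FALSE)
  out
}

#' @export
print.multipop_counts <- function(x, ...) {
  cat("<multipop_counts> ", x$rsid, " chr", x$chrom, ":", x$pos,
      " alleles ", x$major, "/", x$minor, "\n", sep = "")
  print(x$counts)
  invisible(x)
}
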