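# Fixture builders shared across test files. Everything is generated in
# code; no binary or downloaded data.

fixture_snps <- function(rsid, chrom = "1", pos = seq_along(rsid) * 1000L,
                         a1 = "A", a2 = "C", strand = "+") {
  data.frame(rsid = rsid, chrom = chrom, pos = as.integer(pos),
             allele1 = a1, allele2 = a2, strand = strand,
             stringsAsFactors = FALSE)
}

# calls: one character vector per SNP (list), or a matrix
make_table <- function(population, individuals, snps, calls) {
  if (is.list(calls)) calls <- do.call(rbind, calls)
  genotype_table(population, individuals, snps, calls)
}

# Two small populations sharing one A/C SNP where the minor homozygote
# is absent; n0/n1 counts chosen per population.
two_pop_fixture <- function(n0 = c(25L, 25L), n1 = c(25L, 25L),
                            n2 = c(0L, 0L), rsid = "rs1") {
  lapply(seq_along(n0), function(j) {
    calls <- c(rep("AA", n0[j]), rep("AC", n1[j]), rep("CC", n2[j]))
    ids <- sprintf("P%d_%03d", j, seq_along(calls))
    make_table(paste0("POP", j), ids, fixture_snps(rsid), list(calls))
  })
}

# A HapMap-format fixture file with the standard 11 metadata columns.
write_hapmap_fixture <- function(path, snp_lines,
                                 individuals = c("NA001", "NA002", "NA003")) {
  header <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                    "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                    individuals), collapse = " ")
  writeLines(c(header, snp_lines), path)
  path
}

hapmap_line <- function(rsid, alleles, chrom, pos, strand, calls) {
  paste(c(rsid, alleles, chrom, pos, strand,
          "ncbi_b36", "ctr", "-", "-", "-", "QC+", calls), collapse = " ")
}
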