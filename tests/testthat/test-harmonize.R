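test_that("allele roles follow pooled copy counts with a lexicographic tie-break", {
  expect_equal(assign_allele_roles(c(A = 900, C = 100)),
               c(major = "A", minor = "C"))
  expect_equal(assign_allele_roles(c(T = 500, G = 500)),
               c(major = "G", minor = "T"))
  # hand count: n0=2, n1=2, n2=0 over (A, C) gives copies A=6, C=2
  calls <- c("AA", "AA", "AC", "AC")
  copies <- c(A = sum(unlist(strsplit(calls, "")) == "A"),
              C = sum(unlist(strsplit(calls, "")) == "C"))
  expect_equal(copies, c(A = 6L, C = 2L))
  expect_equal(assign_allele_roles(copies), c(major = "A", minor = "C"))
  expect_error(assign_allele_roles(c(A = 1)), "exactly 2")
})

test_that("genotype counting respects order, missingness and allele leaks", {
  cnt <- count_genotypes(c("AA", "AC", "CA", "CC", "NN"), "A", "C")
  expect_equal(cnt[c("n0", "n1", "n2", "n_missing", "n_called")],
               list(n0 = 1L, n1 = 2L, n2 = 1L, n_missing = 1L, n_called = 4L))

  all_missing <- count_genotypes(rep("NN", 5), "A", "C")
  expect_equal(all_missing$n_called, 0L)

  # the 1000-individual worked setup: 500 AA, 500 aa, no heterozygotes
  cnt2 <- count_genotypes(c(rep("AA", 500), rep("CC", 500)), "A", "C")
  expect_equal(cnt2[c("n0", "n1", "n2")], list(n0 = 500L, n1 = 0L, n2 = 500L))

  expect_error(count_genotypes(c("AA", "AG"), "A", "C"), "outside")
})

test_that("harmonization keeps shared bi-allelic SNPs and logs drops", {
  snpsA <- fixture_snps(c("rs1", "rs2", "rs3"),
                        a1 = c("A", "A", "A"), a2 = c("C", "G", "T"))
  snpsB <- fixture_snps(c("rs1", "rs3"), pos = c(1000L, 3000L),
                        a1 = c("A", "A"), a2 = c("C", "T"))
  tabA <- make_table("P1", c("a1", "a2"), snpsA,
                     list(c("AA", "AC"), c("AG", "GG"), c("AA", "AT")))
  tabB <- make_table("P2", c("b1", "b2"), snpsB,
                     list(c("CC", "AC"), c("TT", "AA")))
  h <- harmonize_snps(list(tabA, tabB))

  expect_equal(vapply(h, `[[`, character(1), "rsid"), c("rs1", "rs3"))
  qc <- attr(h, "qc")
  expect_equal(qc$reason[qc$rsid == "rs2"], "absent-in-population")

  rs1 <- h[[1]]
  # pooled copies: A = 4, C = 4 -> tie broken to A major
  expect_equal(c(rs1$major, rs1$minor), c("A", "C"))
  expect_equal(rs1$counts$n0, c(1L, 0L))
  expect_equal(rs1$counts$n1, c(1L, 1L))
  expect_equal(rs1$counts$n2, c(0L, 1L))
  expect_equal(rs1$counts$n0 + rs1$counts$n1 + rs1$counts$n2 +
                 rs1$counts$n_missing, rs1$counts$panel_size)
})

test_that("tri-allelic and all-missing SNPs are dropped with reasons", {
  snps <- fixture_snps("rs1")
  tabA <- make_table("P1", c("a1", "a2"), snps, list(c("AA", "AC")))
  tabB <- make_table("P2", c("b1", "b2"),
                     fixture_snps("rs1", a1 = "A", a2 = "G"),
                     list(c("AG", "GG")))
  h <- harmonize_snps(list(tabA, tabB))
  expect_length(h, 0L)
  expect_true(attr(h, "qc")$reason %in%
                c("multi-allelic", "allele-mismatch", "strand-ambiguous"))

  tabC <- make_table("P2", c("b1", "b2"), snps, list(c("NN", "NN")))
  h2 <- harmonize_snps(list(tabA, tabC))
  expect_length(h2, 0L)
  expect_equal(attr(h2, "qc")$reason, "no-calls")
})

test_that("reverse-complement population is reconciled, ambiguous pairs are not", {
  # P2 reports the same SNP on the opposite strand: T/G is the reverse
  # complement of A/C
  tabA <- make_table("P1", sprintf("a%d", 1:4), fixture_snps("rs1"),
                     list(c("AA", "AC", "CC", "AA")))
  tabB <- make_table("P2", sprintf("b%d", 1:4),
                     fixture_snps("rs1", a1 = "T", a2 = "G", strand = "-"),
                     list(c("TT", "TG", "GG", "TG")))
  h <- harmonize_snps(list(tabA, tabB))
  expect_length(h, 1L)
  expect_equal(c(h[[1]]$major, h[[1]]$minor), c("A", "C"))
  # P2's TT/TG/GG calls complement to AA/AC/CC
  expect_equal(h[[1]]$counts$n0, c(2L, 1L))
  expect_equal(h[[1]]$counts$n1, c(1L, 2L))
  expect_equal(h[[1]]$counts$n2, c(1L, 1L))

  # A/T pairs are their own reverse complement: disagreement cannot be
  # resolved and the SNP is dropped, never guessed
  tabC <- make_table("P1", c("a1", "a2"),
                     fixture_snps("rs9", a1 = "A", a2 = "T"),
                     list(c("AA", "AT")))
  tabD <- make_table("P2", c("b1", "b2"),
                     fixture_snps("rs9", a1 = "A", a2 = "C"),
                     list(c("AA", "AC")))
  h2 <- harmonize_snps(list(tabC, tabD))
  expect_length(h2, 0L)
})

test_that("complement reconciliation is involutive", {
  calls <- c("AA", "AC", "GT", "NN", "CG", "TA")
  cc <- lethalscan:::complement_calls
  expect_equal(cc(cc(calls)), calls)
})

test_that("monomorphic SNPs are kept and call-rate filters apply", {
  tabs <- list(
    make_table("P1", c("a1", "a2"), fixture_snps("rs1"), list(c("AA", "AA"))),
    make_table("P2", c("b1", "b2"), fixture_snps("rs1"), list(c("AA", "NN"))))
  h <- harmonize_snps(tabs)
  expect_length(h, 1L)
  expect_equal(h[[1]]$counts$n0, c(2L, 1L))

  # P2 call rate 0.5 fails a 0.75 floor
  h2 <- harmonize_snps(tabs, min_call_rate = 0.75)
  expect_length(h2, 0L)
  expect_equal(attr(h2, "qc")$reason, "low-call-rate")
})

test_that("retained SNP set is invariant to population order", {
  set.seed(11)
  cfg <- sim_config(n_snps = 40, populations = hapmap_populations()[1:4, ],
                    missing_rate = 0.05, seed = 99)
  tabs <- generate_panel(cfg)$tables
  h_fwd <- harmonize_snps(tabs)
  h_rev <- harmonize_snps(rev(tabs))
  expect_equal(vapply(h_fwd, `[[`, character(1), "rsid"),
               vapply(h_rev, `[[`, character(1), "rsid"))
  # per-population decomposition always sums to the panel size
  for (mpc in h_fwd)
    expect_equal(mpc$counts$n0 + mpc$counts$n1 + mpc$counts$n2 +
                   mpc$counts$n_missing, mpc$counts$panel_size)
})

test_that("duplicate populations are rejected, single populations allowed", {
  tabs <- two_pop_fixture()
  h1 <- harmonize_snps(list(tabs[[1]]))
  expect_length(h1, 1L)
  expect_equal(h1[[1]]$counts$population, "POP1")
  tabs[[2]]$population <- "POP1"
  expect_error(harmonize_snps(tabs), "duplicate population")
})
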