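test_that("config validation enforces the simulator invariants", {
  expect_error(sim_config(10, missing_rate = 1), "\\[0, 1\\)")
  expect_error(sim_config(10, maf = 0.7), "\\[0, 0.5\\]")
  expect_error(sim_config(10, maf = c(0.4, 0.1)), "lo <= hi")
  expect_error(sim_config(10, lethal = data.frame(snp = c(2L, 2L),
                                                  class = 2L, survival = 0)),
               "duplicate")
  expect_error(sim_config(10, lethal = data.frame(snp = 11L, class = 2L,
                                                  survival = 0)),
               "out of range")
  expect_error(sim_config(10, lethal = data.frame(snp = 1L, class = 2L,
                                                  survival = 1.5)),
               "survival")
  pops <- data.frame(label = "P1", size = 0L)
  expect_error(sim_config(10, populations = pops), ">= 1")

  cfg <- sim_config(0)
  panel <- generate_panel(cfg)
  expect_equal(n_snps(panel$tables[[1]]), 0L)
  expect_equal(nrow(panel$truth), 0L)
})

test_that("the default panel reproduces the HapMap population structure", {
  pops <- hapmap_populations()
  expect_equal(nrow(pops), 11L)
  expect_equal(sum(pops$size), 1417L)
  expect_equal(pops$size[pops$label == "CEU"], 174L)
  expect_equal(pops$size[pops$label == "YRI"], 209L)

  panel <- generate_panel(sim_config(n_snps = 5, seed = 3))
  expect_named(panel$tables, pops$label)
  expect_equal(sum(vapply(panel$tables, n_individuals, integer(1))), 1417L)
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_snps = 30, missing_rate = 0.02,
                    lethal = data.frame(snp = 4L, class = 1L, survival = 0.2),
                    seed = 77)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1, p2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_hapmap_genotypes(p1$tables$CEU, file.path(d1, "ceu.txt"))
  write_hapmap_genotypes(p2$tables$CEU, file.path(d2, "ceu.txt"))
  expect_identical(readLines(file.path(d1, "ceu.txt")),
                   readLines(file.path(d2, "ceu.txt")))

  p3 <- generate_panel(sim_config(n_snps = 30, missing_rate = 0.02,
                                  seed = 78))
  expect_false(identical(p1$tables$CEU$calls, p3$tables$CEU$calls))
})

test_that("fixed-frequency populations match Hardy-Weinberg proportions", {
  set.seed(8)
  q <- 0.3
  size <- 100000L
  tab <- simulate_population("BIG", size, q, fixture_snps("rs1"))
  cnt <- count_genotypes(tab$calls[1, ], "A", "C")
  probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  for (i in 1:3) {
    obs <- c(cnt$n0, cnt$n1, cnt$n2)[i]
    se <- sqrt(size * probs[i] * (1 - probs[i]))
    expect_lt(abs(obs - size * probs[i]), 3 * se)
  }

  # q = 0: everyone is major homozygote
  tab0 <- simulate_population("MONO", 500L, 0, fixture_snps("rs1"))
  expect_true(all(tab0$calls == "AA"))
})

test_that("viability selection shifts survivors to the conditional distribution", {
  # fully lethal minor homozygote at q = 0.3: survivor frequencies
  # [0.49, 0.42, 0] / 0.91
  set.seed(9)
  size <- 100000L
  lethal <- data.frame(snp = 1L, class = 2L, survival = 0)
  tab <- simulate_population("SEL", size, 0.3, fixture_snps("rs1"),
                             lethal = lethal)
  cnt <- count_genotypes(tab$calls[1, ], "A", "C")
  expect_equal(cnt$n2, 0L)
  cond <- c(0.49, 0.42, 0) / 0.91
  for (i in 1:2) {
    obs <- c(cnt$n0, cnt$n1)[i]
    se <- sqrt(size * cond[i] * (1 - cond[i]))
    expect_lt(abs(obs - size * cond[i]), 3 * se)
  }

  # no survivable genotype: monomorphic major with a lethal major class
  bad <- data.frame(snp = 1L, class = 0L, survival = 0)
  expect_error(
    simulate_population("DOA", 10L, 0, fixture_snps("rs1"), lethal = bad),
    "survive")
})

test_that("missingness masks calls at the configured rate", {
  set.seed(10)
  cfg <- sim_config(n_snps = 50, populations = data.frame(label = "P1",
                                                          size = 200L),
                    maf = 0.2, missing_rate = 0.1, seed = 5)
  tab <- generate_panel(cfg)$tables[[1]]
  rate <- mean(tab$calls == "NN")
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / length(tab$calls)))
})

test_that("a fully lethal class is absent everywhere and recovered by the test", {
  cfg <- sim_config(n_snps = 20,
                    lethal = data.frame(snp = 5L, class = 2L, survival = 0,
                                        q = 0.3),
                    seed = 21)
  panel <- generate_panel(cfg)
  for (tab in panel$tables) {
    cnt <- count_genotypes(tab$calls[5, ], tab$snps$allele1[5],
                           tab$snps$allele2[5])
    expect_equal(cnt$n2, 0L)
  }
  s <- scan_chromosome(panel$tables)
  hit <- Filter(function(r) r$snp$rsid == "snp000005", s$results)
  expect_length(hit, 1L)
  expect_equal(hit[[1]]$genotype_class, 2L)
})

test_that("null and power study harnesses validate inputs and limits", {
  null_cfg <- sim_config(n_snps = 40,
                         populations = hapmap_populations()[1:3, ], seed = 1)
  lethal_cfg <- sim_config(n_snps = 40,
                           populations = hapmap_populations()[1:3, ],
                           lethal = data.frame(snp = 2L, class = 2L,
                                               survival = 0, q = 0.3),
                           seed = 1)
  expect_error(run_null_simulation(lethal_cfg), "without lethal")
  expect_error(run_null_simulation(null_cfg, reps = 0), "reps")
  expect_error(run_power_simulation(null_cfg), "at least one lethal")

  # vanishing alpha cannot flag anything
  res <- run_null_simulation(null_cfg, alpha = 1e-300, reps = 2)
  expect_equal(res$fwer, 0)
  expect_equal(res$per_test_rate, 0)

  # monomorphic genomes cannot flag anything
  mono <- sim_config(n_snps = 40, populations = hapmap_populations()[1:3, ],
                     maf = 0, seed = 2)
  res2 <- run_null_simulation(mono, alpha = 0.05, reps = 2)
  expect_equal(res2$fwer, 0)
})

test_that("detection power responds to effect size as expected", {
  # a planted SNP with survival 1 is just a null SNP: never detected here
  s1 <- sim_config(n_snps = 30, populations = hapmap_populations()[1:3, ],
                   lethal = data.frame(snp = 3L, class = 2L, survival = 1,
                                       q = 0.3),
                   seed = 4)
  pow1 <- run_power_simulation(s1, reps = 3)
  expect_equal(pow1$detection$rate, 0)

  # a rare allele in one small population is far weaker evidence than a
  # common allele in three populations
  weak <- sim_config(n_snps = 30,
                     populations = data.frame(label = "ASW", size = 87L),
                     lethal = data.frame(snp = 3L, class = 2L, survival = 0,
                                         q = 0.02),
                     seed = 4)
  strong <- sim_config(n_snps = 30, populations = hapmap_populations()[1:3, ],
                       lethal = data.frame(snp = 3L, class = 2L, survival = 0,
                                           q = 0.3),
                       seed = 4)
  pow_weak <- run_power_simulation(weak, reps = 3)
  pow_strong <- run_power_simulation(strong, reps = 3)
  expect_lt(pow_weak$detection$rate, pow_strong$detection$rate)
  expect_equal(pow_strong$detection$rate, 1)
})
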