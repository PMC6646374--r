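#' The 11 HapMap phase-3 population samples
#'
#' Labels, descriptions and sample sizes of the 11 population panels
#' (1417 individuals in total) that the synthetic generator emulates by
#' default.
#'
#' @return Data frame with columns `label`, `description`, `size`.
#' @export
hapmap_populations <- function() {
  data.frame(
    label = c("ASW", "CEU", "CHB", "CHD", "GIH", "JPT",
              "LWK", "MEX", "MKK", "TSI", "YRI"),
    description = c(
      "African Ancestry in the Southwest USA",
      "Utah residents with Northern and Western European ancestry (CEPH)",
      "Han Chinese in Beijing, China",
      "Chinese in Metropolitan Denver, Colorado",
      "Gujarati Indians in Houston, Texas",
      "Japanese in Tokyo, Japan",
      "Luhya in Webuye, Kenya",
      "Mexican Ancestry in Los Angeles, California",
      "Maasai in Kinyawa, Kenya",
      "Toscans in Italy",
      "Yoruba in Ibadan, Nigeria"),
    size = c(87L, 174L, 139L, 109L, 101L, 116L,
             110L, 86L, 184L, 102L, 209L),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic multi-population genotype panel
#'
#' Bundles and validates everything the generator needs. Defaults emulate
#' the HapMap phase-3 panel: 11 populations with the published sample
#' sizes, independent per-population per-SNP minor-allele frequencies
#' drawn uniformly from `maf = c(0.05, 0.5)`, no viability selection and
#' no missingness.
#'
#' @param n_snps Number of SNPs to simulate.
#' @param populations Data frame with columns `label` and `size`.
#' @param maf Minor-allele frequency specification: a single value in
#'   `[0, 0.5]` used everywhere, a length-2 range `c(lo, hi)` sampled
#'   independently per SNP and population, or an `n_snps` x
#'   `nrow(populations)` matrix of frequencies.
#' @param lethal Optional data frame of SNPs under viability selection,
#'   with columns `snp` (1-based SNP index), `class` (0, 1 or 2),
#'   `survival` (probability in `[0, 1]` that a conceived individual of
#'   that genotype survives to sampling), and optionally `q` (a fixed
#'   minor-allele frequency imposed on that SNP in every population).
#' @param missing_rate Probability in `[0, 1)` that any emitted call is
#'   masked to `"NN"`.
#' @param seed Integer RNG seed; the generator is fully deterministic
#'   given the config (R's default Mersenne-Twister stream).
#' @param chrom Autosome label for the simulated SNPs.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_snps, populations = hapmap_populations(),
                       maf = c(0.05, 0.5), lethal = NULL,
                       missing_rate = 0, seed = 1L, chrom = "1") {
  if (length(n_snps) != 1L || is.na(n_snps) || n_snps < 0 ||
      n_snps != round(n_snps))
    stop("n_snps must be a non-negative integer")
  if (!is.data.frame(populations) ||
      !all(c("label", "size") %in% names(populations)) ||
      nrow(populations) < 1L)
    stop("populations must be a data frame with columns label, size")
  if (any(populations$size < 1) ||
      any(populations$size != round(populations$size)))
    stop("population sizes must be integers >= 1")
  if (anyDuplicated(populations$label))
    stop("duplicate population label")
  npop <- nrow(populations)

  if (is.matrix(maf)) {
    if (!all(dim(maf) == c(n_snps, npop)))
      stop("maf matrix must be n_snps x n_populations")
    if (any(maf < 0) || any(maf > 0.5))
      stop("minor-allele frequencies must lie in [0, 0.5]")
  } else if (length(maf) == 1L) {
    if (maf < 0 || maf > 0.5) stop("maf must lie in [0, 0.5]")
  } else if (length(maf) == 2L) {
    if (any(maf < 0) || any(maf > 0.5) || maf[1L] > maf[2L])
      stop("maf range must satisfy 0 <= lo <= hi <= 0.5")
  } else stop("maf must be a value, a range c(lo, hi), or a matrix")

  if (!is.null(lethal)) {
    if (!is.data.frame(lethal) ||
        !all(c("snp", "class", "survival") %in% names(lethal)))
      stop("lethal must be a data frame with columns snp, class, survival")
    if (nrow(lethal) > 0) {
      if (anyDuplicated(lethal$snp))
        stop("duplicate SNP index in lethal specification")
      if (any(lethal$snp < 1) || any(lethal$snp > n_snps))
        stop("lethal SNP index out of range 1..n_snps")
      if (!all(lethal$class %in% c(0, 1, 2)))
        stop("lethal class must be 0, 1 or 2")
      if (any(lethal$survival < 0) || any(lethal$survival > 1))
        stop("survival probability must lie in [0, 1]")
      if ("q" %in% names(lethal) &&
          any(!is.na(lethal$q) & (lethal$q < 0 | lethal$q > 0.5)))
        stop("lethal q override must lie in [0, 0.5]")
    }
  }
  if (length(missing_rate) != 1L || is.na(missing_rate) ||
      missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (length(seed) != 1L || is.na(seed) || seed != round(seed))
    stop("seed must be an integer")
  if (!normalize_chrom(chrom) %in% autosome_labels())
    stop("chrom must be an autosome label 1..22")

  structure(
    list(n_snps = as.integer(n_snps), populations = populations,
         maf = maf, lethal = lethal,
         missing_rate = missing_rate, seed = as.integer(seed),
         chrom = normalize_chrom(chrom)),
    class = "sim_config")
}

# Draw one genotype index vector (0/1/2) of length `size` for a single SNP
# under Hardy-Weinberg proportions for minor-allele frequency q, with
# optional viability selection: an individual of `class` survives
# conception with probability `survival`; non-survivors are redrawn until
# `size` living individuals are accumulated, mirroring the ascertainment
# of living adults. Errors out if the surviving genotype mass is (near)
# zero, i.e. survivors essentially cannot exist.
draw_genotypes <- function(size, q, class = NULL, survival = 1,
                           max_rounds = 10000L) {
  probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  if (is.null(class) || survival >= 1) {
    u <- stats::runif(size)
    return((u > probs[1L]) + (u > probs[1L] + probs[2L]))
  }
  w <- c(1, 1, 1); w[class + 1L] <- survival
  if (sum(probs * w) < 1e-12)
    stop("no genotype can survive: lethal class ", class,
         " with survival ", survival, " at q = ", q)
  out <- integer(0)
  rounds <- 0L
  while (length(out) < size) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("viability rejection sampling did not converge after ",
           max_rounds, " rounds")
    need <- size - length(out)
    u <- stats::runif(need)
    g <- (u > probs[1L]) + (u > probs[1L] + probs[2L])
    dies <- g == class & stats::runif(need) >= survival
    out <- c(out, g[!dies])
  }
  out[seq_len(size)]
}

#' Simulate one population sample at a set of SNPs
#'
#' Draws, for each SNP, `size` living individuals with genotypes in
#' Hardy-Weinberg proportions for that SNP's minor-allele frequency,
#' applies genotype-specific viability selection by rejection sampling
#' (so exactly `size` survivors are emitted), and masks calls to `"NN"`
#' independently at `missing_rate`. Consumes the current RNG stream; seed
#' control lives in [generate_panel()].
#'
#' @param label Population label.
#' @param size Number of sampled (living) individuals.
#' @param q Numeric vector of per-SNP minor-allele frequencies.
#' @param snps SNP metadata data frame (as in [genotype_table()]);
#'   `allele1` is the designated major and `allele2` the minor allele.
#' @param lethal Optional data frame with columns `snp`, `class`,
#'   `survival` (see [sim_config()]).
#' @param missing_rate Per-call masking probability.
#' @return A [genotype_table()].
#' @export
simulate_population <- function(label, size, q, snps, lethal = NULL,
                                missing_rate = 0) {
  m <- nrow(snps)
  if (length(q) != m) stop("q must have one frequency per SNP")
  geno <- matrix(0L, nrow = m, ncol = size)
  if (m > 0) {
    # vectorized draw for SNPs without viability selection
    lethal_idx <- if (is.null(lethal) || nrow(lethal) == 0) integer(0)
                  else as.integer(lethal$snp)
    plain <- setdiff(seq_len(m), lethal_idx)
    if (length(plain) > 0) {
      qp <- q[plain]
      p0 <- (1 - qp)^2
      p01 <- p0 + 2 * qp * (1 - qp)
      u <- matrix(stats::runif(length(plain) * size), nrow = length(plain))
      geno[plain, ] <- (u > p0) + (u > p01)
    }
    for (r in seq_along(lethal_idx)) {
      s <- lethal_idx[r]
      geno[s, ] <- draw_genotypes(size, q[s], class = lethal$class[r],
                                  survival = lethal$survival[r])
    }
  }

  # map genotype index to call string per SNP: 0 -> A1A1, 1 -> A1A2, 2 -> A2A2
  strs <- cbind(paste0(snps$allele1, snps$allele1),
                paste0(snps$allele1, snps$allele2),
                paste0(snps$allele2, snps$allele2))
  calls <- matrix(strs[cbind(rep.int(seq_len(m), size), as.vector(geno) + 1L)],
                  nrow = m, ncol = size)
  if (missing_rate > 0 && length(calls) > 0)
    calls[stats::runif(length(calls)) < missing_rate] <- "NN"

  individuals <- if (size > 0) sprintf("%s_%04d", label, seq_len(size))
                 else character(0)
  genotype_table(label, individuals, snps, calls, validate = FALSE)
}

#' Generate a full synthetic multi-population panel
#'
#' Deterministic given the config's seed: draws per-population
#' minor-allele frequencies, random allele pairs and positions, simulates
#' each population with [simulate_population()], and returns the tables
#' together with a truth table recording each SNP's per-population `q`,
#' lethal class and survival probability.
#'
#' @param config A [sim_config()].
#' @return List with `tables` (named list of [genotype_table()]s),
#'   `truth` (data frame), and the echoed `config`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  pops <- config$populations
  npop <- nrow(pops)

  # q matrix: SNPs x populations
  qmat <- if (is.matrix(config$maf)) config$maf
          else if (length(config$maf) == 1L) matrix(config$maf, m, npop)
          else matrix(stats::runif(m * npop, config$maf[1L], config$maf[2L]),
                      m, npop)
  lethal <- config$lethal
  if (!is.null(lethal) && nrow(lethal) > 0 && "q" %in% names(lethal)) {
    ov <- !is.na(lethal$q)
    qmat[lethal$snp[ov], ] <- matrix(lethal$q[ov], sum(ov), npop)
  }

  # random distinct allele pairs; allele1 plays the major role in HWE draws
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, m, replace = TRUE)
  shift <- sample.int(3L, m, replace = TRUE)
  a2 <- bases[(match(a1, bases) - 1L + shift) %% 4L + 1L]
  pos <- if (m > 0) sort(sample.int(250000000L, m)) else integer(0)
  snps <- data.frame(
    rsid = if (m > 0) sprintf("snp%06d", seq_len(m)) else character(0),
    chrom = rep(config$chrom, m), pos = pos,
    allele1 = a1, allele2 = a2, strand = rep("+", m),
    stringsAsFactors = FALSE)

  tables <- vector("list", npop)
  names(tables) <- pops$label
  for (j in seq_len(npop)) {
    tables[[j]] <- simulate_population(
      pops$label[j], pops$size[j], qmat[, j], snps,
      lethal = lethal, missing_rate = config$missing_rate)
  }

  truth <- cbind(
    snps[, c("rsid", "chrom", "pos", "allele1", "allele2")],
    lethal_class = rep(NA_integer_, m),
    survival = rep(NA_real_, m))
  if (!is.null(lethal) && nrow(lethal) > 0) {
    truth$lethal_class[lethal$snp] <- as.integer(lethal$class)
    truth$survival[lethal$snp] <- lethal$survival
  }
  qdf <- as.data.frame(qmat)
  names(qdf) <- paste0("q_", pops$label)
  truth <- cbind(truth, qdf)
  rownames(truth) <- NULL

  list(tables = tables, truth = truth, config = config)
}

#' Estimate the family-wise error rate under the null
#'
#' Repeatedly simulates panels with no viability selection, screens each
#' with [scan_chromosome()], and reports the fraction of replicates with
#' at least one flag (the empirical FWER) together with the flag rate per
#' (SNP, class) hypothesis. The statistic is expected to be conservative
#' because the next-generation distribution is estimated from the same
#' sample in which the absence is observed.
#'
#' @param config A [sim_config()] without lethal SNPs; its seed drives
#'   the whole study (one derived seed per replicate, recorded).
#' @param alpha Significance level passed to the scan.
#' @param reps Number of replicates (>= 1).
#' @param n_source See [test_genotype_class()].
#' @return List with `fwer`, `per_test_rate`, per-replicate `n_flagged`,
#'   `seeds`, `reps`, `alpha`.
#' @export
run_null_simulation <- function(config, alpha = 0.05, reps = 50L,
                                n_source = "called") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$lethal) && nrow(config$lethal) > 0)
    stop("null simulation requires a config without lethal SNPs")
  if (reps < 1) stop("reps must be >= 1")
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, reps)
  n_flagged <- integer(reps)
  flag_pairs <- 0; hyp_total <- 0
  for (r in seq_len(reps)) {
    cfg <- config; cfg$seed <- seeds[r]
    panel <- generate_panel(cfg)
    s <- scan_chromosome(panel$tables, alpha = alpha, n_source = n_source)
    n_flagged[r] <- s$n_flagged_tests
    flag_pairs <- flag_pairs + s$n_flagged_tests
    hyp_total <- hyp_total + s$n_hypotheses
  }
  list(fwer = mean(n_flagged > 0),
       per_test_rate = if (hyp_total > 0) flag_pairs / hyp_total else 0,
       n_flagged = n_flagged, seeds = seeds, reps = reps, alpha = alpha)
}

#' Estimate detection power for planted lethal SNPs
#'
#' Repeatedly simulates panels containing the config's lethal SNPs,
#' screens each replicate, and reports per planted SNP the fraction of
#' replicates in which it was flagged (for its planted class) and the
#' distribution of its combined p-value.
#'
#' @param config A [sim_config()] with at least one lethal SNP.
#' @param alpha,reps,n_source As in [run_null_simulation()].
#' @return List with `detection` (data frame: rsid, class, rate),
#'   `p_values` (matrix reps x planted SNPs, NA when untested), `seeds`,
#'   `reps`, `alpha`.
#' @export
run_power_simulation <- function(config, alpha = 0.05, reps = 20L,
                                 n_source = "called") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$lethal) || nrow(config$lethal) == 0)
    stop("power simulation requires at least one lethal SNP")
  if (reps < 1) stop("reps must be >= 1")
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, reps)
  planted_rsid <- sprintf("snp%06d", config$lethal$snp)
  planted_class <- as.integer(config$lethal$class)
  hits <- matrix(FALSE, reps, length(planted_rsid))
  pvals <- matrix(NA_real_, reps, length(planted_rsid),
                  dimnames = list(NULL, planted_rsid))
  for (r in seq_len(reps)) {
    cfg <- config; cfg$seed <- seeds[r]
    panel <- generate_panel(cfg)
    s <- scan_chromosome(panel$tables, alpha = alpha, n_source = n_source)
    for (res in s$tested) {
      hit <- which(planted_rsid == res$snp$rsid &
                     planted_class == res$genotype_class)
      if (length(hit) == 1L) {
        pvals[r, hit] <- res$p_value
        hits[r, hit] <- isTRUE(res$flagged)
      }
    }
  }
  list(detection = data.frame(rsid = planted_rsid, class = planted_class,
                              rate = colMeans(hits),
                              stringsAsFactors = FALSE),
       p_values = pvals, seeds = seeds, reps = reps, alpha = alpha)
}
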