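---
title: "Detecting potentially lethal genotypes from abnormal genotype distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting potentially lethal genotypes from abnormal genotype distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethalscan)
```

## The idea

A diploid individual at a bi-allelic SNP carries one of three genotypes:
the major homozygote `AA` (class g0), the heterozygote `Aa` (g1), or the
minor homozygote `aa` (g2). If both homozygotes are common in a
population, random mating keeps producing heterozygotes: a population
that is half `AA` and half `aa` should see half of its children carry
`Aa`. When a genotype class that random mating predicts in quantity is
*never* observed — in any of several independently sampled populations —
the most parsimonious genetic explanation is that carriers of that
genotype do not survive to sampling age: the fertilized embryo fails to
develop, or the carrier dies in childhood. `lethalscan` turns that
reasoning into a screen with an explicit error model.

## Model and statistic

Within one population, write `P = [p0, p1, p2]` for the observed
genotype-class frequencies among called genotypes. Assuming every
mating pair within the population is equally likely (random mating, no
inbreeding or assortment), offspring genotype frequencies are the
Hardy–Weinberg proportions determined by the allele frequencies
`a = p0 + p1/2` and `b = p2 + p1/2`:

$$P^* = [a^2,\; 2ab,\; b^2].$$

`next_gen_distribution()` implements this update. Three algebraic facts
are load-bearing and are enforced as property tests: the output is a
probability vector; allele frequencies are conserved (`a` and `b` are
unchanged); and the update is idempotent — Hardy–Weinberg equilibrium is
reached in a single generation, so `P*` doubles as the expected
distribution of the *current* population when nothing is removing
genotypes.

If class `g_i` is entirely absent from a sample of `n_j` called
genotypes, while its expected frequency is `p_i*`, the absence has
binomial probability

$$\Pr(e_{ij}) = (1 - p_i^*)^{n_j},$$

and across `J` independently sampled populations the joint absence has
probability $\prod_{j} \Pr(e_{ij})$. The statistic is only evaluated
when the class count is zero in *every* population — otherwise the
event did not occur and no test is made (`test_genotype_class()`
returns `NULL`).

With `k` SNPs screened, all three classes of every SNP count as
hypotheses, so the Bonferroni threshold is $\alpha/(3k)$. The screen is
deliberately strict: population substructure (see Limitations) can
inflate the evidence for heterozygote absences, and a conservative
correction buys back some of that risk.

## Numerical choices

* All products are sums of logs. The per-population term is computed as
  `n * log1p(-p_star)`, which keeps full precision for the small
  `p_star` values that dominate real screens; `stats::dbinom(0, n, p,
  log = TRUE)` is used as an independent oracle in the tests, never as
  the implementation.
* A combined p-value below double underflow is reported as exactly 0
  with the log value retained (`log_p_value`); the 1000-individual
  worked example already produces p ≈ 1e-301, so this is not a corner
  case.
* A monomorphic SNP has `p_star = 0` for its unobserved classes, hence
  p-value 1; such SNPs are kept through harmonization and can never be
  flagged, which keeps `k` honest without special-casing.
* When a chromosome retains zero SNPs the threshold is reported as
  `NaN` and nothing is flagged.
* Flagged results are ordered by (p-value, chromosome, position, rsid)
  so output is reproducible and independent of input file order.

## Harmonization

`harmonize_snps()` intersects SNPs by rsid across populations and
enforces a single bi-allelic interpretation:

* **Allele roles are global.** Major/minor are assigned from allele
  copy counts pooled over all populations (ties broken
  lexicographically), so class g2 means the same genotype in every
  population — a prerequisite for multiplying per-population
  probabilities for "the same" class.
* **Strand flips are repaired only when forced.** If a population
  reports the reverse-complement allele pair of the consensus
  (majority) pair, its calls are complemented; A/T and C/G pairs are
  their own reverse complements, so disagreements involving them are
  dropped as strand-ambiguous rather than guessed. Reconciliation is
  involutive (complementing twice is the identity), which the tests
  check directly.
* **Call-rate policy.** The default keeps any SNP with at least one
  called genotype per population (`min_call_rate = 0`); a population
  with no data at a SNP contributes no information to the product and
  the SNP is dropped with a logged reason. There is no published
  call-rate or minor-allele-frequency floor for this screen, so both
  exist only as optional filters (`min_call_rate`, `min_maf`, defaults
  0) for sensitivity analysis.
* A single population table is accepted: intersection and the
  cross-population product then degenerate gracefully, which is useful
  for per-population diagnostics and for power studies of small
  isolated samples.

Every exclusion is logged to a QC table with one of the reasons
`absent-in-population`, `multi-allelic`, `strand-ambiguous`,
`allele-mismatch`, `no-calls`, `low-call-rate`, `low-maf`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | family-wise significance level before the 3k correction |
| `n_source` | `"called"` | binomial sample size per population: called genotypes at the SNP, or the full panel size (`"panel"`) |
| `correction` | `"per-chromosome"` | scope of `k` in `alpha/(3k)`; `"genome-wide"` pools `k` over chromosomes and is never more permissive |
| `min_call_rate` | 0 | per-population call-rate floor |
| `min_maf` | 0 | pooled minor-allele-frequency floor |

`n_source = "called"` is the default because a missing call carries no
observation: treating it as a potential carrier (as `"panel"` does)
overstates `n_j` and makes absences look less probable than the data
support. The `"panel"` mode is retained because published
expected-count tables for this kind of screen are keyed to panel sizes;
both modes are exposed and tested.

## The synthetic panel generator

`generate_panel()` emulates the structure of the HapMap phase-3 panel:
11 populations with the published sample sizes (1417 individuals in
total, `hapmap_populations()`), per-population per-SNP minor-allele
frequencies drawn independently from U(0.05, 0.5) by default — real
panels show exactly this kind of cross-population frequency scatter —
Hardy–Weinberg genotype sampling within each population, optional
genotype-specific viability selection, and optional uniform missingness.

Viability selection is implemented as rejection sampling to a *fixed
number of survivors*: conceived individuals of the lethal class survive
with probability `s`, non-survivors are redrawn, and exactly `size`
living individuals are emitted. This mirrors how cohorts are actually
ascertained — sampled individuals are living adults — and is what makes
a fully lethal class (`s = 0`) exactly absent rather than merely rare.
Thinning (emitting fewer individuals) would model a different, wrong,
sampling process. The sampler errors out if the surviving genotype mass
is (numerically) zero.

The generator is deterministic given its seed (R's default
Mersenne–Twister stream; non-lethal SNPs take a vectorized path, lethal
SNPs an explicit rejection loop, and the draw order is fixed), and the
truth table records per SNP the per-population `q`, the lethal class
and its survival probability, so end-to-end recovery can be asserted
exactly.

What the simulator deliberately does **not** model: linkage
disequilibrium between SNPs (the statistic is single-site), population
substructure or inbreeding within a panel, relatedness between sampled
individuals, genotyping error, or informative missingness. Passing
tests therefore demonstrate the statistic's behaviour under its own
assumptions — they do not certify those assumptions for real cohorts,
where substructure in particular is known to bias this screen (below).

## Validation studies

Two study harnesses quantify operating characteristics, at the sizes
the package uses for its own acceptance checks:

* **Type-I error** (`run_null_simulation()`): 50 replicate panels of
  2000 null SNPs across the 11 HapMap-sized populations at
  `alpha = 0.05`. The empirical family-wise error rate is required to
  stay at or below 0.1; in practice it sits near 0 because `P*` is
  estimated from the same sample in which the absence is observed,
  which makes the statistic conservative (an absent class also drags
  its own expected frequency estimate down).
* **Power** (`run_power_simulation()`): a fully lethal minor homozygote
  at `q = 0.3` in all 11 populations among 2000 SNPs is detected in
  every one of 20 replicates — the pooled expected carrier count is
  ~75, giving combined p-values around e^-75, orders of magnitude below
  the threshold 0.05/6000. Power decays toward the null rate as `s`
  approaches 1 or as `q` and the panel shrink, which the tests check by
  monotonicity rather than by absolute calibration.

## Limitations

* **Substructure.** If a population is internally stratified, random
  mating within the whole panel is the wrong null: heterozygote
  deficits arise without any lethality (Wahlund effect), inflating
  false positives for g1-absences, while homozygote-lethal signals can
  be masked. The screen does not attempt a stratification correction —
  the strict Bonferroni threshold is the only mitigation — so flagged
  heterozygote absences deserve extra scepticism.
* **Same-sample estimation.** `P*` is estimated from the sample being
  tested, with no bias correction or pseudo-counts; this is what makes
  the null simulation conservative, and it is documented rather than
  "fixed" because any correction would change the published statistic.
* **Autosomes only.** X/Y/MT inheritance breaks the diploid
  random-mating algebra; such rows are dropped at read time.
* Absence of a genotype class is evidence about viability *to sampling
  age* only; it cannot distinguish embryonic lethality from early
  mortality, and flagged SNPs are candidates for follow-up, not
  diagnoses.
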