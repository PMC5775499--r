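---
title: "Population-genomic monitoring of staged reintroductions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genomic monitoring of staged reintroductions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reintropop)
```

## The problem

Species rescued from near-extinction are often restored by *staged*
reintroductions: a captive breeding stock is founded from a single surviving
source population, primary populations are released from captivity, and
secondary populations are later founded from established primary ones. Alpine
ibex (*Capra ibex*) are the canonical example: a species rebuilt from roughly
one hundred survivors into tens of thousands of animals through up to four
serial bottlenecks (source, captive stock of 88 founders, primary and
secondary releases). Every founding event and every generation at small size
removes genetic variation and accumulates drift and inbreeding, and the
stepwise strategy leaves a characteristic genomic footprint: a diversity
gradient from source to secondary populations, population differentiation
that increases with reintroduction rank, and long runs of homozygosity (ROH)
concentrated in the most recently founded populations.

`reintropop` packages the statistics used to measure that footprint from
reduced-representation (RAD-seq) SNP data, together with a forward simulator
of the whole process, so that every estimator can be validated against a
demography whose truth is known.

## The simulation model

`simulate_reintroduction()` is a forward Wright-Fisher simulator of standing
variation:

* **Stage graph.** A `demography_model()` is a rooted tree of stages, each
  with a founder count, a constant diploid size $N_e$, and a number of
  non-overlapping generations. Founding draws individuals *without
  replacement* from the parent stage (unbiased in expectation); each
  subsequent generation draws, for every one of the $N_e$ offspring, two
  distinct parents uniformly at random (monoecious random mating, no
  selfing).
* **Genome.** Markers sit at fixed physical positions on a small set of
  chromosomes (`default_genome()`: 5 chromosomes x 100 Mb with one marker per
  50 kb, i.e. 10,000 markers). Transmitted gametes recombine under the
  Haldane model: crossover counts are Poisson with mean equal to the genetic
  map length (uniform 1 cM/Mb by default), positions uniform. No new
  mutation: over the ~10-generation horizon of a reintroduction history,
  standing variation dominates and mutation is negligible.
* **Initial state.** The root population is initialised at linkage
  equilibrium with allele frequencies drawn uniformly from [0.05, 0.95]
  (configurable). Both haplotypes of every root individual get a unique
  ancestry label when `track_ibd = TRUE`, so true autozygous tracts are
  recoverable exactly (`true_ibd_segments()`).

Because the founding draw is unbiased, a stage with `generations = t`
accumulates *exactly* $t$ reproduction rounds of drift at its $N_e$. This
makes the simulator consistent with Wright's divergence equation
$1 - F_{ST} = (1 - 1/(2N_e))^t$ by construction, which the test suite checks
quantitatively (two sister stages at $N_e = 60$, $t = 10$ give mean
$F_{ST} \approx 0.080$). When an experiment calls for "a population of
constant $N_e$ evolved $t$ generations from a large source", found the stage
with the whole parent (`founders = parent Ne`) — the draw is then a no-op and
drift is exactly $t$ rounds at the new size.

The default ibex preset (`default_ibex_demography()`) encodes the documented
history: source $N_e = 1000$, 88 captive founders, three primary populations
($N_e = 300$) and three secondary ones ($N_e = 80$, each from a single
primary), 10 generations after each release (the documented range is 8-10;
10 reproduces the published $N_e$ inversions). Two parameters are not on
record and were fixed once: two generations of captive breeding (the zoos
bred for about a decade before the first releases), and founder groups of 30
(primary) and 20 (secondary) individuals, consistent with the published
post-founding $N_e$ ranges.

## The observation model

RAD-seq genotypes are not clean draws from the population.
`apply_rad_observation()` models the two artefacts that matter for the
downstream statistics:

* **Coverage-dependent missingness.** Depth per genotype is negative
  binomial (default mean 14, dispersion 3) around a per-individual mean that
  varies lognormally among individuals (sdlog 0.3, i.e. a coverage CV of
  about 30%, typical of barcoded libraries). Calls below 7 reads are set
  missing — the same per-strand threshold whose doubled, cut-site-level
  value (14x) anchors the SNP-density denominator
  (`effective_cutsite_coverage()`).
* **Genotype error.** With probability 0.001 (GATK-quality filtered calls)
  a retained heterozygote becomes a random homozygote and vice versa.

What the generator does *not* emulate: allele dropout correlated with
genotype (restriction-site polymorphism), PCR duplicates, reference bias,
and linked selection. A green test therefore establishes correctness of the
estimators under drift, sampling and random missingness — not robustness to
every RAD artefact.

## SNP panels and diversity statistics

`build_panel()` applies the panel rules in a fixed order: genotyping rate
(per group, then overall) -> monomorphic -> singleton/private doubleton ->
MAF. The order matters because missingness filtering changes which sites
look monomorphic; it is configurable, and the presets mirror the standard
RAD panels (overall rate >= 45% "general"; >= 50% per group and >= 60%
overall "multispecies"; > 80% within group "intraspecies"). A singleton is a
minor allele seen in one heterozygote, a private doubleton a minor allele
seen only as one homozygote — both reduce to "all minor-allele copies in one
individual", which is how the filter is implemented and tested by exhaustive
enumeration. `coverage_paralog_filter()` drops sites whose mean
individual-normalised depth is at least twice the expectation (collapsed
paralogs), and is scale-invariant by construction.

SNP density divides the count of segregating sites (minor allele count >= 1)
by the median covered kilobases at >= 7 reads. "Median sequence length
covered" is read as the median *across individuals* of per-individual
covered bp; the alternative population-level reading is available via
`median_scope = "population"`. Expected heterozygosity is Nei's gene
diversity $2p(1-p)$ without small-sample correction (an $2n/(2n-1)$ option
exists); $F_{IS} = (H_e - H_o)/H_e$ is computed from multilocus means. No
numeric claim is made against published per-population $F_{IS}$ tables:
those derive from external software whose locus weighting is not documented,
and the package tests $F_{IS}$ only for internal consistency (near zero
under random mating). Pairwise $F_{ST}$ is Weir & Cockerham's multilocus
$\theta$ (ratio of summed variance components; slightly negative estimates
are reported as computed). PCA mean-centres dosages per site, imputes
missing to the site mean, and eigendecomposes the individual covariance
matrix; coordinates are defined up to sign.

## Runs of homozygosity

`call_roh()` reproduces the plink `--homozyg` three-stage scheme at the
published parameterization: 25-SNP sliding windows (at most 1 heterozygous
and 5 missing calls), a SNP is "in a homozygous segment" when at least 5% of
the *full* windows containing it score homozygous (edge SNPs belong to fewer
windows and are judged against their actual window count), and maximal
flagged runs — split wherever neighbouring SNPs are more than 1,000 kb
apart, before any criterion is evaluated — become segments when they hold
>= 25 SNPs, span >= 1,000 kb, contain <= 1 heterozygote, and average at
least one SNP per 50 kb. Segment length is `end - start + 1` (inclusive bp;
the convention is not on record and is documented here). A heterozygote
inside a qualifying run is retained and counted in `n_het`, not trimmed.

Two numerical notes. First, the caller is pinned *exactly* to an independent
brute-force oracle on over a thousand randomized fixtures. Second, total
called ROH length is **not** monotone under removal of a heterozygous call,
although intuition suggests it should be: converting a het to a homozygote
can extend a flagged run into a region that violates the per-segment het or
density cap, and because maximal runs are evaluated whole (no sub-run
search, matching the reference behaviour), the merged run can fail where its
parts passed. The monotone property — and the one the tests assert — lives
at the flagging stage: removing a het can only add flagged SNPs.

$F_{ROH}$ is the summed length of segments longer than 10 Mb divided by the
autosomal genome length (the sum of contig lengths from the genome map or
the VCF header). Tract-length classes ((1-5], (5-10], (10-20], (20-30],
>30 Mb) summarise, per population, the proportion of individuals carrying at
least one segment in the class.

## Effective population size

Three estimators, matching the three signals a reintroduction leaves:

* **LD (`ne_from_ld()`).** Squared Burrows composite correlations of
  unphased dosages over locus pairs at MAF >= 0.1 and >= 250 kb apart (or on
  different chromosomes), mean-corrected for sample size
  ($1/S + 3.19/S^2$ for $S \ge 30$, the small-sample variant below) and
  inverted as $N_e = 1/(3 \hat r^2_{drift})$ (random mating; the monogamy
  constant 2 is available). The r-squared statistic matters: the composite
  uses the half-covariance of dosages with an $n/(n-1)$ debiasing factor
  over $\hat p \hat q$ expected-variance denominators. Only this form
  reproduces the published sample-size expectation on a null experiment
  (independent draws from an infinite population) and recovers the true
  $N_e$ in simulation (median within a few percent of truth at
  $N_e = 100$, $S = 50$, 2,000 unlinked loci); a plain Pearson correlation
  of dosages under-measures $r^2$ by $(n/(n-1))^2$ and inflates $N_e$ by
  roughly 40%. A non-positive drift component yields an infinite estimate,
  reported as such.
* **Heterozygosity loss (`ne_from_het_loss()`).** Inverts
  $H_{t+1} = (1 - 1/(2N_e)) H_t$: a 15% loss over 8 generations gives
  $N_e \approx 25$.
* **FST drift (`ne_from_fst_drift()`).** Inverts Wright's equation;
  $F_{ST} = 0.04$ (resp. 0.08) at $t = 10$ gives $N_e \approx 120$ (resp.
  60). The forward form `fst_expected_under_drift()` closes an exact
  round-trip identity that is property-tested.

**Confidence intervals.** The design originally called for a
chromosome-block jackknife on mean $r^2$. Implementation proved it wrong
here: every locus pair shares the same sampled individuals, so the dominant
variance component of mean $r^2$ is *between individuals*, which locus-block
resampling cannot see — measured coverage was near 60% where roughly 95% was
nominal. The package therefore uses a delete-one-individual jackknife
(efficient crossproduct downdating on complete data), whose measured
coverage is about 90-95% in the package's own replication experiments. It
still differs from the parametric chi-square interval of the original LD
method; coverage is approximate by design.

**Drift FST on frequencies.** For simulator-consistency checks the package
also exposes `drift_fst()`: against a known ancestral frequency,
$F = \sum d^2 / \sum p_0 q_0$; between two drifted sisters, the
infinite-sample variance-components form
$F = \sum d^2 / (2\sum(\bar p \bar q + d^2/4))$. Weir-Cockerham on whole
*finite* populations would subtract the final generation's binomial variance
as if it were sampling noise and systematically report about one generation
less drift; the frequency-based forms are unbiased for Wright's $F$ and are
what the acceptance checks use.

## Numerical and testing choices

* Positions are 1-based throughout (VCF convention); all lengths in bp.
* Phase is ignored (`0|1` equals `0/1`); half-missing genotypes (`0/.`) are
  treated as missing — their handling is not on record upstream.
* Site footprint defaults to 180 bp (RAD loci sequenced both directions
  within 90 bp of the cut site) and rides along in the `SF` INFO field so
  that VCF round trips preserve the SNP-density denominator.
* Monte-Carlo tests fix their seeds and use tolerances of
  $\max(\text{floor}, 3 \times \text{SE})$ with floors chosen before the
  tests were first run.
* Directional tests (diversity gradient, FST rank, long-ROH burden) run on a
  scaled-down preset (source $N_e$ 150, primary 50, secondary 25, 3 x 50 Mb
  genome) over 20 seeds to stay inside the test-time budget; the 50 kb
  marker spacing is kept so the ROH density criterion stays attainable by
  construction.
* The pipeline derives per-stage seeds as master seed + 1 (simulate), + 2
  (observe), + 3 (resampling), so stages can be rerun in isolation and
  identical configurations produce byte-identical tables.

## Known limitations

No migration between reintroduced stages (documented as negligible for this
history), no selection, no overlapping generations, no sex-specific
demography (the 55 male / 45 female founding is represented only by the
founder count), and no model-based HBD inference — ROH here are the windowed,
threshold-based kind, deliberately matching the reference parameterization.
Real-data $F_{IS}$ and per-population heterozygosity depend on filtering
choices of upstream genotype callers that this package does not re-implement
(GATK hard filters are out of scope); analyses of real VCFs should treat the
panel presets as the documented starting point, not as a guarantee of
identity with any published table.
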