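# reintropop

Population genomics of staged species reintroductions.

Many species were rescued from near-extinction by *serial* reintroductions:
a captive stock founded from one surviving source population, primary
populations released from captivity, and secondary populations founded later
from established primary ones. Each founding and every generation at small
size erodes diversity and accumulates drift and inbreeding. `reintropop` is
for conservation geneticists who monitor that process from reduced-
representation (RAD-seq) SNP data. It provides

* a forward **Wright–Fisher simulator** of staged reintroduction
  demographies with recombination, IBD ground truth, and a RAD-seq-like
  observation model (negative-binomial depth, coverage-dependent
  missingness, genotype error), so every estimator can be validated against
  a known truth;
* **SNP-panel filters** (genotyping rate per group and overall, monomorphic,
  singleton/private-doubleton, MAF, coverage-based paralog removal, distance
  thinning);
* **diversity statistics**: SNP density per covered kilobase with individual
  resampling curves, Nei's expected heterozygosity, observed
  heterozygosity, F<sub>IS</sub>, Weir–Cockerham F<sub>ST</sub>, and a
  genotype-covariance PCA;
* a windowed **runs-of-homozygosity** caller replicating the plink
  `--homozyg` parameterization (25-SNP windows, ≤1 het, ≤5 missing, 5%
  window-hit threshold, ≥25 SNPs / ≥1,000 kb / ≤1 het / ≥1 SNP per 50 kb /
  ≤1,000 kb gaps), length-class summaries, and the
  F<sub>ROH</sub> inbreeding coefficient (ROH > 10 Mb over the autosomal
  length);
* three **effective population size** estimators: LD-based
  (Burrows composite r², MAF ≥ 0.1, ≥250 kb spacing,
  N<sub>e</sub> = 1/(3 r²<sub>drift</sub>), delete-one-individual jackknife
  CI), heterozygosity loss (H<sub>t+1</sub> = (1 − 1/2N<sub>e</sub>) H<sub>t</sub>),
  and Wright's F<sub>ST</sub>-drift equation
  (1 − F<sub>ST</sub> = (1 − 1/2N<sub>e</sub>)<sup>t</sup>).

The core quantities, in the field's notation: expected heterozygosity decays
as E[H<sub>t</sub>] = H<sub>0</sub>(1 − 1/(2N<sub>e</sub>))<sup>t</sup>;
pairwise differentiation accumulates as
F<sub>ST</sub> = 1 − (1 − 1/(2N<sub>e</sub>))<sup>t</sup>; and
F<sub>ROH</sub> = Σ len(ROH > 10 Mb) / L<sub>autosome</sub>.

## Worked example

Simulate a scaled-down reintroduction history (source N<sub>e</sub> 150,
captive stock of 30, two primaries at N<sub>e</sub> 50, two secondaries at
N<sub>e</sub> 25, 10 generations each; 3 × 50 Mb genome, one marker per
50 kb), push it through the RAD observation model, and analyze:

```r
library(reintropop)
dem <- default_ibex_demography(
  source_ne = 150L, captive_founders = 30L, n_primary = 2L,
  primary_founders = 20L, primary_ne = 50L,
  n_secondary = 2L, secondary_founders = 15L, secondary_ne = 25L)
gen <- default_genome(n_chrom = 3L, chrom_length_bp = 5e7)
sim <- simulate_reintroduction(dem, gen, seed = 1, sample_n = 12)
obs <- apply_rad_observation(combined_genotypes(sim), observation_params(), seed = 2)
panel <- build_panel(obs$genotypes, sim$popmap, panel_preset("general"))
```

The diversity table (`diversity_table(panel, cov, sim$popmap)`) prints:

```
  population          role  n median_bp snp_count snp_density    He    Ho
1     source autochthonous 12    416880      2839        6.81 0.349 0.365
2    captive       captive 12    444600      2804        6.31 0.341 0.369
3   primary1       primary 12    419040      2494        5.95 0.303 0.330
4   primary2       primary 12    383490      2438        6.36 0.297 0.332
5 secondary1     secondary 12    400140      2071        5.18 0.257 0.263
6 secondary2     secondary 12    375300      1986        5.29 0.242 0.265
```

SNP count and heterozygosity fall monotonically from source through primary
to secondary populations — the serial-founder footprint. ROH burden runs the
other way (`call_roh(panel)` + `roh_profiles()`, mean Mb of called ROH per
individual):

```
  population total_mb
     source      0.10
   primary1      1.20
   primary2      1.23
 secondary1      4.48
 secondary2      4.44
```

and Weir–Cockerham F<sub>ST</sub> between the source and a secondary
population is 0.132 here. Inverting Wright's equation at the published
divergence (F<sub>ST</sub> = 0.08 after 10 generations):

```r
ne_from_fst_drift(0.08, 10)
#> Ne estimate [fst_drift]: 60.2
```

The full pipeline (simulate → observe → filter → diversity/FST/ROH/Ne
tables + manifest) runs from a single config:

```r
run_pipeline(list(mode = "simulate", seed = 1), "out_dir")
```

or from the command line: `exec/reintropop simulate --config run.yaml --out DIR`
and `exec/reintropop analyze --vcf file.vcf --popmap map.tsv --out DIR`
(population map: `individual<TAB>population<TAB>role`, roles from
autochthonous/captive/primary/secondary/mixed).

## Documentation

The methods vignette (`vignettes/reintroduction-genomics.Rmd`) documents the
simulation and observation models and their assumptions, every tunable
parameter with its default and rationale, the numerical choices (filter
order, segment-length convention, r² statistic, jackknife design), and known
limitations.
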