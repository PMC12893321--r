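# hylopop

Conservation population genomics for very small primate populations studied
through noninvasive sequencing, built around the Hainan gibbon system: a
critically endangered ape that declined to about a dozen individuals,
rebounded, and turned out to consist of two cryptic genetic lineages whose
recent natural crosses coincided with the recovery.

The package provides, as tested reusable R functions:

* **Fecal-genotyping QC** — allele-dropout (ADO) estimation from
  parent-offspring trios via Mendelian inconsistency (with an exact
  detection-model inversion to a per-allele rate), duplicate-library
  genotype discordance, ADO-versus-depth profiles with plateau detection,
  and the coverage-saturation model *y = a − e^(−bx+c)* used to plan
  sequencing effort.
* **Population-genetic statistics** — genome-wide and expected
  heterozygosity (*H*<sub>e</sub> = 2*p*(1−*p*)), realized and masked
  genetic load (realized = 2·hom/(2·hom + het) with the minor allele as
  derived), Grantham-score missense classification (deleterious ≥ 150),
  *F*<sub>ROH</sub> from length-thresholded runs of homozygosity, GC
  content at fourfold-degenerate sites (GC4) as a recombination proxy with
  a median high/low split, and pedigree-based crossover-rate estimation
  from phased haplotypes.
* **Balancing-selection scan** — folded site-frequency spectra, a
  frequency-clustering score for detecting clusters of
  intermediate-frequency polymorphisms, and the top-5% selection rule with
  gene-versus-flank recombination comparisons.
* **A non-Wright-Fisher forward simulator** — individual-based gibbon
  demography with yearly time steps: a gene-block genome (19,197 × 1458 bp
  genes on 25 chromosomes, 100 kb spacing, crossover probability 10⁻³
  between genes), a gamma distribution of deleterious fitness effects with
  *s*-dependent dominance (*h* = 0 / 0.01 / 0.1 / 0.4), polygynous
  age-structured mating (breeding males hold two fixed mates; females
  breed every 2 years), age-specific mortality, bounded density
  regulation, exact autozygosity (ROH) tracking, and the five-phase
  demographic scenario with a 450-year two-lineage split — plus an
  island-control scenario without the post-glacial expansion.
* **Population viability analysis** — 100-generation projections under
  three lineage-cross mating regimes (all matings inter-lineage, half,
  random), with extinction rates, size and inbreeding trajectories, and
  matched-replicate nonparametric comparisons.
* **Synthetic-data generators** — trios with injected dropout, duplicate
  libraries with known error sites, two-lineage panels with known split
  times, and phased pedigrees with known crossovers, each with an exact
  truth record so every estimator is testable end to end.

## Worked example

Estimating ADO from synthetic trios with 5% injected per-allele dropout:

```r
library(hylopop)
cfg   <- synth_config(n_sites = 10000, n_individuals = 10,
                      ado_rate = 0.05, seed = 42)
trios <- gen_trios(cfg)
count_mendelian_ado(trios$trios)
#> ADO: 3397 events / 51109 informative sites = 0.0665 raw rate (per-allele estimate 0.0486)
```

The raw Mendelian-inconsistency rate (0.066) is not the per-allele dropout
probability — dropout is only visible in some genotype configurations — but
inverting the exact detection model recovers the injected 5% (0.0486,
within sampling error). Duplicate libraries with 3% per-genotype error give
a discordance of 0.0586 over 60,000 jointly-called genotypes, matching the
two-draw error expectation 2e(1−e) + e²/2.

Running the scaled demographic model (q = 1/20: 960 genes, ancestral
K = 500) and a small PVA:

```r
lay <- genome_layout(scale_factor = 1/20)
sc  <- gibbon_scenario(scale_factor = 1/20)
r   <- run_scenario(sc, lay, seed = 7, record_every = 50)
r
#> sim_trajectory 'gibbon': 99 records over 4928 years, final N = 7
r$trajectory[r$trajectory$year %in% c(2500, 3500, 4250),
             c("year", "N", "froh500", "realized_weak", "mean_fitness")]
#>    year   N froh500 realized_weak mean_fitness
#> 50 2500 465  0.0159         0.180        0.981
#> 70 3500  27  0.3091         0.886        0.989
#> 85 4250 920  0.0131         0.742        0.975
```

The trajectory shows the model's core behaviour: the LGM bottleneck
(year 3500, scaled K = 25) inflates runs-of-homozygosity inbreeding
(*F*<sub>ROH</sub> 0.016 → 0.31) and realized load, and the post-glacial
expansion (year 4250, scaled K = 1000) deflates both. The end state carries
the two lineage labels and seeds the PVA:

```r
pv <- run_pva(r$population, "all_cross", n_replicates = 20,
              K = round(2000 / 20), layout = lay, seed = 9)
pv
#> pva_result 'all_cross': 20 replicates x 100 generations (K = 100)
#>   extinction rate 0.000
```

`compare_scenarios()` contrasts the three mating regimes with binomial
extinction intervals and matched-replicate signed-rank tests; at 200
replicates the all-cross regime shows significantly lower inbreeding than
random mating.

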