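---
title: "Models and methods in hylopop"
author: "hylopop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hylopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hylopop)
```

hylopop is a toolkit for conservation genomics of very small primate
populations studied through noninvasive (fecal) sequencing, built around the
Hainan gibbon system: a species that declined to roughly a dozen individuals
and has since rebounded, with two cryptic genetic lineages whose recent
crosses appear to have helped. The package covers four layers: genotype
quality control for low-input samples, the population-genetic statistics
used to quantify inbreeding, genetic load and recombination, a
balancing-selection scan, and an individual-based forward simulator with a
population viability analysis (PVA) of lineage-cross mating strategies.
Every layer is exercisable on synthetic data with exact truth records, so
the whole pipeline is testable without restricted field samples.

## Genotype QC for fecal sequencing data

Fecal DNA yields little host material, so heterozygous genotypes are prone
to allele dropout (ADO): one allele fails to be observed and the call
collapses to a false homozygote.

**Trio-based ADO counting.** `count_mendelian_ado()` scans
parent-parent-offspring genotypes for the two diagnostic inconsistency
patterns: a homozygote x heterozygote pair with an offspring homozygous for
the allele the homozygous parent does not carry, and opposite homozygotes
with any homozygous offspring. The *raw rate* divides events by informative
sites (sites where all three members are called and a rule could fire).
Because dropout is only visible in some configurations, the raw rate is a
biased estimate of the per-allele dropout probability; the function
therefore also inverts an exact detection model — Hardy-Weinberg parents,
Mendelian transmission, independent per-allele dropout at heterozygotes,
missing calls excluded — by one-dimensional root finding, yielding a
method-of-moments *per-allele* estimate. Both numbers are reported; the
denominator and raw counts are kept so alternative conventions can be
recomputed.

**Duplicate libraries.** `genotype_discordance()` is the fraction of
jointly-called genotypes that differ between two libraries prepared from
the same individuals; it captures ADO plus any other random or systematic
error (false alleles), so it is expected to exceed the trio-based rate.

**Depth dependence.** `ado_depth_profile()` bins genotypes by read depth
(offspring depth or trio mean, switchable, since either convention is
defensible) and reports an ADO estimate per bin plus the plateau depth: the
first bin after the last rate change exceeding the tolerance (default
0.005). A flat profile plateaus at the first bin; a step profile at the
step.

**Coverage saturation.** `fit_solow()` models genome coverage as
\(y = a - e^{-bx + c}\) with \(a\) the maximal coverage. This
parameterisation is the identifiable one: an additive constant outside the
exponential would be confounded with \(a\). Fitting is Levenberg-Marquardt
with a linearised start (`log(a0 - y)` regression), box constraint
\(a \le 1\), and the residual trace retained (it is non-increasing because
only improving steps are accepted). The tipping point solves
\(y'(x) = b e^{-bx+c} = \tau\) for the configured marginal-gain tolerance
\(\tau\).

## Population-genetic statistics

* `genome_heterozygosity()`: heterozygous sites over callable genome
  length; `window_heterozygosity()` gives the 1-Mb sliding profile used to
  compare hybrid offspring with their parents.
* `expected_heterozygosity()`: \(H_e = 2p(1-p)\) with \(p\) the
  major-allele frequency.
* `genetic_load()`: realized load \(= 2 n_{hom} / (2 n_{hom} + n_{het})\)
  over sites of one mutation class, with the sample minor allele as the
  derived allele (no outgroup polarisation; a 0.5-frequency tie keeps the
  alternate allele derived). The masked load is the complement on the same
  denominator — the published texts do not print a masked-load formula, so
  the complement-on-shared-denominator definition is this package's stated
  convention, which makes realized + masked = 1 an enforced invariant. A
  sample with no derived alleles returns 0/0 with a flag rather than an
  error.
* `classify_missense()`: Grantham-score classification, deleterious at
  scores of 150 and above, valid range 5-215.
* `froh()`: \(F_{ROH} = \sum_i \mathrm{length}(ROH_i) / L\) over segments
  at or above the threshold (500 kb and 1 Mb conventionally). Segment
  *detection* from empirical genotypes is deliberately out of scope —
  segments come from the simulator's exact autozygosity tracker or from
  external callers.
* `gc4()` / `partition_gc4()`: GC fraction at third positions of
  fourfold-degenerate codons (standard genetic code only), a proxy for
  local recombination via GC-biased gene conversion; genes split at the
  median GC4 into high/low recombination classes, with median ties assigned
  to the low class (switchable) for a deterministic partition.
* `pedigree_recombination_rate()`: crossovers per neighbouring phased
  allele pair, counted from parental-haplotype origin switches in offspring
  gametes.

## Balancing-selection scan

`folded_sfs()` bins segregating sites by minor-allele count.
`beta_score()` scores a core site by how tightly flanking folded
frequencies cluster around the core's folded frequency, with kernel
\(w_i = 1 - |f_i - f_0|/0.5\); the published method this emulates is a
family of allele-frequency-correlation statistics whose exact functional
form is not reproduced here, so the kernel is deliberately simple,
documented, and bypassable — externally computed scores can be fed straight
into `select_top()`, which applies the top-5% rule with exactly
\(\lceil 0.05 n \rceil\) sites selected and ties broken by ascending
position. `flank_compare()` contrasts per-gene recombination rates against
10-kb flanks with paired and unpaired nonparametric tests.

## The forward simulator

`run_scenario()` drives an individual-based, non-Wright-Fisher model in
yearly time steps: pair maintenance, reproduction, then viability
selection.

**Genome.** 19,197 gene blocks of 1458 bp (~28 Mb coding) on 25
chromosomes, separated by 100 kb of intergenic sequence. Mutations arise
only in genes at \(10^{-8}\) per site per generation; crossovers occur only
between adjacent genes with probability `intergenic_length x 1e-8 = 1e-3`
per meiosis, never within a gene; chromosomes assort freely.

**Fitness effects.** 30% of new mutations are neutral; the rest draw
selection coefficients from a gamma DFE (shape 0.186, mean -0.0131 — an
external human-derived calibration, exposed in `dfe_config()`), truncated
at \(s = -1\). Dominance follows the step map \(h = 0\) (\(s \le -0.1\)),
0.01, 0.1, 0.4 (\(s \ge -0.001\)); the boundary \(s = -0.1\), unassigned by
the strict inequalities of the map, goes to the more recessive class.
Fitness is multiplicative: \((1+s)\) per homozygous and \((1+hs)\) per
heterozygous mutation, floored at zero. Mutations fixed in the whole living
population are converted to substitutions: their fitness cost becomes a
population-wide constant and their counts stay in the load bookkeeping.

**Mating.** Gibbons are polygynous: each breeding male (age 7+) holds up to
two fixed female mates (age 7+), sires at most one offspring per year with
the mate who has waited longest, females breed at most every 2 years (which
subsumes the ~1.5 years of maternal care), widowed males re-pair, and new
bonds prefer females who did not breed the previous year. Both sexes use
age 7 as breeding onset (field estimates put female onset at 5-8; the
mating rule pins mates at 7+, so 7 is used for both, configurable).

**Survival.** Each year an individual survives with probability
\(\min(1,\; w \times a(\mathrm{age}) \times \min(K/N,\; d_{max}))\), where
\(w\) is genetic fitness and \(a\) the age factor. The published age table
(0.1 newborns, 0.05 ages 1-2, 0.03 ages 3-6, 0.1 age 7, 0.05 ages 8-30,
0.25 ages 31-35, 0.5 ages 36-40, death past 40) is introduced in its source
as realising *age-specific mortality*, and only the mortality reading
(\(a = 1 - m\)) yields a demographically viable population — under the
literal multiplier reading prime-age adults would survive at 5% per year
and every scenario goes immediately extinct. Both readings are available
(`age_factor_mode`), mortality being the default. Density dependence uses
the ratio \(K/N\) with a bounded release (\(d_{max} = 2\) by default):
populations below carrying capacity get at most a doubling of vital rates.
The bound matters in both directions — with no release at all, populations
at the observed lineage sizes (K of 5-6) fade out within decades even
without any genetic load, while an unbounded release lets density
compensation rescue genetically near-inviable offspring and erases
inbreeding depression entirely.

**Demographic scenarios.** `gibbon_scenario()`: burn-in at K = 10,000
(50,000 y), LGM bottleneck at K = 500 (20,000 y), post-glacial expansion
ramping to K = 20,000 (15,000 y), decline to K = 3000 until 450 y ago, then
a lineage split. The post-split sizes are described in the source material
as a *continuing decline* reaching K = 6 (lineage A) and 5 (lineage B)
today; hylopop therefore ramps K linearly from the lineages' proportional
share of the pre-split capacity down to 6/5 (a step collapse held for 450 y
is available via configuration, but it is unsurvivable and contradicts the
existence of the present-day population). `island_scenario()` is identical
without the expansion phase: a continuous decline from the bottleneck to
the present census size.

**Autozygosity tracking.** ROH are tracked exactly, not called from
genotypes: every haplotype carries per-gene ancestry labels and an ROH is a
maximal run of genes where both labels agree. Labels fixed at burn-in start
would saturate (after a bottleneck the population coalesces to few founders
and every genome looks fully autozygous forever), so hylopop uses two
staggered label layers refreshed every `roh_window` years, measuring
F_ROH on the layer at least half a window old. Because recombination
shortens IBD tracts as \(e^{-2gr\ell}\), autozygosity older than the
half-window contributes negligibly above the 500 kb threshold; the default
window is twice the age below which ~90% of threshold-passing tracts arise,
derived from the layout's recombination rate.

**Desk rescaling.** A scale factor \(q\) (the package's reference runs use
\(q = 1/20\): ~1000 genes, scaled ancestral K of 500) multiplies gene
number, carrying capacities and epoch durations by \(q\) and divides the
per-site mutation rate, per-site recombination rate and selection
coefficients by \(q\). This is the standard coalescent-consistent
rescaling: it preserves per-site diversity (4Nu), the population
recombination rate (4Nr), drift per epoch, selection intensity (Ns and
s x generations), genome-wide deleterious input per generation, and —
because time compression and recombination inflation cancel — physical IBD
tract lengths in bp, so the 500 kb / 1 Mb ROH thresholds carry over
unchanged. Census-scale capacities (the split lineages at 6/5, already
single-family sizes) and their durations are not scaled. Two limitations
are inherent and stated rather than hidden: the strongly deleterious tail
saturates at \(s = -1\) (rescaled recessive lethals), and the absolute
amount of segregating masked load (lethal equivalents per diploid) scales
below its full-scale value because it grows with the number of loci — so
scaled runs reproduce directional and relative contrasts faithfully, but
absolute extinction probabilities driven by inbreeding depression come out
lower than in a full-scale model.

## Population viability analysis

`run_pva()` projects a starting population (by default the gibbon
scenario's end state, which carries pure lineage-A/B ancestry labels) for
100 generations at K = 2000 (scaled by \(q\)) under three mate-choice
regimes: every new pair inter-lineage (`all_cross`), each pairing
constrained inter-lineage with probability 0.5 (`half_cross` — the
"half of matings" reading; the "half of individuals" reading can be
emulated by mixing scenarios), or unconstrained (`random`). Offspring
ancestry is the parental mean and admixed individuals count as
inter-lineage partners for anyone, so the constraint binds exactly where it
should: in the first generations, before admixture spreads. Replicates
cycle over a list of independent burn-in end states; extinction is
population size zero. Because either lineage can drift to extinction during
the 450-year isolation while the real population demonstrably survived with
both lineages breeding, PVA starts are conditioned with
`pva_start_viable()`: both lineages present and at least one male and one
female young enough to pair. `compare_scenarios()` reports extinction
rates with exact binomial intervals and matched-replicate signed-rank tests
on inbreeding and size.

## Synthetic data

`synth_config()` drives four generators with exact truth records: trios
with injected per-allele dropout (dropout hits heterozygous calls; one lost
allele gives a false homozygote, two a missing call), duplicate libraries
with independent per-genotype errors, two-lineage panels diverged by
Wright-Fisher frequency drift for a configurable number of generations, and
fully informative phased pedigrees with per-interval Bernoulli crossovers.
Defaults emulate the noninvasive SNP panels the QC layer targets: MAF
uniform on [0.05, 0.5] (matching the usual MAF filter), negative-binomial
depth with mean 10 (the depth at which the ADO trend levels off). The
generators deliberately do not model read-level errors, reference bias,
contamination or linkage within panels, so passing tests demonstrate
estimator correctness under the stated error model, not robustness to
every artefact of real fecal data.

## Numerical and tie-break conventions

* GC4 median ties go to the low-recombination class (switchable).
* `select_top()` breaks score ties by ascending position.
* The deleterious-class boundaries at \(s = -0.01\) and \(-0.001\), left
  ambiguous by strict inequalities, follow the dominance map's grouping
  (both belong to the class whose \(h\) they receive).
* The ADO depth-profile plateau is the first bin after the last
  super-tolerance change; empty bins are reported but skipped.
* The Solow fit refuses constant coverage (degenerate) and non-convergence
  surfaces the last residual.
* All generators and simulations are pure functions of (configuration,
  seed); the simulator consumes R's RNG stream, so `set.seed()` reproduces
  runs bit for bit.

## Reference problem sizes

The package's own acceptance runs use \(q = 1/20\) (960 genes, scaled
ancestral K = 500), 20 demographic-scenario replicates for the inbreeding
trajectory, and 200 PVA replicates per mating scenario; the property suite
uses \(10^4\)-site QC panels, 50 paired gibbon/island replicates and small
neutral populations (K = 60) for the Wright-Fisher drift checks. These
sizes were chosen so that every claim is backed by replicated computation
at desk scale; all of them are plain arguments, so larger studies are a
matter of compute, not code.
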