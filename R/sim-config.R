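#' Gene-block genome layout for the forward simulator
#'
#' The simulated genome consists of `n_genes` coding blocks of `gene_length`
#' bp spread over `n_chromosomes` chromosomes and separated by
#' `intergenic_length` bp of non-coding sequence. Mutations arise in genes at
#' `mutation_rate` per site per generation; crossovers occur only between
#' adjacent genes with probability `intergenic_length * recombination_rate`
#' per meiosis (1e-3 at the defaults), recombination within a gene is not
#' allowed, and chromosomes assort freely.
#'
#' `scale_factor` (q < 1) shrinks the model for desk runs under a
#' coalescent-invariant rescaling: `n_genes` is multiplied by q while the
#' per-site mutation and recombination rates are divided by q (carrying
#' capacities and epoch durations are scaled by the demographic scenario,
#' see [gibbon_scenario()]). This preserves per-site diversity (4Nu), the
#' population recombination rate (4Nr), drift per epoch, the genome-wide
#' deleterious input per generation, and physical IBD tract lengths in bp —
#' so ROH length thresholds carry over unchanged. Selection coefficients are
#' not rescaled (the strong-selection tail cannot be), so Ns is reduced by
#' q; scaled runs are comparative, not absolute, reconstructions.
#'
#' @param n_chromosomes,n_genes,gene_length,intergenic_length layout counts
#'   and sizes (defaults 25 chromosomes, 19,197 genes of 1458 bp, 100 kb
#'   spacing: a ~28 Mb coding genome).
#' @param mutation_rate per-site per-generation mutation rate (default 1e-8).
#' @param recombination_rate per-site per-generation crossover rate (default
#'   1e-8).
#' @param scale_factor desk-run rescaling factor q in (0, 1].
#' @return Object of class `genome_layout`.
#' @export
genome_layout <- function(n_chromosomes = 25L, n_genes = 19197L,
                          gene_length = 1458L, intergenic_length = 1e5,
                          mutation_rate = 1e-8, recombination_rate = 1e-8,
                          scale_factor = 1) {
  stopifnot(scale_factor > 0, scale_factor <= 1)
  q <- scale_factor
  n_genes_s <- max(50L, as.integer(round(n_genes * q)))
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    n_genes = n_genes_s,
    gene_length = as.integer(gene_length),
    intergenic_length = intergenic_length,
    mutation_rate = mutation_rate / q,
    intergene_crossover_prob = min(0.5, intergenic_length *
                                     recombination_rate / q),
    scale_factor = q,
    coding_length = as.numeric(n_genes_s) * gene_length,
    span = gene_length + intergenic_length),
    class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf(
    "genome_layout: %d genes x %d bp on %d chromosomes (q = %g)\n  u = %.3g /site/gen, inter-gene crossover prob = %.3g\n",
    x$n_genes, x$gene_length, x$n_chromosomes, x$scale_factor,
    x$mutation_rate, x$intergene_crossover_prob))
  invisible(x)
}

#' Distribution of fitness effects for new mutations
#'
#' A fraction `neutral_prop` of new mutations is neutral (s = 0); the rest
#' are deleterious with selection coefficients drawn as the negative of a
#' gamma distribution with the given shape and (negative) mean, truncated at
#' s = -1. The default shape/mean come from a large-sample human DFE
#' estimate — they are external calibration inputs, not quantities this
#' package infers. The dominance coefficient follows the s-dependent step
#' map: h = 0 for s <= -0.1, 0.01 for -0.1 < s < -0.01, 0.1 for
#' -0.01 <= s < -0.001, 0.4 for s >= -0.001 (the boundary s = -0.1, left
#' unassigned by the strict inequalities, goes to the more recessive class).
#'
#' @param neutral_prop proportion of neutral mutations (default 0.3).
#' @param gamma_shape gamma shape parameter (default 0.186).
#' @param gamma_mean mean selection coefficient of deleterious mutations,
#'   negative (default -0.01314833).
#' @return Object of class `dfe_config`.
#' @export
dfe_config <- function(neutral_prop = 0.3, gamma_shape = 0.186,
                       gamma_mean = -0.01314833) {
  assert_prob(neutral_prop, "neutral_prop")
  if (gamma_shape <= 0) stop_hylopop("`gamma_shape` must be > 0")
  if (gamma_mean >= 0) stop_hylopop("`gamma_mean` must be negative")
  structure(list(neutral_prop = neutral_prop, gamma_shape = gamma_shape,
                 gamma_mean = gamma_mean), class = "dfe_config")
}

#' Gibbon life-history configuration
#'
#' Polygynous age-structured life cycle: breeding males (>= `breeding_age`
#' years) hold up to two fixed female mates (also >= `breeding_age`) and
#' sire one offspring per year, alternating between mates; females breed at
#' most every `breeding_interval` years; survival each year is the product
#' of genetic fitness, an age factor, and density regulation min(1, K/N);
#' nobody survives past `max_age`. The age table (10% newborn, 5% ages 1-2,
#' 3% ages 3-6, 10% age 7, 5% ages 8-30, 25% ages 31-35, 50% ages 36-40) is
#' read as age-specific *mortality* by default (`age_factor_mode =
#' "mortality"`, survival factor 1 - m); `"survival"` applies the table
#' values directly as survival multipliers (a demographically inviable
#' literal reading, kept for comparison).
#'
#' @param breeding_age minimum breeding age in years, both sexes (default 7).
#' @param breeding_interval minimum years between a female's births
#'   (default 2; subsumes the ~1.5 years of maternal care).
#' @param max_age maximum age in years (default 40).
#' @param age_factor_mode `"mortality"` (default) or `"survival"`.
#' @param fecundity probability an eligible pairing produces an offspring in
#'   a given year (default 1: every successful copulation produces one
#'   offspring).
#' @param density_release_max upper bound on the K/N density factor: below
#'   carrying capacity, vital rates can rise at most this many fold
#'   (default 2). Bounding the release keeps sparse populations viable
#'   while leaving survival proportional to genetic fitness.
#' @return Object of class `life_history`.
#' @export
life_history <- function(breeding_age = 7L, breeding_interval = 2L,
                         max_age = 40L,
                         age_factor_mode = c("mortality", "survival"),
                         fecundity = 1, density_release_max = 2) {
  age_factor_mode <- match.arg(age_factor_mode)
  assert_prob(fecundity, "fecundity")
  if (density_release_max < 1)
    stop_hylopop("`density_release_max` must be >= 1")
  structure(list(breeding_age = as.integer(breeding_age),
                 breeding_interval = as.integer(breeding_interval),
                 max_age = as.integer(max_age),
                 age_factor_mode = age_factor_mode,
                 fecundity = fecundity,
                 density_release_max = density_release_max),
            class = "life_history")
}

#' Age factor of the survival probability
#'
#' @param age integer age(s) in years.
#' @param mode `"mortality"` (default; factor = 1 - age-specific mortality)
#'   or `"survival"` (the literal table value).
#' @return Numeric factor(s) in \[0, 1\]; 0 beyond age 40.
#' @export
age_survival_factor <- function(age, mode = c("mortality", "survival")) {
  mode <- match.arg(mode)
  cpp_age_factor(as.integer(age), mode)
}

#' Draw mutation fitness effects
#'
#' Samples `n` new-mutation effects from the configured DFE: selection
#' coefficient, dominance coefficient from the s -> h step map, and the
#' deleterious class label.
#'
#' @param n number of draws.
#' @param dfe a [dfe_config()].
#' @return Data frame with `s`, `h`, `class` (factor: neutral, weak,
#'   moderate, strong, very_strong).
#' @export
draw_mutation_effect <- function(n, dfe = dfe_config()) {
  stopifnot(inherits(dfe, "dfe_config"))
  d <- cpp_draw_effects(as.integer(n), dfe$neutral_prop, dfe$gamma_shape,
                        dfe$gamma_mean)
  data.frame(s = d$s, h = d$h,
             class = factor(mutation_class_labels()[d$cls + 1L],
                            levels = mutation_class_labels()))
}

mutation_class_labels <- function()
  c("neutral", "weak", "moderate", "strong", "very_strong")

#' Dominance coefficient implied by a selection coefficient
#'
#' @param s selection coefficient(s), <= 0.
#' @return Dominance coefficient(s) under the step map used by the
#'   simulator (0.5 for neutral s = 0, where dominance is inconsequential).
#' @export
dominance_from_s <- function(s) cpp_h_from_s(as.numeric(s))

#' Deleterious class of a selection coefficient
#'
#' Very strong: s <= -0.1; strong: -0.1 < s < -0.01; moderate:
#' -0.01 <= s < -0.001; weak: -0.001 <= s < 0; neutral: s = 0.
#'
#' @param s selection coefficient(s).
#' @return Factor of class labels.
#' @export
mutation_class_from_s <- function(s) {
  factor(mutation_class_labels()[cpp_class_from_s(as.numeric(s)) + 1L],
         levels = mutation_class_labels())
}

#' Multiplicative fitness of a diploid genotype list
#'
#' Absolute fitness of an individual given its mutations: a factor (1 + s)
#' per homozygous mutation and (1 + h s) per heterozygous mutation,
#' multiplied across loci and floored at 0.
#'
#' @param s selection coefficients of the individual's mutations.
#' @param h dominance coefficients (defaults to the s -> h map).
#' @param zygosity character vector, `"hom"` or `"het"`, per mutation.
#' @return Absolute fitness (>= 0). Mutation-free input gives 1.
#' @export
individual_fitness <- function(s, h = dominance_from_s(s), zygosity) {
  if (length(s) == 0L) return(1)
  stopifnot(length(s) == length(zygosity), length(h) == length(s),
            all(zygosity %in% c("hom", "het")))
  fac <- ifelse(zygosity == "hom", 1 + s, 1 + h * s)
  max(0, prod(pmax(fac, 0)))
}

# K and duration rescaling for demographic epochs: carrying capacities at
# census scale (< 10 individuals after scaling) are kept as printed, and
# their epoch durations are then also kept (drift per generation at a fixed
# census K does not rescale).
scale_K <- function(K, q) ifelse(K * q >= 10, round(K * q), K)

#' Demographic scenario for the forward simulator
#'
#' An ordered sequence of epochs, each a duration in years with a carrying
#' capacity that may ramp linearly from `K_start` to `K_end`, optionally
#' followed by a split of the population into two lineages (A and B) held at
#' separate carrying capacities for `split$duration` years.
#'
#' @param epochs data frame with columns `duration_years`, `K_start`,
#'   `K_end`.
#' @param split `NULL` or a list with `duration`, `K_A`, `K_B`.
#' @param label scenario label.
#' @return Object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(epochs, split = NULL, label = "custom") {
  stopifnot(is.data.frame(epochs),
            all(c("duration_years", "K_start", "K_end") %in% names(epochs)),
            all(epochs$duration_years > 0), all(epochs$K_start > 0),
            all(epochs$K_end > 0))
  if (!is.null(split))
    stopifnot(all(c("duration", "K_A", "K_B") %in% names(split)))
  structure(list(epochs = epochs, split = split, label = label),
            class = "demographic_scenario")
}

#' The inferred gibbon demographic scenario
#'
#' Five sequential phases: (i) ancestral burn-in at K = 10,000 for 50,000
#' years; (ii) a pre-LGM bottleneck at K = 500 for 20,000 years; (iii) a
#' post-glacial expansion ramping to a peak K of 20,000 over 15,000 years;
#' (iv) a decline to K = 3000 lasting until ~450 years ago; (v) a split 450
#' years ago into lineages A and B whose sizes continue to decline, reaching
#' K = 6 (A) and K = 5 (B) at the present. The post-split decline is a
#' linear K ramp from the lineages' proportional share of the pre-split
#' capacity down to the present values (a step collapse is available by
#' setting `split$K_A_start`/`K_B_start` equal to `K_A`/`K_B`). With
#' `scale_factor` q < 1, carrying capacities and epoch durations are
#' multiplied by q, except that census-scale capacities (the split lineages)
#' and their durations are kept as printed.
#'
#' @param scale_factor desk-run rescaling q in (0, 1].
#' @return A [demographic_scenario()].
#' @export
gibbon_scenario <- function(scale_factor = 1) {
  q <- scale_factor
  epochs <- data.frame(
    duration_years = round(c(50000, 20000, 15000, 4550) * q),
    K_start = scale_K(c(10000, 500, 500, 3000), q),
    K_end = scale_K(c(10000, 500, 20000, 3000), q))
  k_last <- epochs$K_end[4]
  demographic_scenario(epochs,
                       split = list(duration = 450, K_A = 6, K_B = 5,
                                    K_A_start = round(k_last * 6 / 11),
                                    K_B_start = round(k_last * 5 / 11)),
                       label = "gibbon")
}

#' Island-control demographic scenario
#'
#' Identical to [gibbon_scenario()] but without the post-glacial expansion
#' phase: after the LGM bottleneck the population declines continuously
#' (linear ramp in K) from the bottleneck size to the present census size
#' over the same total time span, then splits into the two lineages.
#'
#' @param scale_factor desk-run rescaling q in (0, 1].
#' @return A [demographic_scenario()].
#' @export
island_scenario <- function(scale_factor = 1) {
  q <- scale_factor
  epochs <- data.frame(
    duration_years = round(c(50000, 20000, 19550) * q),
    K_start = scale_K(c(10000, 500, 500), q),
    K_end = c(scale_K(c(10000, 500), q), 11))
  demographic_scenario(epochs,
                       split = list(duration = 450, K_A = 6, K_B = 5,
                                    K_A_start = 6, K_B_start = 5),
                       label = "island_control")
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat(sprintf("demographic_scenario '%s': %d epochs%s\n", x$label,
              nrow(x$epochs),
              if (is.null(x$split)) "" else
                sprintf(" + split (%d y, K_A=%g, K_B=%g)", x$split$duration,
                        x$split$K_A, x$split$K_B)))
  print(x$epochs)
  invisible(x)
}
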