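test_that("trio generator is Mendelian before dropout and records truth exactly", {
  cfg <- synth_config(n_sites = 4000, n_individuals = 12, ado_rate = 0,
                      seed = 3)
  out <- gen_trios(cfg)
  expect_equal(nrow(out$truth), 0L)
  # no dropout: no Mendelian-inconsistency events at all
  est <- count_mendelian_ado(out$trios, per_allele = FALSE)
  expect_identical(est$n_events, 0L)
  expect_gt(est$n_informative, 0L)
})

test_that("injected dropout fraction matches the configured per-allele rate", {
  cfg <- synth_config(n_sites = 10000, n_individuals = 10, ado_rate = 0.05,
                      seed = 11)
  out <- gen_trios(cfg)
  # opportunities = 2 alleles per true heterozygous genotype; true hets are
  # the observed hets plus every genotype in the truth record
  n_het_true <- sum(out$trios$father == 1L, na.rm = TRUE) +
    sum(out$trios$mother == 1L, na.rm = TRUE) +
    sum(out$trios$offspring == 1L, na.rm = TRUE) + nrow(out$truth)
  n_dropped <- sum(out$truth$n_dropped)
  opportunities <- 2 * n_het_true
  frac <- n_dropped / opportunities
  expect_lt(abs(frac - 0.05), binom_ci(0.05, opportunities, z = 2.58))
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- synth_config(n_sites = 500, n_individuals = 5, ado_rate = 0.1,
                      genotype_error_rate = 0.05, seed = 9)
  expect_identical(gen_trios(cfg), gen_trios(cfg))
  expect_identical(gen_duplicate_libraries(cfg), gen_duplicate_libraries(cfg))
  expect_identical(gen_two_lineage_panel(cfg), gen_two_lineage_panel(cfg))
  expect_identical(gen_phased_pedigree(10, 0.3, 50, seed = 4),
                   gen_phased_pedigree(10, 0.3, 50, seed = 4))
})

test_that("degenerate MAF configurations are rejected by name", {
  cfg <- synth_config(seed = 1)
  cfg$maf_distribution <- list(dist = "uniform", min = 0, max = 0)
  expect_error(gen_trios(cfg), "uniform")
  cfg$maf_distribution <- list(dist = "nosuch")
  expect_error(gen_trios(cfg), "nosuch")
})

test_that("duplicate libraries differ only at injected error sites", {
  cfg <- synth_config(n_sites = 20000, n_individuals = 3,
                      genotype_error_rate = 0.03, seed = 21)
  dup <- gen_duplicate_libraries(cfg)
  # discrepancies exactly at the recorded discordant sites
  idx <- which(dup$libA$gt != dup$libB$gt)
  expect_identical(sort(idx),
                   sort((dup$discordant_sites$site - 1L) * nrow(dup$libA$gt) +
                          dup$discordant_sites$row))
  # every discordant site appears in the error truth record
  key <- paste(dup$discordant_sites$row, dup$discordant_sites$site)
  expect_true(all(key %in% paste(dup$truth$row, dup$truth$site)))
  # discordance within 99% CI of 2e(1-e) + e^2/2
  d <- genotype_discordance(dup$libA, dup$libB)
  e <- 0.03
  expected <- 2 * e * (1 - e) + e^2 / 2
  expect_lt(abs(as.numeric(d) - expected),
            binom_ci(expected, attr(d, "n_compared"), z = 2.58))

  none <- gen_duplicate_libraries(synth_config(n_sites = 1000,
                                               n_individuals = 3,
                                               genotype_error_rate = 0,
                                               seed = 2))
  expect_identical(none$libA$gt, none$libB$gt)
  expect_error(synth_config(n_individuals = 0), "positive")
})

test_that("two-lineage divergence grows with split time and is null at zero", {
  base <- synth_config(n_sites = 3000, n_individuals = 20, seed = 5,
                       drift_ne = 50)
  base$split_generations <- 0L
  p0 <- gen_two_lineage_panel(base)
  f0 <- attr(p0, "freqs")
  expect_identical(f0$A, f0$B)  # no drift at split 0
  base$split_generations <- 5L
  short <- gen_two_lineage_panel(base)
  base$split_generations <- 100L
  long <- gen_two_lineage_panel(base)
  div <- function(p) {
    f <- attr(p, "freqs")
    mean((f$A - f$B)^2)
  }
  # Wright-Fisher drift oracle: E[(fA-fB)^2] = 2 f0(1-f0) (1-(1-1/2Ne)^g)
  fr <- attr(long, "freqs")$ancestral
  exp_long <- mean(2 * fr * (1 - fr) * (1 - (1 - 1 / 100)^100))
  expect_gt(div(long), div(short))
  expect_lt(abs(div(long) - exp_long) / exp_long, 0.2)
  expect_error(gen_two_lineage_panel(synth_config(n_individuals = 3,
                                                  seed = 1)),
               "2 individuals per lineage")
})

test_that("phased pedigrees are parental mosaics with exact truth crossovers", {
  none <- gen_phased_pedigree(20, 0, 100, seed = 6)
  expect_true(all(apply(none$gametes, 1, function(g) length(unique(g)) == 1)))
  expect_true(all(lengths(none$truth_crossovers) == 0))

  half <- gen_phased_pedigree(200, 0.5, 100, seed = 7)
  sw <- half$gametes[, -1] != half$gametes[, -100]
  expect_lt(abs(mean(sw) - 0.5), binom_ci(0.5, length(sw), z = 2.58))
  # switches occur exactly at the recorded crossover intervals
  for (i in c(1, 57, 200)) {
    expect_identical(unname(which(half$gametes[i, -1] !=
                                    half$gametes[i, -100])),
                     half$truth_crossovers[[i]])
  }
  expect_error(gen_phased_pedigree(5, 0.1, 1, seed = 1), "adjacent")
})
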