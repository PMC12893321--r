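test_that("mutation effects follow the DFE and the s -> h step map", {
  expect_equal(dominance_from_s(-0.2), 0)
  expect_equal(dominance_from_s(-0.1), 0)      # boundary: more recessive class
  expect_equal(dominance_from_s(-0.05), 0.01)
  expect_equal(dominance_from_s(-0.01), 0.1)   # printed: h = 0.1 for s >= -0.01
  expect_equal(dominance_from_s(-0.005), 0.1)
  expect_equal(dominance_from_s(-0.0005), 0.4)
  expect_identical(as.character(mutation_class_from_s(c(-0.2, -0.05, -0.005,
                                                        -5e-4, 0))),
                   c("very_strong", "strong", "moderate", "weak", "neutral"))
  set.seed(41)
  d <- draw_mutation_effect(1e5)
  p_neut <- mean(d$s == 0)
  expect_lt(abs(p_neut - 0.3), binom_ci(0.3, 1e5, z = 2.58))
  sdel <- d$s[d$s < 0]
  # gamma mean of the deleterious tail (truncation at -1 is negligible mass)
  se <- sd(sdel) / sqrt(length(sdel))
  expect_lt(abs(mean(sdel) - (-0.01314833)), 3.5 * se + 2e-4)
  # h consistent with s for every draw
  expect_equal(d$h[d$s < 0], dominance_from_s(d$s[d$s < 0]))
})

test_that("individual fitness is multiplicative with dominance", {
  expect_equal(individual_fitness(numeric(0), zygosity = character(0)), 1)
  expect_equal(individual_fitness(-0.1, zygosity = "hom"), 0.9)
  expect_equal(individual_fitness(-0.1, h = 0.01, zygosity = "het"), 0.999)
  expect_equal(individual_fitness(c(-0.1, -0.1), h = c(0, 0.01),
                                  zygosity = c("hom", "het")),
               0.9 * 0.999)
  expect_equal(individual_fitness(-1, zygosity = "hom"), 0)
})

test_that("age factors follow the printed table in both readings", {
  expect_equal(age_survival_factor(0, "survival"), 0.1)
  expect_equal(age_survival_factor(38, "survival"), 0.5)
  expect_equal(age_survival_factor(0, "mortality"), 0.9)
  expect_equal(age_survival_factor(c(1, 4, 7, 20, 33, 38), "mortality"),
               1 - c(0.05, 0.03, 0.10, 0.05, 0.25, 0.50))
  expect_equal(age_survival_factor(41, "survival"), 0)  # beyond max age
})

test_that("meiosis respects gene cohesion, assortment and crossover rate", {
  set.seed(43)
  # no crossover, no mutation: each chromosome copies one parental haplotype
  g <- hylopop:::cpp_test_gametes(100, 4, 0, integer(0), integer(0), 50, 0)
  for (r in 1:50) {
    src <- g$sources[r, ]
    expect_true(all(apply(matrix(src, nrow = 25), 2,
                          function(x) length(unique(x)) == 1)))
  }
  # chromosomes assort independently: both sources appear
  expect_gt(sd(g$sources), 0)
  # crossover frequency per interval matches the layout rate of 1e-3
  g <- hylopop:::cpp_test_gametes(200, 1, 1e-3, integer(0), integer(0),
                                  10000, 0)
  sw <- g$sources[, -1] != g$sources[, -200]
  expect_lt(abs(mean(sw) - 1e-3), binom_ci(1e-3, length(sw), z = 3))
  # mutations in the same gene are never separated
  g <- hylopop:::cpp_test_gametes(50, 2, 0.5, c(rep(7L, 3), 20L),
                                  c(7L, 30L), 400, 0)
  for (r in 1:400) {
    ids <- g$gametes[[r]]
    h1_gene7 <- sum(ids %in% 0:2)       # the three h1 mutations in gene 7
    h2_gene7 <- sum(ids == 4L)          # the h2 mutation in gene 7
    expect_true(h1_gene7 %in% c(0L, 3L))
    expect_true(!(h1_gene7 == 3L && h2_gene7 == 1L))  # one haplotype per gene
  }
})

test_that("neutral configurations accumulate zero load and drift like Wright-Fisher", {
  lay <- test_layout()
  sc <- demographic_scenario(data.frame(duration_years = 400,
                                        K_start = 60, K_end = 60),
                             label = "neutral")
  r <- run_scenario(sc, lay, dfe = neutral_dfe(), seed = 47,
                    record_every = 50, roh_subsample = 20)
  tr <- r$trajectory
  cols <- grep("realized|masked", names(tr), value = TRUE)
  expect_true(all(as.matrix(tr[!is.na(tr$froh500), cols]) == 0))

  # Wright-Fisher limit: the implied drift Ne from allele-frequency variance
  # is consistent across two successive windows (F_2T = 1 - (1-F_T)^2)
  freqs_of <- function(pop) {
    f <- pop_mutation_freqs(pop)
    setNames(f$freq, f$id)
  }
  p0 <- freqs_of(r$population)
  c1 <- continue_population(r$population, years = 100, K = 60, layout = lay,
                            dfe = neutral_dfe(), seed = 48,
                            record_every = 100)
  p1 <- freqs_of(c1$population)
  c2 <- continue_population(c1$population, years = 100, K = 60, layout = lay,
                            dfe = neutral_dfe(), seed = 49,
                            record_every = 100)
  p2 <- freqs_of(c2$population)
  fstat <- function(pa, pb) {
    ids <- names(pa)[pa > 0.1 & pa < 0.9]
    b <- pb[ids]; b[is.na(b)] <- 0
    a <- pa[ids]
    mean((b - a)^2 / (a * (1 - a)))
  }
  f1 <- fstat(p0, p1)              # one 10-generation window
  f2 <- fstat(p0, p2)              # two windows
  expect_gt(f1, 0)
  # consistency of the implied per-window inbreeding increment
  pred_f2 <- 1 - (1 - f1)^2
  expect_lt(abs(f2 - pred_f2) / pred_f2, 0.5)
})

test_that("scenario runs are deterministic and respect capacity and ROH ordering", {
  lay <- test_layout()
  sc <- demographic_scenario(data.frame(duration_years = 300,
                                        K_start = 50, K_end = 50),
                             label = "flat")
  a <- run_scenario(sc, lay, seed = 53, record_every = 25)
  b <- run_scenario(sc, lay, seed = 53, record_every = 25)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$population, b$population)
  tr <- a$trajectory
  ok <- !is.na(tr$froh500)
  # F_ROH(>=1Mb) <= F_ROH(>=500kb) at every recorded point
  expect_true(all(tr$froh1mb[ok] <= tr$froh500[ok] + 1e-12))
  # population stays within the density-regulation band around K
  expect_true(all(tr$N <= 50 * 1.6))
})

test_that("bottleneck raises and expansion lowers inbreeding and load", {
  lay <- test_layout()
  sc <- gibbon_scenario(scale_factor = lay$scale_factor)
  f_burn <- f_lgm <- f_peak <- l_burn <- l_lgm <- l_peak <- numeric(0)
  for (seed in 61:63) {
    r <- run_scenario(sc, lay, seed = seed, record_every = 50)
    tr <- r$trajectory
    at <- function(yr) tr[tr$year == yr, ]
    f_burn <- c(f_burn, at(2500)$froh500)
    f_lgm <- c(f_lgm, at(3500)$froh500)
    f_peak <- c(f_peak, at(4250)$froh500)
    l_burn <- c(l_burn, at(2500)$realized_weak)
    l_lgm <- c(l_lgm, at(3500)$realized_weak)
    l_peak <- c(l_peak, at(4250)$realized_weak)
  }
  expect_gt(mean(f_lgm), mean(f_burn))   # bottleneck inflates F_ROH
  expect_lt(mean(f_peak), mean(f_lgm))   # expansion deflates it
  expect_gt(mean(l_lgm), mean(l_burn))   # realized load rises in bottleneck
  expect_lt(mean(l_peak), mean(l_lgm))   # and falls during expansion
})
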