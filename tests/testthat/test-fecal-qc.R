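test_that("Mendelian ADO counting follows the two diagnostic rules", {
  # hom x het parents, offspring homozygous for the absent allele: one event
  est <- count_mendelian_ado(make_trios(0, 1, 2), per_allele = FALSE)
  expect_identical(est$n_events, 1L)
  expect_identical(est$n_informative, 1L)
  expect_equal(est$rate, 1)
  # allele-relabelled mirror of the same rule
  expect_identical(count_mendelian_ado(make_trios(2, 1, 0),
                                       per_allele = FALSE)$n_events, 1L)
  # opposite homozygotes with a heterozygous offspring: consistent
  expect_identical(count_mendelian_ado(make_trios(0, 2, 1),
                                       per_allele = FALSE)$n_events, 0L)
  # opposite homozygotes with any homozygous offspring: event
  expect_identical(count_mendelian_ado(make_trios(0, 2, 0),
                                       per_allele = FALSE)$n_events, 1L)
  expect_identical(count_mendelian_ado(make_trios(0, 2, 2),
                                       per_allele = FALSE)$n_events, 1L)
  # het x het is uninformative; missing genotypes are excluded
  expect_error(count_mendelian_ado(make_trios(1, 1, 2)), "informative")
  expect_error(count_mendelian_ado(make_trios(0, NA, 2)), "informative")
})

test_that("per-allele ADO estimate recovers injected rates on synthetic trios", {
  for (rate in c(0.01, 0.05, 0.10)) {
    cfg <- synth_config(n_sites = 10000, n_individuals = 10,
                        ado_rate = rate, seed = 100 + round(1000 * rate))
    out <- gen_trios(cfg)
    est <- count_mendelian_ado(out$trios)
    # invert the binomial 95% CI of the raw event rate through the same
    # detection model to get a CI for the per-allele rate
    ci <- stats::binom.test(est$n_events, est$n_informative)$conf.int
    lo <- hylopop:::invert_ado_rate(ci[1], out$trios$maf)
    hi <- hylopop:::invert_ado_rate(ci[2], out$trios$maf)
    expect_true(rate >= lo && rate <= hi,
                label = sprintf("rate %.2f inside [%.4f, %.4f]",
                                rate, lo, hi))
  }
})

test_that("duplicate-library discordance is the jointly-called differing fraction", {
  expect_equal(as.numeric(genotype_discordance(matrix(0:2, 1),
                                               matrix(0:2, 1))), 0)
  d <- genotype_discordance(matrix(c(0L, 1L, 2L), 1),
                            matrix(c(0L, 2L, 2L), 1))
  expect_equal(as.numeric(d), 1 / 3)
  # symmetry
  a <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 10)
  b <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 10)
  expect_equal(as.numeric(genotype_discordance(a, b)),
               as.numeric(genotype_discordance(b, a)))
  expect_equal(as.numeric(genotype_discordance(a, a)), 0)
  expect_error(genotype_discordance(matrix(NA_integer_, 2, 2),
                                    matrix(NA_integer_, 2, 2)),
               "jointly-called")
  # exact agreement with the generator's truth record
  dup <- gen_duplicate_libraries(synth_config(n_sites = 5000,
                                              n_individuals = 4,
                                              genotype_error_rate = 0.02,
                                              seed = 8))
  d <- genotype_discordance(dup$libA, dup$libB)
  expect_equal(as.numeric(d),
               nrow(dup$discordant_sites) / attr(d, "n_compared"))
})

test_that("ADO-depth profiles locate the plateau", {
  # two site blocks with different injected dropout, binned by depth
  hi <- gen_trios(synth_config(n_sites = 6000, n_individuals = 10,
                               ado_rate = 0.15, seed = 31))$trios
  lo <- gen_trios(synth_config(n_sites = 6000, n_individuals = 10,
                               ado_rate = 0.01, seed = 32))$trios
  glue <- function(a, b, depths) {
    gt <- function(f) cbind(a[[f]], b[[f]])
    dp <- lapply(1:3, function(i)
      matrix(rep(depths, each = 10 * 6000), nrow = 10))
    names(dp) <- c("father", "mother", "offspring")
    trio_set(gt("father"), gt("mother"), gt("offspring"), depth = dp)
  }
  trios <- glue(hi, lo, c(5, 20))
  prof <- ado_depth_profile(trios, depth_bins = c(0, 10, 15), tolerance = 0.01)
  expect_equal(nrow(prof$profile), 3L)
  expect_identical(prof$profile$n_informative[2], 0L)  # empty middle bin
  r <- prof$profile$rate
  expect_gt(r[1], r[3])               # dropout decays with depth
  expect_equal(prof$plateau_depth, 15) # step location
  # constant dropout: flat profile, plateau at the first bin
  flat <- glue(hi, hi, c(5, 20))
  pf <- ado_depth_profile(flat, depth_bins = c(0, 10, 15), tolerance = 0.01)
  expect_equal(pf$plateau_depth, 0)
})

test_that("Solow coverage model is recovered on noiseless curves", {
  x <- seq(15, 40, by = 5)
  y <- 0.9 - exp(-0.1 * x + 1.0)
  fit <- fit_solow(x, y)
  expect_lt(abs(fit$a - 0.9) / 0.9, 1e-4)
  expect_lt(abs(fit$b - 0.1) / 0.1, 1e-4)
  expect_lt(abs(fit$c - 1.0) / 1.0, 1e-4)
  # fitted curve is monotone increasing over the observed range for b > 0
  grid <- predict(fit, seq(min(x), max(x), length.out = 50))
  expect_true(all(diff(grid) > 0))
  # optimizer residual trace never increases (beyond numerical-zero noise)
  expect_true(all(diff(fit$rss_trace) <= 1e-8))
  # marginal gain at the tipping point equals the tolerance
  gain <- function(x) fit$b * exp(-fit$b * x + fit$c)
  expect_equal(gain(fit$tipping_point), fit$gain_tolerance, tolerance = 1e-8)
})

test_that("degenerate Solow inputs are rejected", {
  expect_error(fit_solow(c(5, 10, 15), rep(0.5, 3)), "degenerate")
  expect_error(fit_solow(c(5, 5, 5), c(0.1, 0.2, 0.3)), "distinct")
  expect_error(fit_solow(c(5, 10, 15), c(0.1, 0.2, 1.3)), "fraction")
})
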