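test_that("genome heterozygosity is het sites over effective length", {
  expect_equal(genome_heterozygosity(0, 1e6), 0)
  expect_equal(genome_heterozygosity(1000, 1e6), 1e-3)
  expect_error(genome_heterozygosity(10, 0), "> 0")
  expect_error(genome_heterozygosity(10, 5), "more heterozygous")
  # windowed rates recombine exactly to the genome-wide value
  set.seed(2)
  pos <- sort(sample.int(1e7, 4000))
  win <- window_heterozygosity(pos, 1e7, window = 1e6)
  expect_equal(sum(win$n_het), length(pos))
  expect_equal(sum(win$het * (win$end - win$start + 1)) / 1e7,
               genome_heterozygosity(length(pos), 1e7))
})

test_that("expected heterozygosity is 2p(1-p)", {
  expect_equal(expected_heterozygosity(0.5), 0.5)
  expect_equal(expected_heterozygosity(1), 0)
  expect_equal(expected_heterozygosity(0.9), 0.18)
  expect_error(expected_heterozygosity(1.2), "\\[0, 1\\]")
})

test_that("realized and masked load follow the homozygous-derived formula", {
  e <- genetic_load(c(rep(1L, 5)), polarize = FALSE)
  expect_equal(e$realized, 0); expect_equal(e$masked, 1)
  e <- genetic_load(c(rep(2L, 3), rep(1L, 4)), polarize = FALSE)
  expect_equal(e$realized, 0.6)
  e <- genetic_load(rep(2L, 7), polarize = FALSE)
  expect_equal(e$realized, 1)
  # no derived alleles: defined as 0/0 with a flag, not an error
  e <- genetic_load(rep(0L, 10), polarize = FALSE)
  expect_true(e$no_derived)
  expect_equal(e$realized + e$masked, 0)
  # invariant: realized + masked = 1 whenever the denominator is positive
  set.seed(4)
  for (i in 1:25) {
    gt <- matrix(sample(c(0:2, NA), 300, replace = TRUE,
                        prob = c(.5, .2, .2, .1)), nrow = 5)
    tab <- genetic_load(gt)
    ok <- !tab$no_derived
    expect_true(all(abs(tab$realized[ok] + tab$masked[ok] - 1) < 1e-12))
  }
  # polarization: the sample major allele is ancestral
  gt <- matrix(c(2L, 2L, 2L, 1L), nrow = 4)  # alt is the major allele
  tab <- genetic_load(gt)
  expect_equal(tab$n_hom_derived, c(0L, 0L, 0L, 0L))
  expect_equal(tab$n_het, c(0L, 0L, 0L, 1L))
})

test_that("Grantham classification splits at 150 inclusive", {
  expect_identical(classify_missense(150), "deleterious")
  expect_identical(classify_missense(149), "benign")
  expect_identical(classify_missense(215), "deleterious")
  expect_identical(classify_missense(5), "benign")
  expect_error(classify_missense(4), "\\[5, 215\\]")
  expect_error(classify_missense(216), "\\[5, 215\\]")
})

test_that("F_ROH sums thresholded segment lengths over genome length", {
  segs <- data.frame(chrom = "1", start = c(1, 7e5 + 1),
                     end = c(6e5, 7e5 + 5e5))
  expect_equal(froh(segs, 5e5, 2e6)$froh, 0.55)
  expect_equal(froh(data.frame(chrom = "1", start = 1, end = 4e5),
                    5e5, 2e6)$froh, 0)
  expect_equal(froh(data.frame(chrom = character(), start = numeric(),
                               end = numeric()), 5e5, 2e6)$froh, 0)
  expect_error(froh(data.frame(chrom = "1", start = c(1, 3e5),
                               end = c(4e5, 6e5)), 5e5, 2e6), "overlap")
  # monotone non-increasing in the length threshold
  set.seed(7)
  len <- sample.int(9e5, 20)
  gaps <- sample.int(1e6, 20)
  starts <- cumsum(c(1, head(len + gaps, -1)))
  segs <- data.frame(chrom = "1", start = starts, end = starts + len)
  vals <- vapply(c(1e5, 5e5, 1e6, 2e6),
                 function(m) froh(segs, m, 5e7)$froh, numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("GC4 covers exactly the fourfold-degenerate third positions", {
  r <- gc4("GCAGCCGCGGCT")  # four alanine codons, thirds A,C,G,T
  expect_equal(r$n_fourfold_sites, 4L)
  expect_equal(r$gc4, 0.5)
  expect_true(is.na(gc4("ATGTGG")$gc4))      # Met + Trp: no fourfold codon
  expect_equal(gc4("GGGCCGACGGTG")$gc4, 1)   # all fourfold thirds G
  expect_error(gc4("ATGTAAGGG"), "stop codon")
  expect_silent(gc4("ATGGGGTAA"))            # terminal stop is fine
  expect_error(gc4("ATGGG"), "divisible by 3")
  # invariant to synonymous third-position changes preserving GC count
  expect_equal(gc4("GCAGCCGCGGCT")$gc4, gc4("GCTGCGGCCGCA")$gc4)
})

test_that("GC4 median split assigns high and low recombination classes", {
  rec <- data.frame(gene_id = letters[1:4], gc4 = c(0.1, 0.2, 0.8, 0.9))
  p <- partition_gc4(rec)
  expect_identical(p$recombination_class, c("low", "low", "high", "high"))
  rec <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    gc4 = seq(0.01, 1, length.out = 100))
  p <- partition_gc4(rec)
  expect_equal(sum(p$recombination_class == "high"), 50L)
  # ties at the median go to the configured class, deterministically
  rec <- data.frame(gene_id = letters[1:5], gc4 = c(0.2, 0.5, 0.5, 0.5, 0.9))
  expect_identical(partition_gc4(rec)$recombination_class,
                   c("low", "low", "low", "low", "high"))
  expect_identical(partition_gc4(rec, ties = "high")$recombination_class,
                   c("low", "high", "high", "high", "high"))
  expect_error(partition_gc4(data.frame(gene_id = c("a", "b"),
                                        gc4 = c(0.5, 0.5))), "identical")
})

test_that("pedigree crossover counting matches phased truth exactly", {
  # parent AB/ab, offspring gamete Ab: one crossover over one adjacent pair
  expect_equal(as.numeric(pedigree_recombination_rate(matrix(c(0L, 1L), 1))),
               1)
  expect_equal(as.numeric(pedigree_recombination_rate(
    matrix(c(0L, 0L, 0L, 1L, 1L, 1L), 2, byrow = TRUE))), 0)
  expect_error(pedigree_recombination_rate(matrix(0L, 3, 1)), "fewer than 2")
  # truth-record round trip and convergence at several rates
  for (r in c(0, 0.01, 0.5)) {
    ped <- gen_phased_pedigree(150, r, 120, seed = round(1000 * r) + 1)
    est <- pedigree_recombination_rate(ped)
    truth <- sum(lengths(ped$truth_crossovers)) / (150 * 119)
    expect_equal(as.numeric(est), truth)  # exact
    expect_lt(abs(est - r), binom_ci(max(r, 0.002), 150 * 119, z = 3) + 1e-9)
  }
  # region restriction uses only the requested loci
  ped <- gen_phased_pedigree(50, 0.2, 100, seed = 5)
  sub <- pedigree_recombination_rate(ped, region = c(10, 30))
  expect_equal(attr(sub, "n_pairs"), 50L * 20L)
})
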