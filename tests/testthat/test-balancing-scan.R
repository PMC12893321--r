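test_that("folded SFS bins by minor-allele count and conserves site totals", {
  # 2 diploids = 4 chromosomes; alt counts 1 and 3 fold to the same bin
  gt <- matrix(c(1L, 0L,   # site 1: alt count 1
                 2L, 1L),  # site 2: alt count 3
               nrow = 2)
  sfs <- folded_sfs(gt)
  expect_equal(unname(sfs), c(2L, 0L))
  # all sites at 50%: single occupied bin
  gt <- matrix(rep(1L, 20), nrow = 2)
  sfs <- folded_sfs(gt)
  expect_equal(unname(sfs), c(0L, 10L))
  # conservation: bin totals equal the segregating-site count
  set.seed(11)
  for (i in 1:20) {
    gt <- matrix(sample(0:2, 25 * 8, replace = TRUE), nrow = 5)
    ac <- colSums(gt)
    seg <- ac > 0 & ac < 10
    expect_equal(sum(folded_sfs(gt)), sum(seg))
  }
  expect_warning(folded_sfs(matrix(0L, 3, 4)), "segregating")
})

test_that("folded SFS matches the neutral 1/i spectrum on simulated data", {
  # sample derived counts from the neutral SFS (P(i) ~ 1/i), build genotypes
  # by permuting alleles over chromosomes, fold, and compare
  set.seed(13)
  n <- 10            # diploids -> 20 chromosomes
  n_sites <- 20000
  pi_unf <- (1 / (1:19)) / sum(1 / (1:19))
  counts <- sample(1:19, n_sites, replace = TRUE, prob = pi_unf)
  gt <- vapply(counts, function(k) {
    hap <- sample(c(rep(1L, k), rep(0L, 20 - k)))
    hap[seq(1, 20, 2)] + hap[seq(2, 20, 2)]
  }, integer(n))
  sfs <- folded_sfs(gt)
  exp_folded <- vapply(1:10, function(i) {
    p <- pi_unf[i] + if (i < 10) pi_unf[20 - i] else 0
    p * n_sites
  }, numeric(1))
  expect_true(all(abs(sfs - exp_folded) <
                    3 * sqrt(exp_folded * (1 - exp_folded / n_sites)) + 3))
})

test_that("clustered intermediate frequencies outscore spread frequencies", {
  core <- 0.35
  clustered <- beta_score(c(rep(core, 10), core), core = 11)
  spread <- beta_score(c(seq(0.01, 0.5, length.out = 10), core), core = 11)
  expect_gt(clustered, spread)
  expect_equal(beta_score(0.3, core = 1), 0)  # single-site baseline
  expect_error(beta_score(numeric(0), core = 1), "empty")
  expect_error(beta_score(c(0.2, 0.6), core = 1), "\\(0, 0.5\\]")
  # strand relabelling changes nothing once frequencies are folded
  f <- c(0.1, 0.3, 0.2, 0.45, 0.3)
  folded <- pmin(f, 1 - f)
  expect_equal(beta_score(folded, 3), beta_score(pmin(1 - f, f), 3))
})

test_that("top-fraction selection has exact size and stable tie-breaks", {
  s <- select_top(data.frame(position = 1:100, score = sample(100)))
  expect_equal(sum(s$selected), 5L)
  # all-equal scores: ceiling(0.05 n) selected, lowest positions first
  s <- select_top(data.frame(position = 1:30, score = rep(1, 30)))
  expect_equal(which(s$selected), 1:2)
  expect_error(select_top(numeric(0)), "no scores")
  # invariance under monotone transforms of the scores
  set.seed(17)
  for (i in 1:10) {
    sc <- data.frame(position = sample(1e6, 60), score = rnorm(60))
    a <- select_top(sc)
    sc2 <- sc; sc2$score <- exp(sc$score)
    b <- select_top(sc2)
    expect_identical(a$position[a$selected], b$position[b$selected])
  }
})

test_that("selected cores are enriched at synthetic balanced loci", {
  # frequency-clustered windows around "balanced" positions vs a uniform
  # background; the scan should pull its top scores from the balanced loci
  set.seed(19)
  n_bal <- 6
  bal_pos <- seq(5e4, 3e5, length.out = n_bal)
  # balancing selection maintains a cluster of intermediate-frequency
  # polymorphisms around the balanced site: extra linked variants at
  # frequencies concentrated near the balanced equilibrium
  linked <- unlist(lapply(bal_pos, function(b)
    round(b + runif(8, -800, 800))))
  pos <- sort(c(round(bal_pos), linked, sample.int(4e5, 400)))
  freqs <- runif(length(pos), 0.01, 0.5)
  for (b in bal_pos) {
    idx <- which(abs(pos - b) < 1000)
    freqs[idx] <- pmin(0.5, pmax(0.01, 0.35 + rnorm(length(idx), 0, 0.01)))
  }
  scan <- beta_scan(pos, freqs, window_size = 1000)
  top <- select_top(scan, fraction = 0.05)
  hits <- vapply(bal_pos, function(b)
    any(abs(top$position[top$selected] - b) < 1000), logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("gene-flank comparison reports paired and unpaired contrasts", {
  set.seed(23)
  n <- 40
  flat <- data.frame(gene_id = seq_len(n), gene = rep(0.2, n),
                     left_flank = rep(0.2, n), right_flank = rep(0.2, n))
  res <- flank_compare(flat)
  expect_null(res$left_vs_right)
  expect_null(res$gene_vs_flank_paired)
  # elevated gene rates are detected with the right sign
  up <- data.frame(gene_id = seq_len(n),
                   gene = 0.3 + rnorm(n, 0, 0.01),
                   left_flank = 0.1 + rnorm(n, 0, 0.01),
                   right_flank = 0.1 + rnorm(n, 0, 0.01))
  res <- flank_compare(up)
  expect_lt(res$gene_vs_flank_paired$p.value, 1e-4)
  expect_lt(res$gene_vs_flank_unpaired$p.value, 1e-4)
  # symmetric flanks: no left/right signal
  expect_gt(res$left_vs_right$p.value, 0.01)
  # genes missing a flank are excluded and counted
  up$left_flank[3] <- NA
  expect_equal(flank_compare(up)$n_excluded, 1L)
})
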