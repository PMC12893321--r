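#' Configuration for the synthetic-data generators
#'
#' Holds every knob of the synthetic genotype generators: panel size, the
#' minor-allele-frequency (MAF) spectrum, the per-allele dropout rate injected
#' into heterozygous calls, the per-genotype error rate used for duplicate
#' libraries, the read-depth distribution, and the lineage split time.
#' All generators are pure functions of (config, seed): the same config and
#' seed give bit-identical output.
#'
#' @param n_sites number of biallelic sites to simulate.
#' @param n_individuals number of individuals (for [gen_trios()] this is the
#'   number of trios).
#' @param maf_distribution a list naming the MAF distribution and its
#'   parameters. Supported: `list(dist = "uniform", min, max)` (default
#'   uniform on \[0.05, 0.5\], matching the usual MAF filter applied to
#'   noninvasive SNP panels) and `list(dist = "beta", shape1, shape2)`
#'   (rescaled to (0, 0.5\]).
#' @param ado_rate per-allele dropout probability in \[0, 1\]. Each true
#'   allele of a heterozygous genotype is independently unobserved with this
#'   probability; one dropped allele yields a false homozygote of the
#'   surviving allele, two dropped alleles yield a missing call.
#' @param genotype_error_rate per-genotype error probability used by
#'   [gen_duplicate_libraries()].
#' @param depth_distribution a list naming the per-genotype read-depth
#'   distribution: `list(dist = "nbinom", mu, size)` (default mu = 10,
#'   size = 5) or `list(dist = "poisson", lambda)`.
#' @param split_generations generations of independent drift separating the
#'   two lineages in [gen_two_lineage_panel()].
#' @param drift_ne diploid effective size used for the per-generation
#'   Wright-Fisher drift of lineage allele frequencies.
#' @param seed integer seed; every generator derives all randomness from it.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_sites = 10000L,
                         n_individuals = 10L,
                         maf_distribution = list(dist = "uniform",
                                                 min = 0.05, max = 0.5),
                         ado_rate = 0,
                         genotype_error_rate = 0,
                         depth_distribution = list(dist = "nbinom",
                                                   mu = 10, size = 5),
                         split_generations = 50L,
                         drift_ne = 100L,
                         seed = 1L) {
  assert_count(n_sites, "n_sites")
  assert_count(n_individuals, "n_individuals")
  assert_prob(ado_rate, "ado_rate")
  assert_prob(genotype_error_rate, "genotype_error_rate")
  assert_count(split_generations, "split_generations", positive = FALSE)
  assert_count(drift_ne, "drift_ne")
  if (is.null(maf_distribution$dist))
    stop_hylopop("`maf_distribution` must name a distribution via $dist")
  structure(list(n_sites = as.integer(n_sites),
                 n_individuals = as.integer(n_individuals),
                 maf_distribution = maf_distribution,
                 ado_rate = ado_rate,
                 genotype_error_rate = genotype_error_rate,
                 depth_distribution = depth_distribution,
                 split_generations = as.integer(split_generations),
                 drift_ne = as.integer(drift_ne),
                 seed = as.integer(seed)),
            class = "synth_config")
}

draw_maf <- function(cfg, n) {
  md <- cfg$maf_distribution
  f <- switch(md$dist,
    uniform = runif(n, md$min %||% 0.05, md$max %||% 0.5),
    beta = 0.5 * rbeta_safe(n, md$shape1, md$shape2),
    stop_hylopop(sprintf("unknown maf_distribution '%s'", md$dist)))
  if (all(f <= 0) || all(f >= 1))
    stop_hylopop(sprintf(
      "degenerate maf_distribution '%s': all sites fixed", md$dist))
  pmin(pmax(f, 0), 0.5)
}

rbeta_safe <- function(n, shape1, shape2) {
  if (is.null(shape1) || is.null(shape2))
    stop_hylopop("beta maf_distribution needs $shape1 and $shape2")
  stats::rbeta(n, shape1, shape2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

draw_depth <- function(cfg, n) {
  dd <- cfg$depth_distribution
  switch(dd$dist %||% "nbinom",
    nbinom = rnbinom(n, mu = dd$mu %||% 10, size = dd$size %||% 5),
    poisson = rpois(n, dd$lambda %||% 10),
    stop_hylopop(sprintf("unknown depth_distribution '%s'", dd$dist)))
}

# HWE genotype draws (alt-allele counts) at frequencies f, as an n x length(f)
# integer matrix.
rgeno_hwe <- function(n, f) {
  matrix(rbinom(n * length(f), 2L, rep(f, each = n)), nrow = n)
}

# Apply per-allele dropout to heterozygous entries of gt. Returns list(gt,
# truth) where truth records every genotype at which >= 1 allele was dropped.
inject_ado <- function(gt, ado_rate, member = "ind") {
  truth <- data.frame(member = character(), row = integer(), site = integer(),
                      n_dropped = integer(), true_gt = integer(),
                      obs_gt = integer(), stringsAsFactors = FALSE)
  if (ado_rate <= 0) return(list(gt = gt, truth = truth))
  het <- which(!is.na(gt) & gt == 1L)
  if (!length(het)) return(list(gt = gt, truth = truth))
  drop_ref <- rbinom(length(het), 1L, ado_rate) == 1L  # drop the ref allele
  drop_alt <- rbinom(length(het), 1L, ado_rate) == 1L  # drop the alt allele
  n_drop <- drop_ref + drop_alt
  affected <- which(n_drop > 0L)
  if (length(affected)) {
    idx <- het[affected]
    obs <- ifelse(n_drop[affected] == 2L, NA_integer_,
                  ifelse(drop_ref[affected], 2L, 0L))
    gt[idx] <- obs
    truth <- data.frame(member = member,
                        row = ((idx - 1L) %% nrow(gt)) + 1L,
                        site = ((idx - 1L) %/% nrow(gt)) + 1L,
                        n_dropped = n_drop[affected],
                        true_gt = 1L, obs_gt = obs,
                        stringsAsFactors = FALSE)
  }
  list(gt = gt, truth = truth)
}

#' Generate parent-parent-offspring trios with injected allele dropout
#'
#' Draws per-site minor-allele frequencies from the configured spectrum,
#' parents under Hardy-Weinberg proportions, offspring by Mendelian
#' transmission, then injects per-allele dropout into the heterozygous calls
#' of all three members. The returned truth record lists every dropout event,
#' which is sufficient to reconstruct the pre-dropout genotypes exactly.
#'
#' @param cfg a [synth_config()].
#' @return A list with `trios` (a [trio_set()], with per-genotype depths) and
#'   `truth` (data frame of dropout events: member, trio row, site, number of
#'   alleles dropped, true and observed genotype).
#' @export
gen_trios <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_individuals
    f <- draw_maf(cfg, cfg$n_sites)
    fa <- rgeno_hwe(n, f)
    mo <- rgeno_hwe(n, f)
    # one transmitted allele per parent: P(alt | gt) = gt / 2
    off <- matrix(rbinom(length(fa), 1L, fa / 2) +
                  rbinom(length(mo), 1L, mo / 2), nrow = n)
    a_fa <- inject_ado(fa, cfg$ado_rate, "father")
    a_mo <- inject_ado(mo, cfg$ado_rate, "mother")
    a_of <- inject_ado(off, cfg$ado_rate, "offspring")
    depth <- lapply(1:3, function(i)
      matrix(draw_depth(cfg, length(fa)), nrow = n))
    names(depth) <- c("father", "mother", "offspring")
    list(trios = trio_set(a_fa$gt, a_mo$gt, a_of$gt, depth = depth, maf = f),
         truth = rbind(a_fa$truth, a_mo$truth, a_of$truth))
  })
}

#' Generate duplicate sequencing libraries for the same individuals
#'
#' Emulates the duplicate-library design used to measure genotyping
#' discordance in low-input data: the same true genotypes are observed twice,
#' each observation independently corrupted at the configured per-genotype
#' error rate (an erroneous call is replaced by one of the two other genotype
#' classes, uniformly).
#'
#' @param cfg a [synth_config()].
#' @return A list with `libA`, `libB` (two [genotype_matrix()] objects over
#'   the same individuals and sites), `truth` (data frame of injected errors:
#'   library, individual, site, true and observed genotype) and
#'   `discordant_sites` (data frame of individual/site pairs at which the two
#'   libraries actually disagree).
#' @export
gen_duplicate_libraries <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_individuals < 1L) stop_hylopop("need at least one individual")
  with_seed(cfg$seed, {
    f <- draw_maf(cfg, cfg$n_sites)
    true_gt <- rgeno_hwe(cfg$n_individuals, f)
    corrupt <- function(gt, lib) {
      err <- which(rbinom(length(gt), 1L, cfg$genotype_error_rate) == 1L)
      truth <- data.frame(library = character(), row = integer(),
                          site = integer(), true_gt = integer(),
                          obs_gt = integer(), stringsAsFactors = FALSE)
      if (length(err)) {
        shift <- sample(1:2, length(err), replace = TRUE)
        obs <- (gt[err] + shift) %% 3L
        gt[err] <- obs
        truth <- data.frame(library = lib,
                            row = ((err - 1L) %% nrow(gt)) + 1L,
                            site = ((err - 1L) %/% nrow(gt)) + 1L,
                            true_gt = true_gt[err], obs_gt = obs,
                            stringsAsFactors = FALSE)
      }
      list(gt = gt, truth = truth)
    }
    a <- corrupt(true_gt, "A")
    b <- corrupt(true_gt, "B")
    ids <- sprintf("ind%03d", seq_len(cfg$n_individuals))
    rownames(a$gt) <- rownames(b$gt) <- ids
    diff_idx <- which(a$gt != b$gt)
    discordant <- data.frame(
      row = ((diff_idx - 1L) %% nrow(a$gt)) + 1L,
      site = ((diff_idx - 1L) %/% nrow(a$gt)) + 1L)
    list(libA = genotype_matrix(a$gt),
         libB = genotype_matrix(b$gt),
         truth = rbind(a$truth, b$truth),
         discordant_sites = discordant)
  })
}

#' Generate a two-lineage genotype panel with known divergence
#'
#' Starts from a shared ancestral allele-frequency spectrum and lets the two
#' lineages drift independently for `split_generations` Wright-Fisher
#' generations at diploid size `drift_ne`, then samples individuals under
#' Hardy-Weinberg proportions within each lineage. Between-lineage divergence
#' therefore increases with the configured split time and is zero in
#' expectation at `split_generations = 0`.
#'
#' @param cfg a [synth_config()]; `n_individuals` is split evenly between the
#'   lineages (at least 2 per lineage).
#' @return A [genotype_matrix()] with per-individual `lineage` labels ("A",
#'   "B") and an attribute `freqs` holding the ancestral and per-lineage true
#'   allele frequencies.
#' @export
gen_two_lineage_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n_a <- cfg$n_individuals %/% 2L
  n_b <- cfg$n_individuals - n_a
  if (n_a < 2L || n_b < 2L)
    stop_hylopop("need at least 2 individuals per lineage")
  with_seed(cfg$seed, {
    f0 <- draw_maf(cfg, cfg$n_sites)
    drift <- function(f) {
      for (g in seq_len(cfg$split_generations))
        f <- rbinom(length(f), 2L * cfg$drift_ne, f) / (2 * cfg$drift_ne)
      f
    }
    fa <- drift(f0)
    fb <- drift(f0)
    gt <- rbind(rgeno_hwe(n_a, fa), rgeno_hwe(n_b, fb))
    gm <- genotype_matrix(gt, lineage = rep(c("A", "B"), c(n_a, n_b)))
    attr(gm, "freqs") <- data.frame(ancestral = f0, A = fa, B = fb)
    gm
  })
}

#' Generate a phased pedigree with known crossover positions
#'
#' Builds a fully informative phased parent (haplotype 1 carries allele 0 at
#' every locus, haplotype 2 allele 1) and simulates `n_meioses` gametes with
#' independent crossovers in each inter-locus interval. Offspring haplotypes
#' are exact parental mosaics whose switch points are returned as the truth
#' record, so downstream crossover counting can be checked exactly.
#'
#' @param n_meioses number of gametes to simulate.
#' @param crossover_rate per-interval crossover probability in \[0, 1\].
#' @param n_loci number of phased loci (>= 2).
#' @param seed integer seed.
#' @return An object of class `phased_pedigree`: a list with `gametes`
#'   (n_meioses x n_loci matrix of parental-haplotype origins, 0 or 1),
#'   `truth_crossovers` (list of crossover interval indices per meiosis,
#'   interval i lying between loci i and i+1) and `n_loci`.
#' @export
gen_phased_pedigree <- function(n_meioses, crossover_rate, n_loci,
                                seed = 1L) {
  assert_count(n_meioses, "n_meioses")
  assert_prob(crossover_rate, "crossover_rate")
  assert_count(n_loci, "n_loci")
  if (n_loci < 2L) stop_hylopop("`n_loci` must be >= 2 (no adjacent pairs)")
  with_seed(seed, {
    start <- rbinom(n_meioses, 1L, 0.5)
    switches <- matrix(rbinom(n_meioses * (n_loci - 1L), 1L, crossover_rate),
                       nrow = n_meioses)
    # cumulative xor of switches gives the haplotype origin at each locus
    cums <- switches
    if (ncol(cums) > 1L)
      for (j in 2:ncol(cums)) cums[, j] <- cums[, j - 1L] + cums[, j]
    gametes <- cbind(start, (start + cums) %% 2L)
    colnames(gametes) <- sprintf("locus%04d", seq_len(n_loci))
    rownames(gametes) <- sprintf("meiosis%03d", seq_len(n_meioses))
    truth <- apply(switches, 1, function(s) which(s == 1L), simplify = FALSE)
    structure(list(gametes = gametes, truth_crossovers = truth,
                   n_loci = as.integer(n_loci),
                   crossover_rate = crossover_rate),
              class = "phased_pedigree")
  })
}

#' @export
print.phased_pedigree <- function(x, ...) {
  cat(sprintf("phased_pedigree: %d meioses x %d loci, %d true crossovers\n",
              nrow(x$gametes), x$n_loci,
              sum(lengths(x$truth_crossovers))))
  invisible(x)
}
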