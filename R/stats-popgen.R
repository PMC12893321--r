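#' Genome-wide heterozygosity
#'
#' Number of heterozygous sites divided by the effective (callable) length of
#' the reference genome, the standard per-bp diversity measure for a single
#' diploid individual.
#'
#' @param n_het_sites count of heterozygous sites.
#' @param effective_length callable genome length in bp (> 0).
#' @return Per-bp heterozygosity in \[0, 1\].
#' @export
genome_heterozygosity <- function(n_het_sites, effective_length) {
  assert_count(n_het_sites, "n_het_sites", positive = FALSE)
  if (!is.numeric(effective_length) || effective_length <= 0)
    stop_hylopop("`effective_length` must be > 0")
  h <- n_het_sites / effective_length
  if (h > 1) stop_hylopop("more heterozygous sites than callable bases")
  h
}

#' Heterozygosity in sliding windows
#'
#' Counts heterozygous sites in non-overlapping windows along a chromosome
#' and converts each to a per-bp rate; used e.g. to compare the genomic
#' heterozygosity distribution of hybrid offspring with their parents.
#'
#' @param het_pos integer positions (bp, 1-based) of heterozygous sites.
#' @param genome_length chromosome/genome length in bp.
#' @param window window size in bp (default 1 Mb).
#' @return Data frame with `start`, `end`, `n_het`, `het`.
#' @export
window_heterozygosity <- function(het_pos, genome_length, window = 1e6) {
  starts <- seq(1, genome_length, by = window)
  ends <- pmin(starts + window - 1, genome_length)
  idx <- findInterval(het_pos, starts)
  counts <- tabulate(idx, nbins = length(starts))
  data.frame(start = starts, end = ends, n_het = counts,
             het = counts / (ends - starts + 1))
}

#' Expected heterozygosity at a locus
#'
#' \eqn{H_e = 2p(1-p)} with `p` the major-allele frequency; maximal (0.5)
#' at p = 0.5 and zero when the locus is fixed.
#'
#' @param p major-allele frequency (or frequencies), in \[0, 1\].
#' @return Expected heterozygosity, same length as `p`.
#' @export
expected_heterozygosity <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop_hylopop("allele frequencies must lie in [0, 1]")
  2 * p * (1 - p)
}

#' Realized and masked genetic load from genotype counts
#'
#' For a set of sites carrying mutations of one deleterious class (or LoF),
#' the realized load of an individual is
#' \deqn{2 n_{hom} / (2 n_{hom} + n_{het}),}
#' the fraction of its derived deleterious alleles exposed in homozygous
#' state; the masked load is the complementary fraction hidden in
#' heterozygotes (realized + masked = 1 on the shared denominator). The
#' derived allele is the minor allele: homozygous major-allele genotypes are
#' taken as the ancestral state, with no outgroup polarization.
#'
#' @param gt genotypes at the classified sites in the 0/1/2/`NA` encoding:
#'   a vector (one individual) or an individuals x sites matrix.
#' @param class_label label of the mutation class the sites belong to (e.g.
#'   `"deleterious"`, `"lof"`); carried through to the result.
#' @param polarize recode alleles so the derived allele is the sample minor
#'   allele (default `TRUE`; set `FALSE` if `gt` already counts derived
#'   alleles). At a 0.5-frequency tie the alternate allele is kept derived.
#' @return For a vector, an object of class `load_estimate` (fields
#'   `n_hom_derived`, `n_het`, `realized`, `masked`, `class_label`,
#'   `no_derived`). For a matrix, a data frame with one row per individual.
#' @export
genetic_load <- function(gt, class_label = "deleterious", polarize = TRUE) {
  if (is.matrix(gt)) {
    gm <- gt
    if (polarize) gm <- polarize_minor(gm)
    out <- do.call(rbind, lapply(seq_len(nrow(gm)), function(i) {
      e <- load_from_counts(sum(gm[i, ] == 2L, na.rm = TRUE),
                            sum(gm[i, ] == 1L, na.rm = TRUE), class_label)
      data.frame(individual = rownames(gm)[i] %||% i,
                 n_hom_derived = e$n_hom_derived, n_het = e$n_het,
                 realized = e$realized, masked = e$masked,
                 no_derived = e$no_derived)
    }))
    out$class_label <- class_label
    return(out)
  }
  if (polarize) {
    f <- mean(gt, na.rm = TRUE) / 2
    if (is.finite(f) && f > 0.5) gt <- 2L - gt
  }
  load_from_counts(sum(gt == 2L, na.rm = TRUE),
                   sum(gt == 1L, na.rm = TRUE), class_label)
}

polarize_minor <- function(gm) {
  f <- colMeans(gm, na.rm = TRUE) / 2
  flip <- which(is.finite(f) & f > 0.5)
  if (length(flip)) gm[, flip] <- 2L - gm[, flip]
  gm
}

load_from_counts <- function(n_hom, n_het, class_label) {
  denom <- 2 * n_hom + n_het
  if (denom == 0) {
    est <- list(n_hom_derived = n_hom, n_het = n_het, realized = 0,
                masked = 0, class_label = class_label, no_derived = TRUE)
  } else {
    est <- list(n_hom_derived = n_hom, n_het = n_het,
                realized = 2 * n_hom / denom, masked = n_het / denom,
                class_label = class_label, no_derived = FALSE)
  }
  structure(est, class = "load_estimate")
}

#' @export
print.load_estimate <- function(x, ...) {
  cat(sprintf("%s load: realized %.4f, masked %.4f (%d hom, %d het)%s\n",
              x$class_label, x$realized, x$masked, x$n_hom_derived, x$n_het,
              if (x$no_derived) " [no derived alleles]" else ""))
  invisible(x)
}

#' Classify a missense mutation by Grantham score
#'
#' Physicochemical-distance classification of amino-acid substitutions:
#' scores of 150 and above are deleterious, below 150 benign. Valid Grantham
#' scores range from 5 to 215.
#'
#' @param grantham_score integer score(s) in \[5, 215\].
#' @return Character vector, `"deleterious"` or `"benign"`.
#' @export
classify_missense <- function(grantham_score) {
  if (any(!is.finite(grantham_score) | grantham_score < 5 |
          grantham_score > 215))
    stop_hylopop("Grantham scores must lie in [5, 215]")
  ifelse(grantham_score >= 150, "deleterious", "benign")
}

#' Runs-of-homozygosity inbreeding coefficient
#'
#' \eqn{F_{ROH} = \sum_i length(ROH_i) / L}: the summed length of ROH
#' segments at or above the minimum length threshold, divided by the total
#' genome length. Segment detection is not performed here; segments come
#' from the forward simulator's autozygosity tracker or an external caller.
#'
#' @param segments data frame with columns `chrom`, `start`, `end` (bp,
#'   inclusive coordinates), sorted and non-overlapping within chromosomes.
#'   May have zero rows.
#' @param min_length minimum ROH length retained, in bp (conventionally
#'   5e5 or 1e6).
#' @param genome_length total genome length L in bp.
#' @return Object of class `roh_profile`: list with `segments` (retained),
#'   `min_length`, `froh`.
#' @export
froh <- function(segments, min_length = 5e5, genome_length) {
  if (is.null(segments) || nrow(segments) == 0L) {
    return(structure(list(segments = segments, min_length = min_length,
                          froh = 0), class = "roh_profile"))
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(segments)))
  if (any(segments$end < segments$start))
    stop_hylopop("ROH segments must have end >= start")
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1] <= s$end[-nrow(s)]))
      stop_hylopop(sprintf("overlapping ROH segments on chromosome %s", ch))
  }
  len <- segments$end - segments$start + 1
  keep <- len >= min_length
  fr <- sum(len[keep]) / genome_length
  if (fr > 1) stop_hylopop("ROH lengths exceed the genome length")
  structure(list(segments = segments[keep, , drop = FALSE],
                 min_length = min_length, froh = fr),
            class = "roh_profile")
}

#' @export
print.roh_profile <- function(x, ...) {
  cat(sprintf("F_ROH(>=%g bp) = %.4f over %d segments\n",
              x$min_length, x$froh, nrow(x$segments)))
  invisible(x)
}

#' Pedigree-based recombination rate
#'
#' Counts crossovers over neighbouring phased allele pairs: for each pair of
#' adjacent informative loci, a crossover occurred if one allele was
#' inherited from one parental haplotype and the other from the other (e.g.
#' parent AB/ab, offspring gamete Ab or aB). The regional recombination rate
#' is crossover events divided by the number of neighbouring phased allele
#' pairs examined.
#'
#' @param phased a [gen_phased_pedigree()] object, or a matrix of
#'   parental-haplotype origins (meioses x loci, entries 0/1).
#' @param region optional integer pair `c(from, to)` restricting the loci
#'   considered (default all).
#' @return Recombination rate (fraction) with attributes `n_crossovers` and
#'   `n_pairs`.
#' @export
pedigree_recombination_rate <- function(phased, region = NULL) {
  g <- if (inherits(phased, "phased_pedigree")) phased$gametes
       else as.matrix(phased)
  if (!is.null(region)) {
    if (length(region) != 2L || region[1] >= region[2])
      stop_hylopop("`region` must be c(from, to) with from < to")
    g <- g[, region[1]:region[2], drop = FALSE]
  }
  if (ncol(g) < 2L)
    stop_hylopop("fewer than 2 informative loci in the region")
  sw <- g[, -1L, drop = FALSE] != g[, -ncol(g), drop = FALSE]
  structure(sum(sw) / length(sw),
            n_crossovers = sum(sw), n_pairs = length(sw))
}
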