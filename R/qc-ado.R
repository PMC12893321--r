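#' Count allele-dropout events in trios by Mendelian inconsistency
#'
#' Scans parent-parent-offspring genotype triples for the two diagnostic
#' Mendelian-inconsistency patterns produced by allele dropout (ADO) in
#' low-input (e.g. fecal) sequencing data:
#'
#' * homozygote x heterozygote parents with an offspring homozygous for the
#'   allele the homozygous parent does not carry (AA x Aa -> aa, and its
#'   allele-relabelled mirror), and
#' * opposite-homozygote parents (AA x aa) with any homozygous offspring.
#'
#' A site enters the denominator ("informative") when all three members are
#' called and the parental pair matches one of the two patterns above; the
#' raw ADO rate is events / informative sites. Because a dropout is only
#' *visible* in a subset of configurations, the raw rate underestimates the
#' per-allele dropout probability; when `per_allele = TRUE` the function also
#' inverts an exact detection-probability model (Hardy-Weinberg parents,
#' Mendelian transmission, independent per-allele dropout at heterozygous
#' genotypes) to return a method-of-moments estimate of the per-allele rate.
#'
#' @param trios a [trio_set()].
#' @param per_allele also compute the detection-corrected per-allele dropout
#'   estimate (default `TRUE`).
#' @param maf optional per-site minor-allele frequencies used by the
#'   correction; defaults to `trios$maf` when present, otherwise allele
#'   frequencies estimated from the called parental genotypes.
#' @return An object of class `ado_estimate`: list with `n_events`,
#'   `n_informative`, `rate` (= n_events / n_informative) and, when
#'   requested, `per_allele_rate`.
#' @export
count_mendelian_ado <- function(trios, per_allele = TRUE, maf = NULL) {
  stopifnot(inherits(trios, "trio_set"))
  cls <- classify_trio_sites(trios$father, trios$mother, trios$offspring)
  if (cls$n_informative == 0L)
    stop_hylopop("no informative sites: no trio has a hom x het or hom x opposite-hom parental pair with all members called")
  est <- structure(list(n_events = cls$n_events,
                        n_informative = cls$n_informative,
                        rate = cls$n_events / cls$n_informative,
                        n_homhet = cls$n_homhet, n_homhom = cls$n_homhom),
                   class = "ado_estimate")
  if (per_allele) {
    if (is.null(maf)) maf <- trios$maf
    if (is.null(maf)) {
      par_gt <- rbind(trios$father, trios$mother)
      maf <- colMeans(par_gt, na.rm = TRUE) / 2
      maf <- pmin(maf, 1 - maf)
      maf <- maf[is.finite(maf)]
    }
    est$per_allele_rate <- invert_ado_rate(est$rate, maf)
  }
  est
}

#' @export
print.ado_estimate <- function(x, ...) {
  cat(sprintf("ADO: %d events / %d informative sites = %.4f raw rate",
              x$n_events, x$n_informative, x$rate))
  if (!is.null(x$per_allele_rate))
    cat(sprintf(" (per-allele estimate %.4f)", x$per_allele_rate))
  cat("\n")
  invisible(x)
}

# Vectorised classification of trio genotype cells into informative sites and
# ADO events under the two Mendelian-inconsistency rules.
classify_trio_sites <- function(fa, mo, of) {
  called <- !is.na(fa) & !is.na(mo) & !is.na(of)
  lo <- pmin(fa, mo)
  hi <- pmax(fa, mo)
  homhet <- called & ((lo == 0L & hi == 1L) | (lo == 1L & hi == 2L))
  homhom <- called & lo == 0L & hi == 2L
  # hom x het: event when offspring is the homozygote opposite the hom parent
  opp <- ifelse(lo == 0L, 2L, 0L)
  ev_homhet <- homhet & of == opp
  ev_homhom <- homhom & (of == 0L | of == 2L)
  list(n_informative = sum(homhet) + sum(homhom),
       n_events = sum(ev_homhet) + sum(ev_homhom),
       n_homhet = sum(homhet), n_homhom = sum(homhom))
}

# Expected (event, informative) probabilities at one site of minor-allele
# frequency f under per-allele dropout rate p, by exhaustive enumeration of
# true parental genotypes, Mendelian offspring, and dropout outcomes.
# Returns the summed coefficients over the supplied f values for each of the
# 27 true-genotype triples, so the p-dependence can be evaluated cheaply.
ado_expectation_fn <- function(f) {
  hwe <- cbind((1 - f)^2, 2 * f * (1 - f), f^2)  # P(gt = 0,1,2 | f)
  mendel <- function(g1, g2, g3) {
    # P(offspring g3 | parents g1, g2): sum of two Bernoulli transmissions
    t1 <- g1 / 2; t2 <- g2 / 2
    switch(g3 + 1L,
           (1 - t1) * (1 - t2),
           t1 * (1 - t2) + (1 - t1) * t2,
           t1 * t2)
  }
  w <- array(0, c(3, 3, 3))
  for (g1 in 0:2) for (g2 in 0:2) for (g3 in 0:2)
    w[g1 + 1, g2 + 1, g3 + 1] <-
      sum(hwe[, g1 + 1] * hwe[, g2 + 1]) * mendel(g1, g2, g3)
  # observation model: P(obs | true) with obs in 0:2 (missing excluded)
  function(p) {
    O <- rbind(c(1, 0, 0),
               c(p * (1 - p), (1 - p)^2, p * (1 - p)),
               c(0, 0, 1))
    e_event <- 0; e_inf <- 0
    for (g1 in 0:2) for (g2 in 0:2) for (g3 in 0:2) {
      wt <- w[g1 + 1, g2 + 1, g3 + 1]
      if (wt == 0) next
      for (o1 in 0:2) for (o2 in 0:2) for (o3 in 0:2) {
        pr <- O[g1 + 1, o1 + 1] * O[g2 + 1, o2 + 1] * O[g3 + 1, o3 + 1]
        if (pr == 0) next
        lo <- min(o1, o2); hi <- max(o1, o2)
        homhet <- (lo == 0 && hi == 1) || (lo == 1 && hi == 2)
        homhom <- lo == 0 && hi == 2
        if (!homhet && !homhom) next
        e_inf <- e_inf + wt * pr
        event <- if (homhet) o3 == (if (lo == 0) 2 else 0)
                 else o3 == 0 || o3 == 2
        if (event) e_event <- e_event + wt * pr
      }
    }
    c(event = e_event, informative = e_inf)
  }
}

# Solve E[event]/E[informative] (p) = observed raw rate for the per-allele
# dropout probability p.
invert_ado_rate <- function(observed_rate, maf) {
  if (observed_rate <= 0) return(0)
  expct <- ado_expectation_fn(maf)
  g <- function(p) { e <- expct(p); e[["event"]] / e[["informative"]] }
  hi <- 0.999
  if (g(hi) <= observed_rate) return(NA_real_)  # rate beyond model range
  uniroot(function(p) g(p) - observed_rate, c(1e-9, hi),
          tol = 1e-9)$root
}

#' Genotype discordance between duplicate libraries
#'
#' Fraction of jointly-called genotypes that differ between two genotype
#' matrices obtained from duplicate sequencing libraries of the same
#' individuals. Captures allele dropout plus any other random or systematic
#' genotyping error (e.g. false alleles).
#'
#' @param dupA,dupB [genotype_matrix()] objects (or bare 0/1/2/`NA`
#'   matrices) over the same individuals and sites.
#' @return The discordant fraction (numeric scalar) with attributes
#'   `n_compared` and `n_discordant`.
#' @export
genotype_discordance <- function(dupA, dupB) {
  a <- if (inherits(dupA, "genotype_matrix")) dupA$gt else as.matrix(dupA)
  b <- if (inherits(dupB, "genotype_matrix")) dupB$gt else as.matrix(dupB)
  if (!identical(dim(a), dim(b)))
    stop_hylopop("duplicate libraries must share individuals and sites")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop_hylopop("duplicate libraries must be over the same individuals")
  joint <- !is.na(a) & !is.na(b)
  n <- sum(joint)
  if (n == 0L) stop_hylopop("no jointly-called genotypes to compare")
  d <- sum(a[joint] != b[joint])
  structure(d / n, n_compared = n, n_discordant = d)
}

#' ADO rate as a function of sequencing depth
#'
#' Bins trio genotypes by read depth and computes a Mendelian-inconsistency
#' ADO estimate per bin, then locates the depth at which the ADO trend
#' levels off (the plateau): the smallest bin beyond which every consecutive
#' rate change is below `tolerance`.
#'
#' @param trios a [trio_set()] carrying per-genotype depths.
#' @param depth_bins increasing numeric vector of bin breakpoints; cells with
#'   depth in \[b_i, b_(i+1)) go to bin i, the last bin is open above.
#' @param tolerance absolute rate change below which consecutive bins are
#'   considered flat (default 0.005).
#' @param binning `"offspring"` bins by the offspring genotype depth,
#'   `"mean"` by the mean depth of the three members at that cell.
#' @return A list with `profile` (data frame: bin label, depth bounds,
#'   n_events, n_informative, rate) and `plateau_depth` (lower depth bound
#'   of the first bin after the last rate change exceeding `tolerance`; the
#'   first bin for a flat profile). Empty bins are reported with
#'   `n_informative = 0` and excluded from the plateau search.
#' @export
ado_depth_profile <- function(trios, depth_bins, tolerance = 0.005,
                              binning = c("offspring", "mean")) {
  stopifnot(inherits(trios, "trio_set"))
  binning <- match.arg(binning)
  if (is.null(trios$depth))
    stop_hylopop("trio_set carries no per-genotype depths")
  dp <- switch(binning,
               offspring = trios$depth$offspring,
               mean = (trios$depth$father + trios$depth$mother +
                       trios$depth$offspring) / 3)
  if (is.unsorted(depth_bins, strictly = TRUE))
    stop_hylopop("`depth_bins` must be strictly increasing")
  bin <- findInterval(dp, depth_bins)
  nb <- length(depth_bins)
  rows <- lapply(seq_len(nb), function(i) {
    sel <- bin == i
    masked <- function(m) { m[!sel] <- NA_integer_; m }
    cls <- classify_trio_sites(masked(trios$father), masked(trios$mother),
                               masked(trios$offspring))
    data.frame(bin = i, depth_lo = depth_bins[i],
               depth_hi = if (i < nb) depth_bins[i + 1] else Inf,
               n_events = cls$n_events, n_informative = cls$n_informative,
               rate = if (cls$n_informative > 0)
                 cls$n_events / cls$n_informative else NA_real_)
  })
  profile <- do.call(rbind, rows)
  filled <- profile[profile$n_informative > 0L, , drop = FALSE]
  plateau <- NA_real_
  if (nrow(filled) >= 1L) {
    dr <- abs(diff(filled$rate))
    # plateau = first bin after the last super-tolerance rate change
    # (the final bin qualifies trivially; a flat profile plateaus at bin 1)
    big <- which(dr >= tolerance)
    plateau <- filled$depth_lo[if (length(big)) max(big) + 1L else 1L]
  }
  list(profile = profile, plateau_depth = plateau)
}
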