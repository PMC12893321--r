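#' Folded site-frequency spectrum
#'
#' Counts segregating sites by minor-allele count. The folded spectrum is
#' agnostic to ancestral state: a site at derived count k in n chromosomes is
#' binned at min(k, n - k), giving bins 1 ... floor(n/2). Bin totals sum to
#' the number of segregating sites.
#'
#' @param x a [genotype_matrix()] or a 0/1/2/`NA` matrix (individuals x
#'   sites).
#' @return Named integer vector of counts for minor-allele counts
#'   1 ... floor(n/2) (n = 2 x individuals). Monomorphic-only input yields an
#'   all-zero spectrum with a warning.
#' @export
folded_sfs <- function(x) {
  gt <- if (inherits(x, "genotype_matrix")) x$gt else as.matrix(x)
  n_chr_site <- 2L * colSums(!is.na(gt))
  ac <- colSums(gt, na.rm = TRUE)
  nmax <- 2L * nrow(gt)
  bins <- seq_len(nmax %/% 2L)
  minor <- pmin(ac, n_chr_site - ac)
  seg <- minor > 0L & n_chr_site > 0L
  if (!any(seg)) {
    warning("no segregating sites: empty folded spectrum")
    return(setNames(integer(length(bins)), bins))
  }
  setNames(tabulate(minor[seg], nbins = length(bins)), bins)
}

#' Frequency-clustering balancing-selection score for one window
#'
#' Scores a core site by how tightly the folded allele frequencies of its
#' flanking variants cluster around the core's folded frequency. Balancing
#' selection (e.g. heterozygote advantage) maintains linked variants near the
#' equilibrium frequency of the balanced allele, so windows whose flanks sit
#' at the core frequency score higher than windows with the same number of
#' uniformly spread flanking frequencies. The kernel used here is
#' \eqn{w_i = 1 - |f_i - f_0| / 0.5} summed over flanking sites (folded
#' frequencies lie in (0, 0.5\]); the functional form is deliberately
#' pluggable — externally computed scores can be fed straight to
#' [select_top()].
#'
#' @param freqs folded allele frequencies of all sites in the window
#'   (including the core site), each in (0, 0.5\].
#' @param core index of the core site within `freqs`.
#' @return Numeric score (0 for a single-site window).
#' @export
beta_score <- function(freqs, core) {
  if (length(freqs) == 0L) stop_hylopop("empty window")
  if (core < 1L || core > length(freqs))
    stop_hylopop("`core` must index a site inside the window")
  if (any(freqs <= 0 | freqs > 0.5))
    stop_hylopop("folded frequencies must lie in (0, 0.5]")
  flank <- freqs[-core]
  if (!length(flank)) return(0)
  sum(pmax(0, 1 - abs(flank - freqs[core]) / 0.5))
}

#' Genome scan of the frequency-clustering score
#'
#' Applies [beta_score()] to a window around every site.
#'
#' @param pos site positions in bp (sorted).
#' @param freqs folded allele frequencies per site, in (0, 0.5\].
#' @param window_size flank size in bp on each side of the core site
#'   (default 1000).
#' @return Data frame with `position`, `folded_frequency`, `score`.
#' @export
beta_scan <- function(pos, freqs, window_size = 1000) {
  stopifnot(length(pos) == length(freqs))
  if (is.unsorted(pos)) {
    o <- order(pos); pos <- pos[o]; freqs <- freqs[o]
  }
  lo <- findInterval(pos - window_size, pos, left.open = TRUE) + 1L
  hi <- findInterval(pos + window_size, pos)
  score <- vapply(seq_along(pos), function(i) {
    idx <- lo[i]:hi[i]
    beta_score(freqs[idx], which(idx == i))
  }, numeric(1))
  data.frame(position = pos, folded_frequency = freqs, score = score)
}

#' Select the top-scoring fraction of sites
#'
#' Marks the top 5% (by default) of balancing-selection scores as selected:
#' exactly `ceiling(fraction * n)` sites. Ties at the score threshold are
#' broken deterministically by ascending position.
#'
#' @param scores data frame with `position` and `score` (e.g. from
#'   [beta_scan()]), or a numeric score vector (positions default to index).
#' @param fraction selected fraction (default 0.05).
#' @return Data frame with `position`, `score`, `selected` (logical); the
#'   selected set has size `ceiling(fraction * n)`.
#' @export
select_top <- function(scores, fraction = 0.05) {
  if (is.numeric(scores))
    scores <- data.frame(position = seq_along(scores), score = scores)
  stopifnot(all(c("position", "score") %in% names(scores)))
  n <- nrow(scores)
  if (n == 0L) stop_hylopop("no scores to select from")
  m <- ceiling(fraction * n)
  o <- order(-scores$score, scores$position)
  sel <- logical(n)
  sel[o[seq_len(m)]] <- TRUE
  scores$selected <- sel
  scores[order(scores$position), , drop = FALSE]
}

#' Compare recombination rates of genes with their flanking regions
#'
#' Builds the per-gene triple (left flank, gene, right flank) of regional
#' recombination rates (e.g. from [pedigree_recombination_rate()]) and
#' reports paired and unpaired test statistics: a paired t test between left
#' and right flanks (flank symmetry), and paired plus unpaired Wilcoxon
#' tests of gene vs flank rates. Genes missing a flank rate are excluded and
#' reported.
#'
#' @param rates data frame with columns `gene_id`, `gene`, `left_flank`,
#'   `right_flank` (rates per region).
#' @return List with `table` (complete cases), `n_excluded`,
#'   `left_vs_right` (paired t test), `gene_vs_flank_paired` (Wilcoxon
#'   signed-rank on gene minus mean flank), `gene_vs_flank_unpaired`
#'   (Wilcoxon rank-sum, genes vs pooled flanks). Degenerate inputs (all
#'   differences zero) yield `NULL` test entries.
#' @export
flank_compare <- function(rates) {
  stopifnot(is.data.frame(rates),
            all(c("gene_id", "gene", "left_flank", "right_flank") %in%
                  names(rates)))
  ok <- complete.cases(rates[, c("gene", "left_flank", "right_flank")])
  tab <- rates[ok, , drop = FALSE]
  if (nrow(tab) < 2L) stop_hylopop("need >= 2 genes with both flank rates")
  safe <- function(expr) tryCatch(suppressWarnings(expr),
                                  error = function(e) NULL)
  mean_flank <- (tab$left_flank + tab$right_flank) / 2
  lr <- if (all(tab$left_flank == tab$right_flank)) NULL else
    safe(t.test(tab$left_flank, tab$right_flank, paired = TRUE))
  gf_p <- if (all(tab$gene == mean_flank)) NULL else
    safe(wilcox.test(tab$gene, mean_flank, paired = TRUE, exact = FALSE))
  gf_u <- safe(wilcox.test(tab$gene, c(tab$left_flank, tab$right_flank),
                           exact = FALSE))
  list(table = tab, n_excluded = sum(!ok),
       left_vs_right = lr,
       gene_vs_flank_paired = gf_p,
       gene_vs_flank_unpaired = gf_u)
}
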