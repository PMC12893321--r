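#' GC content at fourfold-degenerate sites (GC4)
#'
#' Computes the GC fraction over third positions of fourfold-degenerate
#' codons of an in-frame coding sequence. Because GC at these synonymous
#' sites is shaped by GC-biased gene conversion, GC4 serves as a proxy for
#' the local recombination rate in primates. Only the standard genetic code
#' is used: a codon is fourfold-degenerate when all four third-position
#' variants of its first two bases encode the same amino acid.
#'
#' @param coding_sequence in-frame nucleotide sequence (character string or
#'   [Biostrings::DNAString]); length must be divisible by 3. A terminal
#'   stop codon is allowed; an internal stop codon is an error.
#' @param gene_id identifier carried into the record.
#' @return Object of class `gc4_record`: list with `gene_id`,
#'   `n_fourfold_sites`, and `gc4` (`NA` when the gene has no
#'   fourfold-degenerate codon).
#' @export
gc4 <- function(coding_sequence, gene_id = "gene") {
  s <- toupper(as.character(coding_sequence))
  if (nchar(s) %% 3L != 0L)
    stop_hylopop("coding sequence length must be divisible by 3")
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (any(is.na(aa)))
    stop_hylopop("sequence contains non-ACGT codons")
  stops <- which(aa == "*")
  if (any(stops < length(codons)))
    stop_hylopop(sprintf("internal stop codon at codon %d",
                         stops[stops < length(codons)][1]))
  ff <- codons %in% fourfold_codons()
  n4 <- sum(ff)
  g <- if (n4 == 0L) NA_real_ else {
    third <- substring(codons[ff], 3, 3)
    mean(third %in% c("G", "C"))
  }
  structure(list(gene_id = gene_id, n_fourfold_sites = n4, gc4 = g),
            class = "gc4_record")
}

# codons whose third position is fully degenerate under the standard code
fourfold_codons <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      gc <- Biostrings::GENETIC_CODE
      prefixes <- unique(substr(names(gc), 1, 2))
      ff <- unlist(lapply(prefixes, function(p) {
        cods <- paste0(p, c("A", "C", "G", "T"))
        if (length(unique(unname(gc[cods]))) == 1L) cods else character()
      }))
      memo <<- ff
    }
    memo
  }
})

#' @export
print.gc4_record <- function(x, ...) {
  cat(sprintf("GC4[%s]: %s over %d fourfold-degenerate sites\n", x$gene_id,
              if (is.na(x$gc4)) "undefined" else sprintf("%.3f", x$gc4),
              x$n_fourfold_sites))
  invisible(x)
}

#' GC4 for every gene in a coding-sequence set
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet] of
#'   in-frame coding sequences.
#' @return Data frame with `gene_id`, `n_fourfold_sites`, `gc4`.
#' @export
gc4_table <- function(sequences) {
  ids <- names(sequences) %||% sprintf("gene%05d", seq_along(sequences))
  rows <- lapply(seq_along(sequences), function(i) {
    r <- gc4(sequences[[i]], ids[i])
    data.frame(gene_id = r$gene_id, n_fourfold_sites = r$n_fourfold_sites,
               gc4 = r$gc4)
  })
  do.call(rbind, rows)
}

#' Split genes into high- and low-recombination classes by GC4
#'
#' Genes in the top 50% of defined GC4 values are classed as
#' high-recombination, the bottom 50% as low-recombination. The split is at
#' the median; values exactly at the median go to the low class by default
#' (switchable), so the assignment is deterministic under ties.
#'
#' @param records data frame with columns `gene_id` and `gc4` (e.g. from
#'   [gc4_table()]); rows with `NA` gc4 are left unclassified.
#' @param ties `"low"` (default) or `"high"`: class receiving values equal
#'   to the median.
#' @return The input data frame with a `recombination_class` column
#'   (`"high"` / `"low"` / `NA`).
#' @export
partition_gc4 <- function(records, ties = c("low", "high")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(records), all(c("gene_id", "gc4") %in% names(records)))
  def <- which(!is.na(records$gc4))
  if (length(def) < 2L)
    stop_hylopop("need >= 2 defined GC4 values to partition")
  v <- records$gc4[def]
  if (max(v) - min(v) < .Machine$double.eps)
    stop_hylopop("degenerate partition: all GC4 values are identical")
  m <- median(v)
  cls <- rep(NA_character_, nrow(records))
  cls[def] <- ifelse(v > m, "high", ifelse(v < m, "low", ties))
  records$recombination_class <- cls
  records
}
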