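#' Genotype matrix container
#'
#' A light container for diploid biallelic genotypes: an integer matrix of
#' alternate-allele counts (0, 1, 2; `NA` = missing) with individuals in rows
#' and sites in columns, optionally carrying a per-genotype read-depth matrix
#' and site coordinates.
#'
#' @param gt integer matrix (individuals x sites) with entries in \{0, 1, 2\}
#'   or `NA` for missing calls.
#' @param depth optional numeric matrix of per-genotype read depths, same
#'   dimensions as `gt`.
#' @param chrom,pos optional site coordinates (length = number of sites);
#'   positions are 1-based as in VCF.
#' @param lineage optional character vector of per-individual lineage labels.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(gt, depth = NULL, chrom = NULL, pos = NULL,
                            lineage = NULL) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  bad <- !is.na(gt) & !(gt %in% 0:2)
  if (any(bad)) stop_hylopop("genotypes must be 0, 1, 2 or NA")
  if (is.null(rownames(gt)))
    rownames(gt) <- sprintf("ind%03d", seq_len(nrow(gt)))
  if (is.null(colnames(gt)))
    colnames(gt) <- sprintf("site%05d", seq_len(ncol(gt)))
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!identical(dim(depth), dim(gt)))
      stop_hylopop("`depth` must match the dimensions of `gt`")
  }
  if (is.null(chrom)) chrom <- rep("1", ncol(gt))
  if (is.null(pos)) pos <- seq_len(ncol(gt))
  structure(list(gt = gt, depth = depth,
                 chrom = as.character(chrom), pos = as.integer(pos),
                 lineage = lineage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d sites (%s depth%s)\n",
              nrow(x$gt), ncol(x$gt),
              if (is.null(x$depth)) "no" else "with",
              if (is.null(x$lineage)) "" else ", lineage labels"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$gt)

#' Parent-parent-offspring trio genotypes
#'
#' Bundles genotype calls (and optional depths) for a set of trios typed at
#' shared sites. Each of `father`, `mother`, `offspring` is a trios x sites
#' integer matrix in the 0/1/2/`NA` encoding of [genotype_matrix()].
#'
#' @param father,mother,offspring integer matrices (trios x sites).
#' @param depth optional list of three matching depth matrices.
#' @param maf optional numeric vector of the true minor-allele frequency per
#'   site (known for synthetic data).
#' @return An object of class `trio_set`.
#' @export
trio_set <- function(father, mother, offspring, depth = NULL, maf = NULL) {
  dims <- lapply(list(father, mother, offspring), dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop_hylopop("trio member matrices must share dimensions")
  structure(list(father = father, mother = mother, offspring = offspring,
                 depth = depth, maf = maf,
                 n_trios = nrow(father), n_sites = ncol(father)),
            class = "trio_set")
}

#' @export
print.trio_set <- function(x, ...) {
  cat(sprintf("trio_set: %d trios x %d sites\n", x$n_trios, x$n_sites))
  invisible(x)
}
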