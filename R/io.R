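#' Read a VCF into a genotype matrix
#'
#' Parses a VCF (via `vcfR`), keeps biallelic SNP sites, and returns the
#' genotypes as alternate-allele counts with per-genotype depths when a DP
#' FORMAT field is present. Multiallelic sites are dropped with a message.
#' Half-called genotypes (e.g. `./0`) are treated as missing. VCF
#' coordinates stay 1-based.
#'
#' @param path path to a (plain-text or gzipped) VCF file.
#' @return A [genotype_matrix()] (individuals in rows, sites in columns).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_hylopop(sprintf("no such file: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi))
    message(sprintf("dropped %d multiallelic site(s)", sum(multi)))
  keep <- which(!multi)
  if (!length(keep)) stop_hylopop("no biallelic sites in VCF")
  gt_raw <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    out
  }
  gt <- t(apply(gt_raw, 2, code))
  if (ncol(gt_raw) == 1L) gt <- matrix(gt, ncol = length(keep))
  rownames(gt) <- colnames(gt_raw)
  colnames(gt) <- rownames(gt_raw)
  depth <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth <- t(dp[keep, , drop = FALSE])
    if (ncol(gt_raw) == 1L) depth <- matrix(depth, ncol = length(keep))
    dimnames(depth) <- dimnames(gt)
  }
  genotype_matrix(gt, depth = depth,
                  chrom = fix[keep, "CHROM"],
                  pos = as.integer(fix[keep, "POS"]))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a plain-text VCF 4.2 with GT (and DP if available) FORMAT fields.
#' REF/ALT default to A/G per site. The writer covers the package's own
#' genotype containers; it is not a general-purpose VCF implementation.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$gt + 1L], nrow = nrow(gm$gt))
  gt_str[is.na(gt_str)] <- "./."
  fmt <- "GT"
  if (!is.null(gm$depth)) {
    dp <- gm$depth
    dp_str <- ifelse(is.na(dp), ".", as.character(dp))
    gt_str <- matrix(paste(gt_str, dp_str, sep = ":"), nrow = nrow(gt_str))
    fmt <- "GT:DP"
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=hylopop",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (fmt == "GT:DP")
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(gm$gt)), collapse = "\t"))
  body <- vapply(seq_len(ncol(gm$gt)), function(j) {
    paste(c(gm$chrom[j], gm$pos[j], colnames(gm$gt)[j], "A", "G", ".",
            "PASS", ".", fmt, gt_str[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a PED-like pedigree table
#'
#' Reads a whitespace-separated table with columns family, id, father,
#' mother, sex (code `"0"` or `NA` = missing parent) and extracts the trios
#' in which both parents are present in the table. Pedigree cycles (an
#' individual among its own ancestors) are rejected.
#'
#' @param path path to the pedigree file (no header; extra columns ignored).
#' @return List with `pedigree` (the parsed table) and `trios` (data frame
#'   `offspring`, `father`, `mother`).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop_hylopop(sprintf("no such file: %s", path))
  ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(ped) < 5L)
    stop_hylopop("pedigree table needs >= 5 columns (family, id, father, mother, sex)")
  ped <- ped[, 1:5]
  names(ped) <- c("family", "id", "father", "mother", "sex")
  for (col in c("id", "father", "mother"))
    ped[[col]] <- as.character(ped[[col]])
  missing_code <- function(x) is.na(x) | x == "0"
  # cycle check: walk parent links from every individual
  parent_of <- function(id) {
    r <- ped[ped$id == id, , drop = FALSE]
    if (!nrow(r)) return(character())
    p <- c(r$father[1], r$mother[1])
    p[!missing_code(p)]
  }
  for (id in ped$id) {
    seen <- character(); frontier <- parent_of(id)
    while (length(frontier)) {
      if (id %in% frontier)
        stop_hylopop(sprintf("pedigree cycle: %s is its own ancestor", id))
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
      frontier <- unique(unlist(lapply(frontier, parent_of)))
    }
  }
  has_both <- !missing_code(ped$father) & !missing_code(ped$mother) &
    ped$father %in% ped$id & ped$mother %in% ped$id
  trios <- data.frame(offspring = ped$id[has_both],
                      father = ped$father[has_both],
                      mother = ped$mother[has_both],
                      stringsAsFactors = FALSE)
  list(pedigree = ped, trios = trios)
}

#' Write a PED-like pedigree table
#'
#' @param pedigree data frame with columns family, id, father, mother, sex.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pedigree <- function(pedigree, path) {
  write.table(pedigree, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED-like gene intervals
#'
#' 0-based half-open intervals: columns chrom, start, end, and optionally
#' name.
#'
#' @param path path to the BED file.
#' @return Data frame with `chrom`, `start`, `end` and `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_hylopop(sprintf("no such file: %s", path))
  b <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 3L) stop_hylopop("BED needs >= 3 columns")
  names(b)[1:3] <- c("chrom", "start", "end")
  if (ncol(b) >= 4L) names(b)[4] <- "name"
  else b$name <- sprintf("region%05d", seq_len(nrow(b)))
  if (any(b$end <= b$start))
    stop_hylopop("BED intervals must have end > start (0-based half-open)")
  b[, c("chrom", "start", "end", "name")]
}

#' Read coding sequences from a FASTA file
#'
#' @param path path to a FASTA file of in-frame coding sequences.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop_hylopop(sprintf("no such file: %s", path))
  Biostrings::readDNAStringSet(path)
}
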